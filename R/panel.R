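#' Define a Y-STR locus panel
#'
#' A locus panel names the loci of a Y-STR multiplex, which of them are
#' constitutively duplicated (reported as an unordered pair of alleles), and
#' which are reported in a derived encoding. The default [yfiler_panel()]
#' describes the 17-locus Yfiler panel: 16 locus labels of which DYS385
#' contributes two allele values, for 17 values per haplotype.
#'
#' @param loci character vector of unique locus names.
#' @param multi_copy subset of `loci` reported as unordered allele pairs.
#' @param derived named list describing derived encodings; each element
#'   `list(minuend, subtrahend)` states that the encoded value of the named
#'   locus is `minuend - subtrahend` of the raw values. Used for the
#'   conventional DYS389II display encoding (raw DYS389II minus DYS389I).
#' @return An object of class `locus_panel`.
#' @export
#' @examples
#' p <- yfiler_panel()
#' p$loci
#' panel_columns(p)
locus_panel <- function(loci, multi_copy = character(), derived = list()) {
  loci <- as.character(loci)
  if (anyDuplicated(loci)) abort("locus names must be unique")
  if (!all(multi_copy %in% loci)) abort("`multi_copy` must be a subset of `loci`")
  if (length(derived) && !all(names(derived) %in% loci)) {
    abort("derived-encoding loci must be members of `loci`")
  }
  structure(
    list(loci = loci, multi_copy = multi_copy, derived = derived),
    class = "locus_panel"
  )
}

#' @rdname locus_panel
#' @export
yfiler_panel <- function() {
  locus_panel(
    loci = c(
      "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
      "DYS393", "DYS385", "DYS438", "DYS439", "DYS437", "DYS448",
      "DYS456", "DYS458", "DYS635", "YGATAH4"
    ),
    multi_copy = "DYS385",
    derived = list(DYS389II = list(minuend = "DYS389II", subtrahend = "DYS389I"))
  )
}

#' Allele column names of a panel
#'
#' Expands multi-copy loci into `a`/`b` columns, so the default Yfiler panel
#' yields 17 allele columns over its 16 locus labels.
#'
#' @param panel a [locus_panel()].
#' @return character vector of allele column names.
#' @export
panel_columns <- function(panel) {
  unlist(lapply(panel$loci, function(l) {
    if (l %in% panel$multi_copy) paste0(l, c("a", "b")) else l
  }), use.names = FALSE)
}

# map an allele column name back to its locus label
column_locus <- function(panel, cols) {
  mc <- panel$multi_copy
  out <- cols
  for (l in mc) out[out %in% paste0(l, c("a", "b"))] <- l
  out
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("<locus_panel> ", length(x$loci), " loci, ",
      length(panel_columns(x)), " allele columns\n", sep = "")
  cat("  loci: ", paste(x$loci, collapse = ", "), "\n", sep = "")
  if (length(x$multi_copy)) {
    cat("  multi-copy: ", paste(x$multi_copy, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
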