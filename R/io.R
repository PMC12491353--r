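#' Coerce a data frame to a validated haplotype table
#'
#' A haplotype table holds one row per male with a `sample_id`, a `population`
#' label and one numeric allele column per panel position (17 columns for the
#' Yfiler panel, DYS385 as `DYS385a`/`DYS385b`). Column names are matched
#' case-insensitively and ignoring punctuation, so YHRD-style headers such as
#' `"Y-GATA-H4"` or `"DYS385 a"` are accepted. Multi-copy pairs are stored
#' sorted ascending (the assay cannot phase the two copies); `NA` marks a
#' missing call.
#'
#' @param x a data frame with sample, population and allele columns. DYS385
#'   may be given as two columns or a single combined `"13-17"` column.
#' @param panel a [locus_panel()]; default [yfiler_panel()].
#' @param validate_alleles reject rows whose alleles are non-positive or whose
#'   fractional part is not one of 0, .1, .2, .3.
#' @return a tibble of class `hap_tbl` with attributes `panel`, `dys389ii`
#'   (`"raw"` or `"encoded"`) and `rejected` (a tibble of dropped rows and
#'   reasons).
#' @export
#' @examples
#' df <- data.frame(sample = c("S1", "S2"), population = "Yemen",
#'                  DYS19 = c(14, 15), DYS389I = 13, DYS389II = 29,
#'                  DYS390 = 23, DYS391 = 10, DYS392 = 11, DYS393 = 12,
#'                  DYS385 = c("13-17", "14-18"), DYS438 = 10, DYS439 = 11,
#'                  DYS437 = 14, DYS448 = 19, DYS456 = 15, DYS458 = "17.2",
#'                  DYS635 = 21, YGATAH4 = 11)
#' as_hap_tbl(df)
as_hap_tbl <- function(x, panel = yfiler_panel(), validate_alleles = TRUE) {
  x <- as_tibble(x)
  nm <- norm_name(names(x))

  id_aliases <- c("SAMPLE", "SAMPLEID", "ID", "SAMPLENAME", "INDIVIDUAL")
  pop_aliases <- c("POPULATION", "POP", "GROUP", "POPULATIONNAME")
  id_col <- which(nm %in% id_aliases)[1]
  pop_col <- which(nm %in% pop_aliases)[1]
  if (is.na(id_col)) abort("no sample-id column found (e.g. 'sample_id')")
  if (is.na(pop_col)) abort("no population column found (e.g. 'population')")

  cols <- panel_columns(panel)
  col_map <- setNames(rep(NA_integer_, length(cols)), cols)
  combined <- character() # multi-copy loci given as one joined column
  for (j in seq_along(nm)) {
    if (j %in% c(id_col, pop_col)) next
    hit <- which(norm_name(cols) == nm[j])
    if (length(hit) == 1) {
      col_map[hit] <- j
    } else if (nm[j] %in% norm_name(panel$multi_copy)) {
      combined <- c(combined, panel$multi_copy[norm_name(panel$multi_copy) == nm[j]])
      col_map[paste0(panel$multi_copy[norm_name(panel$multi_copy) == nm[j]], "a")] <- j
    } else {
      abort(sprintf("unknown column '%s' is neither sample/population nor a panel locus",
                    names(x)[j]))
    }
  }
  missing_cols <- cols[is.na(col_map) &
                         !(cols %in% paste0(combined, "b"))]
  if (length(missing_cols)) {
    abort(paste0("panel columns absent from input: ",
                 paste(missing_cols, collapse = ", ")))
  }

  sample_id <- as.character(x[[id_col]])
  population <- as.character(x[[pop_col]])
  if (anyDuplicated(sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  }

  nr <- nrow(x)
  alleles <- matrix(NA_real_, nr, length(cols), dimnames = list(NULL, cols))
  bad <- rep(NA_character_, nr)
  for (k in seq_along(cols)) {
    locus <- column_locus(panel, cols[k])
    if (locus %in% combined) {
      if (endsWith(cols[k], "b")) next # filled together with the 'a' column
      raw <- as.character(x[[col_map[k]]])
      parts <- strsplit(trimws(raw), "[-/]")
      a <- vapply(parts, function(p) parse_allele(p[1]), numeric(1))
      b <- vapply(parts, function(p) parse_allele(if (length(p) >= 2) p[2] else NA), numeric(1))
      alleles[, paste0(locus, "a")] <- a
      alleles[, paste0(locus, "b")] <- b
      bad[is.nan(a) | is.nan(b)] <- sprintf("unparsable %s value", locus)
    } else {
      v <- vapply(as.character(x[[col_map[k]]]), parse_allele, numeric(1), USE.NAMES = FALSE)
      alleles[, k] <- v
      bad[is.nan(v)] <- sprintf("unparsable %s value", cols[k])
    }
  }
  alleles[is.nan(alleles)] <- NA_real_

  if (validate_alleles) {
    frac_ok <- function(v) {
      f <- round((v - floor(v)) * 10)
      is.na(v) | (v > 0 & abs(v - floor(v) - f / 10) < 1e-6 & f %in% c(0, 1, 2, 3))
    }
    ok <- apply(alleles, 1, function(r) all(frac_ok(r)))
    bad[!ok & is.na(bad)] <- "allele out of range (must be > 0, fraction in .0/.1/.2/.3)"
  }

  # multi-copy pairs sorted ascending, missing copy last
  for (l in if (nr > 0) panel$multi_copy else character()) {
    ab <- alleles[, paste0(l, c("a", "b")), drop = FALSE]
    srt <- t(apply(ab, 1, function(p) {
      v <- sort(p, na.last = TRUE)
      if (length(v) < 2) v <- c(v, NA_real_)
      v
    }))
    alleles[, paste0(l, c("a", "b"))] <- srt
  }

  keep <- is.na(bad)
  rejected <- tibble(sample_id = sample_id[!keep], reason = bad[!keep])
  out <- bind_cols(
    tibble(sample_id = sample_id[keep], population = population[keep]),
    as_tibble(alleles[keep, , drop = FALSE])
  )
  new_hap_tbl(out, panel, dys389ii = "raw", rejected = rejected)
}

new_hap_tbl <- function(x, panel, dys389ii = "raw", rejected = NULL) {
  structure(
    x,
    panel = panel,
    dys389ii = dys389ii,
    rejected = rejected %||% tibble(sample_id = character(), reason = character()),
    class = c("hap_tbl", class(as_tibble(x)))
  )
}

# parse one allele token: "", NA and the sentinel 99 are missing; decimal
# comma accepted; anything non-numeric yields NaN (row rejection marker)
parse_allele <- function(v) {
  if (is.na(v)) return(NA_real_)
  v <- gsub(",", ".", trimws(as.character(v)), fixed = TRUE)
  if (v == "" || v == "99" || toupper(v) == "NA") return(NA_real_)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) NaN else x
}

hap_panel <- function(tbl, panel = NULL) {
  panel %||% attr(tbl, "panel") %||% yfiler_panel()
}

#' Read a Y-STR haplotype table from delimited text
#'
#' Reads TSV (default) or CSV (autodetected from the header line) with one row
#' per male. Unparsable rows are dropped and reported via the `rejected`
#' attribute; duplicate sample ids and unknown locus columns are hard errors.
#' The sentinel allele code `99` and empty cells both map to missing.
#'
#' @param path file path.
#' @inheritParams as_hap_tbl
#' @param delim field delimiter; `NULL` autodetects tab vs comma.
#' @return a `hap_tbl` (see [as_hap_tbl()]).
#' @export
read_haplotypes <- function(path, panel = yfiler_panel(), delim = NULL) {
  header <- readLines(path, n = 1L)
  delim <- delim %||% if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  tbl <- as_hap_tbl(raw, panel = panel)
  rej <- attr(tbl, "rejected")
  if (nrow(rej)) {
    warn(sprintf("%d row(s) rejected while reading '%s' (see attr(, 'rejected'))",
                 nrow(rej), path))
  }
  tbl
}

#' Write a haplotype table to delimited text
#'
#' Round-trips through [read_haplotypes()]: `read(write(t))` reproduces `t`
#' field for field. Missing calls are written as the sentinel code `99`.
#'
#' @param tbl a `hap_tbl`.
#' @param path output file path.
#' @param delim field delimiter (tab default).
#' @param dys385 write multi-copy loci as two columns (`"split"`) or one
#'   joined `"a-b"` column (`"combined"`).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(tbl, path, delim = "\t",
                             dys385 = c("split", "combined")) {
  dys385 <- match.arg(dys385)
  panel <- hap_panel(tbl)
  out <- as_tibble(as.data.frame(tbl))
  fmt <- function(v) ifelse(is.na(v), "99", format(v, trim = TRUE, scientific = FALSE))
  for (cn in panel_columns(panel)) out[[cn]] <- fmt(out[[cn]])
  if (dys385 == "combined") {
    cols_order <- c("sample_id", "population", panel_columns(panel))
    for (l in panel$multi_copy) {
      a <- paste0(l, "a"); b <- paste0(l, "b")
      out[[l]] <- paste0(out[[a]], "-", out[[b]])
      out[[a]] <- NULL; out[[b]] <- NULL
      cols_order[cols_order == a] <- l
      cols_order <- cols_order[cols_order != b]
    }
    out <- out[, cols_order]
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Switch DYS389II between raw and difference-encoded form
#'
#' The conventional allele-frequency display for DYS389II reports the
#' difference between the overall DYS389II repeat number and DYS389I, because
#' the DYS389II amplicon contains the DYS389I repeat stretch. This view is
#' used for frequency reporting only; distance computations use the raw value.
#' The table carries an encoding-state flag, so the operation is idempotent.
#'
#' @param tbl a `hap_tbl`.
#' @param direction `"encode"` (raw -> difference) or `"decode"`.
#' @return the table with DYS389II transformed and its state flag updated.
#'   Profiles missing either DYS389 locus are left unchanged with a warning.
#' @export
encode_dys389ii <- function(tbl, direction = c("encode", "decode")) {
  direction <- match.arg(direction)
  panel <- hap_panel(tbl)
  der <- panel$derived
  if (!length(der)) return(tbl)
  state <- attr(tbl, "dys389ii") %||% "raw"
  target <- if (direction == "encode") "encoded" else "raw"
  if (state == target) return(tbl)
  for (locus in names(der)) {
    m <- der[[locus]]$minuend; s <- der[[locus]]$subtrahend
    both <- !is.na(tbl[[m]]) & !is.na(tbl[[s]])
    if (any(!both)) {
      warn(sprintf("%d profile(s) missing %s or %s left unchanged", sum(!both), m, s))
    }
    if (direction == "encode") {
      tbl[[locus]][both] <- tbl[[m]][both] - tbl[[s]][both]
    } else {
      tbl[[locus]][both] <- tbl[[locus]][both] + tbl[[s]][both]
    }
  }
  attr(tbl, "dys389ii") <- target
  tbl
}

#' Per-locus allele frequencies
#'
#' Counts alleles over non-missing calls at each locus and normalizes to
#' frequencies. Multi-copy loci pool both copies into a single spectrum, so
#' DYS385 has up to two calls per male. Loci with zero non-missing calls are
#' excluded with a warning.
#'
#' @param tbl a `hap_tbl`.
#' @param panel optional [locus_panel()] override.
#' @param encode_dys389ii report DYS389II in its difference encoding
#'   (the conventional frequency-table display).
#' @return tibble with columns `locus`, `allele`, `count`, `n` (haploid calls
#'   at the locus) and `frequency`; frequencies sum to 1 within each locus.
#' @export
allele_frequencies <- function(tbl, panel = NULL, encode_dys389ii = FALSE) {
  panel <- hap_panel(tbl, panel)
  if (!nrow(tbl)) abort("empty haplotype table")
  if (encode_dys389ii) tbl <- encode_dys389ii(tbl, "encode")
  cols <- panel_columns(panel)
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(tbl))[, c("sample_id", cols)],
    cols = dplyr::all_of(cols), names_to = "column", values_to = "allele"
  )
  long$locus <- column_locus(panel, long$column)
  long <- filter(long, !is.na(.data$allele))
  empty <- setdiff(panel$loci, unique(long$locus))
  if (length(empty)) {
    warn(paste0("loci with no non-missing calls excluded: ",
                paste(empty, collapse = ", ")))
  }
  out <- long |>
    count(.data$locus, .data$allele, name = "count") |>
    group_by(.data$locus) |>
    mutate(n = sum(.data$count), frequency = .data$count / .data$n) |>
    ungroup() |>
    arrange(match(.data$locus, panel$loci), .data$allele)
  out
}
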