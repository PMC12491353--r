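#' Haplotype spectrum of a table
#'
#' Collapses profiles into distinct haplotypes over the panel columns and
#' counts their multiplicities. The haplotype key is the ordered tuple of
#' allele values (multi-copy pairs in ascending order); a missing call is a
#' distinct key symbol, so profiles differing only in which locus failed are
#' not merged.
#'
#' @param tbl a `hap_tbl`.
#' @param panel optional [locus_panel()] override.
#' @return a tibble of class `hap_spectrum` with columns `haplotype` (key
#'   string), `count`, and attributes `n` (individuals), `h` (distinct
#'   haplotypes) and `singletons`.
#' @export
haplotype_spectrum <- function(tbl, panel = NULL) {
  panel <- hap_panel(tbl, panel)
  if (!nrow(tbl)) abort("empty haplotype table")
  cols <- panel_columns(panel)
  m <- as.matrix(as.data.frame(tbl)[, cols])
  key <- apply(m, 1, function(r) paste(ifelse(is.na(r), "*", format(r, trim = TRUE)),
                                       collapse = "|"))
  tab <- sort(table(key), decreasing = TRUE)
  out <- tibble(haplotype = names(tab), count = as.integer(tab))
  spectrum_from_counts(out$count, haplotype = out$haplotype)
}

#' Build a spectrum directly from multiplicities
#'
#' @param counts integer multiplicities of the distinct haplotypes.
#' @param haplotype optional key labels (defaults to `H1..Hh`).
#' @return a `hap_spectrum` tibble (see [haplotype_spectrum()]).
#' @export
#' @examples
#' # 117 singletons, four doubletons and one tripleton: 128 males
#' s <- spectrum_from_counts(c(rep(1, 117), rep(2, 4), 3))
#' attr(s, "n"); attr(s, "h"); attr(s, "singletons")
spectrum_from_counts <- function(counts, haplotype = NULL) {
  counts <- as.integer(counts)
  if (!length(counts) || any(counts < 1)) abort("counts must be positive integers")
  out <- tibble(
    haplotype = haplotype %||% paste0("H", seq_along(counts)),
    count = counts
  )
  structure(out,
            n = sum(counts), h = length(counts),
            singletons = sum(counts == 1L),
            class = c("hap_spectrum", class(out)))
}

as_spectrum <- function(x) {
  if (inherits(x, "hap_spectrum")) x else haplotype_spectrum(x)
}

#' Nei haplotype diversity
#'
#' `HD = n (1 - sum p_i^2) / (n - 1)` with `p_i` the counting-method
#' haplotype frequencies.
#'
#' @param x a `hap_spectrum` or `hap_tbl`.
#' @return haplotype diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(x) {
  s <- as_spectrum(x)
  n <- attr(s, "n")
  if (n < 2) abort("haplotype diversity needs n >= 2")
  p <- s$count / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Haplotype match probability (sum of squared haplotype frequencies)
#' @inheritParams haplotype_diversity
#' @export
match_probability <- function(x) {
  s <- as_spectrum(x)
  sum((s$count / attr(s, "n"))^2)
}

#' Haplotype match probability from diversity, `HMP = 1 - HD`
#' @param hd haplotype diversity in `[0, 1]`.
#' @export
hmp <- function(hd) {
  if (is.na(hd) || hd < 0 || hd > 1) abort("HD must lie in [0, 1]")
  1 - hd
}

#' Discrimination capacity, `DC = h / n`
#' @inheritParams haplotype_diversity
#' @export
discrimination_capacity <- function(x) {
  s <- as_spectrum(x)
  attr(s, "h") / attr(s, "n")
}

#' Fraction of unique haplotypes
#'
#' `FUH = 100 * singletons / h`: the percentage of distinct haplotypes that
#' were observed exactly once.
#'
#' @inheritParams haplotype_diversity
#' @return percentage in `[0, 100]`.
#' @export
fraction_unique <- function(x) {
  s <- as_spectrum(x)
  100 * attr(s, "singletons") / attr(s, "h")
}

#' Per-locus diversity and match-probability statistics
#'
#' From an allele-frequency table: match probability `MP = sum p_i^2`, power
#' of discrimination `PD = 1 - MP`, gene diversity both biased
#' (`1 - sum p_i^2`) and unbiased (`n/(n-1)` corrected), and the allele
#' count.
#'
#' @param freqs output of [allele_frequencies()].
#' @return tibble with one row per locus.
#' @export
locus_stats <- function(freqs) {
  freqs |>
    group_by(.data$locus) |>
    summarise(
      n_alleles = dplyr::n(),
      n = .data$n[1],
      MP = sum(.data$frequency^2),
      PD = 1 - .data$MP,
      GD_biased = 1 - .data$MP,
      GD = ifelse(.data$n > 1, .data$n / (.data$n - 1) * .data$GD_biased, 0),
      .groups = "drop"
    ) |>
    arrange(match(.data$locus, unique(freqs$locus)))
}

#' Microvariant carriers per locus
#'
#' A profile counts once per locus if any copy at that locus carries a
#' non-integer (partial-repeat) allele, e.g. 17.2 at DYS458.
#'
#' @inheritParams haplotype_spectrum
#' @return tibble with `locus`, `carriers` and `pct` (percent of profiles).
#' @export
microvariant_scan <- function(tbl, panel = NULL) {
  panel <- hap_panel(tbl, panel)
  cols <- panel_columns(panel)
  m <- as.matrix(as.data.frame(tbl)[, cols])
  frac <- has_fraction(m)
  purrr::map_dfr(panel$loci, function(l) {
    cc <- cols[column_locus(panel, cols) == l]
    carriers <- sum(apply(frac[, cc, drop = FALSE], 1, any))
    tibble(locus = l, carriers = carriers, pct = 100 * carriers / nrow(tbl))
  })
}

#' Forensic summary of a haplotype table
#'
#' Aggregates the haplotype-level parameters (HD, HMP, match probability,
#' discrimination capacity, fraction of unique haplotypes) and the per-locus
#' block (gene diversity, MP/PD, allele counts, microvariant carriers), plus
#' the mean and SD of gene diversity over loci and the number of loci with
#' five or more alleles. The frequency of the most common haplotype is
#' reported under both conventions, count/n (counting method) and count/h.
#'
#' @inheritParams haplotype_spectrum
#' @param unbiased_gd use the unbiased per-locus gene diversity for the
#'   over-loci mean/SD (the STRAF convention); otherwise the biased form.
#' @return an object of class `forensic_summary`; see [tidy.forensic_summary()]
#'   and [glance.forensic_summary()].
#' @export
forensic_summary <- function(tbl, panel = NULL, unbiased_gd = TRUE) {
  panel <- hap_panel(tbl, panel)
  s <- haplotype_spectrum(tbl, panel)
  freqs <- allele_frequencies(tbl, panel)
  per_locus <- locus_stats(freqs) |>
    left_join(microvariant_scan(tbl, panel), by = "locus")
  gd <- if (unbiased_gd) per_locus$GD else per_locus$GD_biased
  hd <- haplotype_diversity(s)
  structure(list(
    spectrum = s,
    per_locus = per_locus,
    stats = tibble(
      n = attr(s, "n"), h = attr(s, "h"), singletons = attr(s, "singletons"),
      HD = hd, HMP = hmp(hd), MP_hap = match_probability(s),
      DC = discrimination_capacity(s), FUH = fraction_unique(s),
      top_freq_n = max(s$count) / attr(s, "n"),
      top_freq_h = max(s$count) / attr(s, "h"),
      mean_GD = mean(gd), sd_GD = stats::sd(gd),
      loci_ge5_alleles = sum(per_locus$n_alleles >= 5)
    )
  ), class = "forensic_summary")
}

#' @export
print.forensic_summary <- function(x, ...) {
  st <- x$stats
  cat(sprintf("Forensic summary: n = %d, h = %d (%d singletons)\n",
              st$n, st$h, st$singletons))
  cat(sprintf("  HD = %.5f  HMP = %.5f  MP = %.5f  DC = %.6f  FUH = %.1f%%\n",
              st$HD, st$HMP, st$MP_hap, st$DC, st$FUH))
  cat(sprintf("  mean GD over loci = %.3f (SD %.3f); %d loci with >= 5 alleles\n",
              st$mean_GD, st$sd_GD, st$loci_ge5_alleles))
  invisible(x)
}

#' Tidy the per-locus block of a forensic summary
#' @param x a `forensic_summary`.
#' @param ... unused.
#' @return tibble with one row per locus.
#' @export
tidy.forensic_summary <- function(x, ...) x$per_locus

#' One-row haplotype-level summary
#' @inheritParams tidy.forensic_summary
#' @export
glance.forensic_summary <- function(x, ...) x$stats
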