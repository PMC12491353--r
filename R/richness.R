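# --- rarefaction-standardized allelic richness ----------------------------
#
# Expected numbers of distinct and private alleles in standardized
# subsamples of g gene copies, via hypergeometric absence probabilities
# computed in log-gamma arithmetic.

# P(allele with count Ni absent from a subsample of size g out of N)
absent_prob <- function(N, Ni, g) {
  ifelse(N - Ni < g, 0, exp(lchoose(N - Ni, g) - lchoose(N, g)))
}

#' Expected number of distinct alleles in a subsample of size g
#'
#' `alpha_g = sum_i [1 - C(N - N_i, g) / C(N, g)]` over the allele counts
#' `N_i` of one population at one locus (haploid counts; `C(a, b) = 0` when
#' `a < b`). At `g = N` this equals the observed number of distinct alleles;
#' at `g = 1` it is 1.
#'
#' @param counts integer allele counts (one population, one locus).
#' @param g subsample size, `1 <= g <= sum(counts)`.
#' @return expected distinct alleles.
#' @export
distinct_rarefaction <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) abort("g must lie in [1, sum(counts)]")
  sum(1 - absent_prob(N, counts, g))
}

#' Expected number of private alleles in subsamples of size g
#'
#' For each population j, the expected number of alleles present in its
#' subsample of size `g` but absent from the size-`g` subsamples of every
#' other population:
#' `pi_g(j) = sum_i (1 - Q_ij) * prod_{j' != j} Q_ij'` with
#' `Q_ij = C(N_jl - N_ijl, g)/C(N_jl, g)`.
#'
#' @param counts allele-by-population integer count matrix for one locus.
#' @param g subsample size, at most the smallest population total.
#' @return named vector of expected private alleles per population.
#' @export
private_rarefaction <- function(counts, g) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort("private alleles require at least two populations")
  Nj <- colSums(counts)
  if (g < 1 || g > min(Nj)) abort("g must lie in [1, min population total]")
  Q <- vapply(seq_len(ncol(counts)),
              function(j) absent_prob(Nj[j], counts[, j], g),
              numeric(nrow(counts)))
  Q <- matrix(Q, nrow = nrow(counts))
  out <- vapply(seq_len(ncol(counts)), function(j) {
    sum((1 - Q[, j]) * apply(Q[, -j, drop = FALSE], 1, prod))
  }, numeric(1))
  setNames(out, colnames(counts))
}

# haploid allele counts per population at one locus (multi-copy pooled)
locus_counts_by_pop <- function(tbl, panel, locus) {
  cols <- panel_columns(panel)
  cc <- cols[column_locus(panel, cols) == locus]
  vals <- as.matrix(as.data.frame(tbl)[, cc, drop = FALSE])
  pops <- unique(tbl$population)
  alleles <- sort(unique(stats::na.omit(as.vector(vals))))
  m <- matrix(0L, length(alleles), length(pops),
              dimnames = list(format(alleles, trim = TRUE), pops))
  for (p in pops) {
    v <- as.vector(vals[tbl$population == p, , drop = FALSE])
    v <- v[!is.na(v)]
    t0 <- table(factor(format(v, trim = TRUE), levels = rownames(m)))
    m[, p] <- as.integer(t0)
  }
  m
}

#' Rarefaction profile of distinct and private alleles
#'
#' Iterates [distinct_rarefaction()] and [private_rarefaction()] over loci
#' and populations on a grid of subsample sizes `g`, bounded above by the
#' smallest per-locus haploid sample among the populations, and also reports
#' the mean over loci per population (the usual per-locus summary display).
#'
#' @param tbl a `hap_tbl` with at least two populations.
#' @param g integer vector of subsample sizes; default `2:g_max` with
#'   `g_max` the smallest per-locus population total.
#' @param panel optional [locus_panel()] override.
#' @return tibble of class `rarefaction_curve` with columns `population`,
#'   `locus`, `g`, `distinct`, `private`; the mean-over-loci view is the
#'   attribute `"mean_over_loci"` (population, g, distinct, private).
#' @export
richness_profile <- function(tbl, g = NULL, panel = NULL) {
  panel <- hap_panel(tbl, panel)
  pops <- unique(tbl$population)
  if (length(pops) < 2) abort("richness profile requires at least two populations")
  counts <- lapply(panel$loci, function(l) locus_counts_by_pop(tbl, panel, l))
  names(counts) <- panel$loci
  g_max <- min(vapply(counts, function(m) min(colSums(m)), numeric(1)))
  if (g_max < 2) abort("smallest per-locus sample is below 2; cannot rarefy")
  g <- g %||% seq(2L, g_max)
  if (any(g > g_max)) abort(sprintf("g exceeds the smallest per-locus sample (%d)", g_max))
  out <- purrr::map_dfr(panel$loci, function(l) {
    m <- counts[[l]]
    purrr::map_dfr(g, function(gg) {
      priv <- private_rarefaction(m, gg)
      tibble(
        population = colnames(m), locus = l, g = gg,
        distinct = vapply(seq_len(ncol(m)),
                          function(j) distinct_rarefaction(m[, j], gg),
                          numeric(1)),
        private = unname(priv)
      )
    })
  })
  mean_view <- out |>
    group_by(.data$population, .data$g) |>
    summarise(distinct = mean(.data$distinct), private = mean(.data$private),
              .groups = "drop")
  structure(out, mean_over_loci = mean_view,
            class = c("rarefaction_curve", class(out)))
}
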