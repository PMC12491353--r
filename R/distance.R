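#' Allele matrix under a distance convention
#'
#' Internal building block for the squared repeat-count distances: one row per
#' profile, one column per included panel position. The switches cover the
#' conventions the published tooling leaves unstated: whether DYS385 enters
#' (as two ascending-sorted positions), whether DYS389II is raw or
#' difference-encoded, and whether microvariants are rounded first.
#'
#' @param tbl a `hap_tbl`.
#' @param panel optional [locus_panel()] override.
#' @param include_multi_copy include multi-copy loci (DYS385) as sorted
#'   positional columns.
#' @param dys389ii `"raw"` or `"encoded"`.
#' @param round_microvariants round alleles to integers before differencing.
#' @return numeric matrix with rownames from `sample_id`.
#' @keywords internal
allele_matrix <- function(tbl, panel = NULL, include_multi_copy = TRUE,
                          dys389ii = c("raw", "encoded"),
                          round_microvariants = FALSE) {
  panel <- hap_panel(tbl, panel)
  dys389ii <- match.arg(dys389ii)
  tbl <- encode_dys389ii(tbl, if (dys389ii == "raw") "decode" else "encode")
  cols <- panel_columns(panel)
  if (!include_multi_copy) {
    cols <- cols[!(column_locus(panel, cols) %in% panel$multi_copy)]
  }
  m <- as.matrix(as.data.frame(tbl)[, cols, drop = FALSE])
  if (round_microvariants) m <- round_half_away(m)
  rownames(m) <- tbl$sample_id
  m
}

#' Squared repeat-count distance between two profiles
#'
#' Sum over included loci of the squared allele difference; multi-copy loci
#' contribute both positions after ascending sort of each pair. Loci missing
#' in either profile contribute 0 (pairwise deletion).
#'
#' @param a,b single-row `hap_tbl`s (or rows of the same table).
#' @inheritParams allele_matrix
#' @return non-negative scalar.
#' @export
haplotype_distance <- function(a, b, panel = NULL, include_multi_copy = TRUE,
                               dys389ii = "raw", round_microvariants = FALSE) {
  panel <- hap_panel(a, panel)
  ma <- allele_matrix(a, panel, include_multi_copy, dys389ii, round_microvariants)
  mb <- allele_matrix(b, panel, include_multi_copy, dys389ii, round_microvariants)
  if (ncol(ma) == 0) abort("empty locus subset")
  d <- (ma[1, ] - mb[1, ])^2
  sum(d, na.rm = TRUE)
}

#' Individual-level squared-distance matrix
#'
#' @inheritParams allele_matrix
#' @return symmetric matrix of pairwise squared repeat-count distances with
#'   zero diagonal, labelled by sample id.
#' @export
str_distance_matrix <- function(tbl, panel = NULL, include_multi_copy = TRUE,
                                dys389ii = "raw", round_microvariants = FALSE) {
  m <- allele_matrix(tbl, panel, include_multi_copy, dys389ii, round_microvariants)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(ncol(m))) {
    dk <- outer(m[, k], m[, k], "-")^2
    dk[is.na(dk)] <- 0
    D <- D + dk
  }
  D
}

#' Average pairwise differences within and between populations
#'
#' For populations X and Y: `PiX` is the mean squared repeat-count distance
#' over all unordered within-population pairs, `PiXY` the mean over all
#' `nX * nY` cross pairs, and the corrected between-population distance is
#' `PiXY - (PiX + PiY)/2`. Populations of size 1 get `NA` within averages
#' (and `NA` corrected entries).
#'
#' @inheritParams allele_matrix
#' @return object of class `pairwise_diff`: list with `pi_x` (tibble),
#'   `pi_xy` and `corrected` (labelled matrices). `tidy()` gives a long view.
#' @export
pairwise_differences <- function(tbl, panel = NULL, include_multi_copy = TRUE,
                                 dys389ii = "raw", round_microvariants = FALSE) {
  panel <- hap_panel(tbl, panel)
  D <- str_distance_matrix(tbl, panel, include_multi_copy, dys389ii,
                           round_microvariants)
  pops <- unique(tbl$population)
  idx <- lapply(pops, function(p) which(tbl$population == p))
  names(idx) <- pops
  pi_x <- vapply(idx, function(i) {
    n <- length(i)
    if (n < 2) return(NA_real_)
    sum(D[i, i][upper.tri(D[i, i])]) / (n * (n - 1) / 2)
  }, numeric(1))
  P <- length(pops)
  pi_xy <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (a in seq_len(P)) {
    pi_xy[a, a] <- pi_x[a]
    for (b in seq_len(P)[-seq_len(a)]) {
      pi_xy[a, b] <- pi_xy[b, a] <-
        mean(D[idx[[a]], idx[[b]], drop = FALSE])
    }
  }
  corrected <- pi_xy - outer(pi_x, pi_x, "+") / 2
  diag(corrected) <- ifelse(is.na(pi_x), NA_real_, 0)
  structure(list(
    pi_x = tibble(population = pops, n = lengths(idx), pi_x = unname(pi_x)),
    pi_xy = pi_xy, corrected = corrected
  ), class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat("<pairwise_diff> within-population averages:\n")
  print(x$pi_x)
  invisible(x)
}

#' Long view of a pairwise-difference result
#' @param x a `pairwise_diff`.
#' @param ... unused.
#' @return tibble with `pop_a`, `pop_b`, `pi_xy`, `corrected` for all
#'   unordered pairs.
#' @export
tidy.pairwise_diff <- function(x, ...) {
  pops <- rownames(x$pi_xy)
  pairs <- which(upper.tri(x$pi_xy), arr.ind = TRUE)
  tibble(
    pop_a = pops[pairs[, 1]], pop_b = pops[pairs[, 2]],
    pi_xy = x$pi_xy[pairs], corrected = x$corrected[pairs]
  )
}

# two-level AMOVA from a precomputed squared-distance matrix and grouping
amova_from_dist <- function(D, groups) {
  check_square_sym(D)
  groups <- as.character(groups)
  pops <- unique(groups)
  P <- length(pops)
  N <- nrow(D)
  np <- vapply(pops, function(p) sum(groups == p), numeric(1))
  if (any(np < 2)) abort("each population needs n >= 2 for AMOVA")
  ssd_total <- sum(D[upper.tri(D)]) / N
  ssd_within <- sum(vapply(pops, function(p) {
    i <- which(groups == p)
    sum(D[i, i][upper.tri(D[i, i])]) / length(i)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1
  df_within <- N - P
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n_c <- (N - sum(np^2) / N) / (P - 1)
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n_c
  denom <- sigma_a + sigma_w
  degenerate <- denom <= 0
  rst <- if (degenerate) 0 else sigma_a / denom
  structure(list(
    SSD_total = ssd_total, SSD_within = ssd_within, SSD_among = ssd_among,
    df_among = df_among, df_within = df_within,
    sigma_a = sigma_a, sigma_w = sigma_w, n_c = n_c,
    rst = rst, degenerate = degenerate, n = np
  ), class = "amova_result")
}

#' Two-level AMOVA and R_ST for a pair of populations
#'
#' Variance components from the squared repeat-count distances: with
#' `N = nA + nB`, `SSD_total = sum_{i<j} d_ij / N`,
#' `SSD_within = sum_p sum_{i<j in p} d_ij / n_p`, mean squares on `P - 1`
#' and `N - P` degrees of freedom, `n_c = (N - sum n_p^2 / N)/(P - 1)`,
#' `sigma2_w = MS_within`, `sigma2_a = (MS_among - MS_within)/n_c` and
#' `R_ST = sigma2_a / (sigma2_a + sigma2_w)`. Negative values are reported as
#' computed, never clamped; a zero total variance yields `R_ST = 0` with the
#' `degenerate` flag set.
#'
#' @inheritParams allele_matrix
#' @param pop_a,pop_b population labels present in `tbl`.
#' @return an `amova_result`; see [glance.amova_result()].
#' @export
amova_pair <- function(tbl, pop_a, pop_b, panel = NULL,
                       include_multi_copy = TRUE, dys389ii = "raw",
                       round_microvariants = FALSE) {
  sub <- tbl[tbl$population %in% c(pop_a, pop_b), , drop = FALSE]
  D <- str_distance_matrix(sub, hap_panel(tbl, panel), include_multi_copy,
                           dys389ii, round_microvariants)
  amova_from_dist(D, sub$population)
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("<amova> R_ST = %.5f (sigma_a = %.4f, sigma_w = %.4f)%s\n",
              x$rst, x$sigma_a, x$sigma_w,
              if (x$degenerate) " [degenerate: zero total variance]" else ""))
  invisible(x)
}

#' One-row AMOVA summary
#' @param x an `amova_result`.
#' @param ... unused.
#' @export
glance.amova_result <- function(x, ...) {
  tibble(
    SSD_total = x$SSD_total, SSD_within = x$SSD_within, SSD_among = x$SSD_among,
    df_among = x$df_among, df_within = x$df_within, n_c = x$n_c,
    sigma_a = x$sigma_a, sigma_w = x$sigma_w, rst = x$rst,
    degenerate = x$degenerate
  )
}

#' Pairwise R_ST matrix over populations
#'
#' Runs [amova_pair()] for every unordered population pair.
#'
#' @inheritParams allele_matrix
#' @return symmetric matrix of pairwise R_ST values (zero diagonal), labelled
#'   by population; negative entries are kept as computed.
#' @export
rst_matrix <- function(tbl, panel = NULL, include_multi_copy = TRUE,
                       dys389ii = "raw", round_microvariants = FALSE) {
  panel <- hap_panel(tbl, panel)
  pops <- unique(tbl$population)
  if (length(pops) < 2) abort("R_ST matrix needs at least two populations")
  D <- str_distance_matrix(tbl, panel, include_multi_copy, dys389ii,
                           round_microvariants)
  R <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) {
    for (b in seq_along(pops)[-seq_len(a)]) {
      i <- which(tbl$population %in% pops[c(a, b)])
      R[a, b] <- R[b, a] <- amova_from_dist(D[i, i], tbl$population[i])$rst
    }
  }
  R
}
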