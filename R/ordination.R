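prep_dist <- function(D) {
  check_square_sym(D)
  if (any(D < 0)) {
    inform("negative distance entries floored at 0 before ordination")
    D[D < 0] <- 0
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("L", seq_len(nrow(D)))
  }
  D
}

# deterministic sign convention: first nonzero coordinate of each axis > 0
fix_signs <- function(X) {
  for (j in seq_len(ncol(X))) {
    nz <- which(abs(X[, j]) > 1e-12)
    if (length(nz) && X[nz[1], j] < 0) X[, j] <- -X[, j]
  }
  X
}

# Kruskal stress-1 (in percent) of a configuration against dissimilarities,
# with the monotone fit obtained by isotonic regression on the rank order
stress1_pct <- function(D, X) {
  lt <- lower.tri(D)
  diss <- D[lt]
  d <- as.matrix(stats::dist(X))[lt]
  ord <- order(diss, d)
  fit <- stats::isoreg(d[ord])$yf
  dhat <- numeric(length(d))
  dhat[ord] <- fit
  100 * sqrt(sum((dhat - d)^2) / sum(d^2))
}

new_mds <- function(points, stress, k, method, converged, iterations) {
  structure(list(points = points, stress = stress, k = k, method = method,
                 converged = converged, iterations = iterations),
            class = "ystr_mds")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared-distance matrix
#' `-1/2 J D^2 J`; coordinates come from the top `k` non-negative
#' eigenvalues. Euclidean-embeddable distances are recovered exactly at the
#' embedding dimension. Axes follow a deterministic sign convention (first
#' nonzero coordinate positive) and are centered.
#'
#' @param D symmetric distance matrix (negative entries are floored at 0
#'   with a message, as can arise with R_ST input).
#' @param k target dimension, `1 <= k < nrow(D)`; silently reduced (with a
#'   warning) if fewer positive eigenvalues exist.
#' @return an object of class `ystr_mds` with fields `points` (labels x k),
#'   `stress` (Kruskal stress-1, percent), `k`, `converged`, `iterations`.
#' @export
classical_mds <- function(D, k = 2) {
  D <- prep_dist(D)
  if (k < 1 || k >= nrow(D)) abort("k must satisfy 1 <= k < number of labels")
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  pos <- sum(fit$eig > 1e-10)
  if (pos < k) {
    warn(sprintf("only %d positive eigenvalues; k reduced from %d", pos, k))
    k <- max(pos, 1L)
  }
  X <- fit$points[, seq_len(k), drop = FALSE]
  X <- fix_signs(scale(X, center = TRUE, scale = FALSE))
  attr(X, "scaled:center") <- NULL
  colnames(X) <- paste0("dim", seq_len(k))
  new_mds(X, stress1_pct(D, X), k, "classical", TRUE, 0L)
}

#' Nonmetric (Kruskal) multidimensional scaling
#'
#' Iterative stress-1 minimization with monotone regression on the
#' dissimilarity ranks (via [MASS::isoMDS()]), initialized from the classical
#' solution by default so the fit is deterministic. Stress is reported
#' times 100 (percent-style).
#'
#' @inheritParams classical_mds
#' @param init optional starting configuration (labels x k matrix); default
#'   the classical solution.
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @param seed optional seed used only when `init = "random"`.
#' @return an `ystr_mds`; `converged` is `FALSE` if the final stress exceeds
#'   the stress of the initial configuration.
#' @export
nonmetric_mds <- function(D, k = 2, init = NULL, max_iter = 100, tol = 1e-4,
                          seed = NULL) {
  D <- prep_dist(D)
  if (k < 1 || k >= nrow(D)) abort("k must satisfy 1 <= k < number of labels")
  if (is.character(init) && identical(init, "random")) {
    if (!is.null(seed)) set.seed(seed)
    init <- matrix(stats::rnorm(nrow(D) * k), ncol = k)
    rownames(init) <- rownames(D)
  }
  if (is.null(init)) init <- classical_mds(D, k)$points
  # isoMDS requires positive off-diagonal dissimilarities
  Dp <- D
  off <- Dp[lower.tri(Dp)]
  if (any(off <= 0)) {
    eps <- if (any(off > 0)) min(off[off > 0]) / 100 else 1e-6
    inform("zero dissimilarities replaced by a small positive value for the nonmetric fit")
    Dp[Dp <= 0] <- eps
    diag(Dp) <- 0
  }
  init_stress <- stress1_pct(D, init)
  fit <- MASS::isoMDS(stats::as.dist(Dp), y = init, k = k, maxit = max_iter,
                      tol = tol, trace = FALSE)
  X <- fix_signs(scale(fit$points, center = TRUE, scale = FALSE))
  attr(X, "scaled:center") <- NULL
  colnames(X) <- paste0("dim", seq_len(k))
  rownames(X) <- rownames(D)
  new_mds(X, fit$stress, k, "nonmetric",
          fit$stress <= init_stress + 1e-8, NA_integer_)
}

#' @export
print.ystr_mds <- function(x, ...) {
  cat(sprintf("<ystr_mds> %s, k = %d, stress-1 = %.4f%%\n",
              x$method, x$k, x$stress))
  invisible(x)
}

#' Tidy MDS coordinates
#' @param x an `ystr_mds`.
#' @param ... unused.
#' @return tibble with `label` and one column per dimension.
#' @export
tidy.ystr_mds <- function(x, ...) {
  bind_cols(tibble(label = rownames(x$points)), as_tibble(x$points))
}

#' One-row MDS summary
#' @inheritParams tidy.ystr_mds
#' @export
glance.ystr_mds <- function(x, ...) {
  tibble(method = x$method, k = x$k, stress = x$stress,
         converged = x$converged, iterations = x$iterations)
}

#' Agglomerative clustering dendrogram (UPGMA by default)
#'
#' Heights are exposed as ultrametric node depths (half the merge distance
#' for average linkage), so two labels at distance `d` merge at height
#' `d / 2`.
#'
#' @param D symmetric distance matrix.
#' @param linkage `"average"` (UPGMA), `"complete"` or `"ward"`.
#' @return an object of class `ystr_dendrogram` wrapping the
#'   [stats::hclust()] fit, with `heights`, `labels` and a `newick` string.
#' @export
upgma <- function(D, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  D <- prep_dist(D)
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[linkage]
  hc <- stats::hclust(stats::as.dist(D), method = method)
  phy <- ape::as.phylo(hc)
  structure(list(
    hclust = hc, labels = hc$labels, heights = hc$height / 2,
    linkage = linkage, newick = ape::write.tree(phy)
  ), class = "ystr_dendrogram")
}

#' @export
print.ystr_dendrogram <- function(x, ...) {
  cat(sprintf("<ystr_dendrogram> %s linkage, %d leaves\n",
              x$linkage, length(x$labels)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#' @param dend an `ystr_dendrogram`.
#' @param k number of clusters.
#' @return tibble with `label` and `cluster`.
#' @export
cut_dendrogram <- function(dend, k) {
  cl <- stats::cutree(dend$hclust, k = k)
  tibble(label = names(cl), cluster = unname(cl))
}

#' Write a dendrogram to a Newick file
#' @param dend an `ystr_dendrogram`.
#' @param path output path.
#' @export
write_newick <- function(dend, path) {
  writeLines(dend$newick, path)
  invisible(path)
}
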