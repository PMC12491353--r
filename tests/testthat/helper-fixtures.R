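# fixtures built in code: a modal Yfiler haplotype and tables derived from it

modal_row <- function(sample = "S1", population = "Yemen") {
  data.frame(
    sample_id = sample, population = population,
    DYS19 = 14, DYS389I = 13, DYS389II = 29, DYS390 = 23, DYS391 = 10,
    DYS392 = 11, DYS393 = 12, DYS385a = 13, DYS385b = 17, DYS438 = 10,
    DYS439 = 11, DYS437 = 14, DYS448 = 19, DYS456 = 15, DYS458 = 17,
    DYS635 = 21, YGATAH4 = 11,
    stringsAsFactors = FALSE
  )
}

# table whose haplotype multiplicities are exactly `counts` (distinct
# haplotypes separated at DYS19, far apart so they never collide)
table_from_counts <- function(counts, population = "Yemen") {
  rows <- list()
  s <- 0
  for (i in seq_along(counts)) {
    for (r in seq_len(counts[i])) {
      s <- s + 1
      row <- modal_row(sprintf("S%03d", s), population)
      row$DYS19 <- 14 + i
      rows[[s]] <- row
    }
  }
  as_hap_tbl(do.call(rbind, rows))
}

# single-locus panel helpers for hand-checkable distance examples
one_locus_panel <- function() locus_panel("L1")

one_locus_table <- function(values, population) {
  df <- data.frame(
    sample_id = sprintf("S%02d", seq_along(values)),
    population = population, L1 = values,
    stringsAsFactors = FALSE
  )
  as_hap_tbl(df, panel = one_locus_panel())
}

# Monte-Carlo rarefaction oracle: resample g gene copies without replacement
mc_distinct <- function(counts, g, reps, seed = 1) {
  set.seed(seed)
  pool <- rep(seq_along(counts), counts)
  draws <- vapply(seq_len(reps), function(i) {
    length(unique(sample(pool, g)))
  }, numeric(1))
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}

mc_private <- function(count_matrix, g, reps, seed = 1) {
  set.seed(seed)
  pools <- lapply(seq_len(ncol(count_matrix)),
                  function(j) rep(seq_len(nrow(count_matrix)), count_matrix[, j]))
  draws <- matrix(0, reps, ncol(count_matrix))
  for (i in seq_len(reps)) {
    subs <- lapply(pools, function(p) unique(sample(p, g)))
    for (j in seq_len(ncol(count_matrix))) {
      others <- unique(unlist(subs[-j]))
      draws[i, j] <- sum(!(subs[[j]] %in% others))
    }
  }
  list(mean = colMeans(draws), se = apply(draws, 2, stats::sd) / sqrt(reps))
}

# exhaustive Steiner oracle: minimal MST length over observed haplotypes
# plus any subset (size <= max_extra) of integer lattice points in the
# bounding box
steiner_min_length <- function(h, max_extra = 2) {
  grids <- lapply(seq_len(ncol(h)), function(k) {
    seq(min(h[, k]), max(h[, k]))
  })
  lattice <- as.matrix(expand.grid(grids))
  keys <- apply(h, 1, paste, collapse = "|")
  cand <- lattice[!(apply(lattice, 1, paste, collapse = "|") %in% keys), ,
                  drop = FALSE]
  best <- ystrpop:::mst_length(ystrpop:::step_dist_matrix(h))
  for (m in 0:min(max_extra, nrow(cand))) {
    if (m == 0) next
    combos <- utils::combn(nrow(cand), m)
    for (cc in seq_len(ncol(combos))) {
      hx <- rbind(h, cand[combos[, cc], , drop = FALSE])
      best <- min(best, ystrpop:::mst_length(ystrpop:::step_dist_matrix(hx)))
    }
  }
  best
}

# exact maximum of mean sum-of-squares over the transportation polytope
# (row sums 1, column sums I * pbar): a convex maximum sits at a vertex,
# and every vertex is the basic solution of a spanning tree of the
# bipartite row/column graph. Enumerates all spanning trees by brute force.
fst_max_oracle <- function(pbar, I) {
  K <- length(pbar)
  col_sum <- I * pbar
  edges <- expand.grid(row = seq_len(I), col = seq_len(K))
  ne <- nrow(edges)
  need <- I + K - 1
  best <- -Inf
  combos <- utils::combn(ne, need)
  for (ci in seq_len(ncol(combos))) {
    sel <- edges[combos[, ci], ]
    # solve tree flows by leaf elimination
    Q <- matrix(NA_real_, I, K)
    rs <- rep(1, I)
    cs <- col_sum
    act <- rep(TRUE, need)
    ok <- TRUE
    for (step in seq_len(need)) {
      deg_r <- tabulate(sel$row[act], I)
      deg_c <- tabulate(sel$col[act], K)
      leaf <- which(act & (deg_r[sel$row] == 1 | deg_c[sel$col] == 1))[1]
      if (is.na(leaf)) { ok <- FALSE; break }
      r <- sel$row[leaf]; c <- sel$col[leaf]
      v <- if (deg_r[r] == 1) rs[r] else cs[c]
      Q[r, c] <- v
      rs[r] <- rs[r] - v
      cs[c] <- cs[c] - v
      act[leaf] <- FALSE
    }
    if (!ok || any(abs(rs) > 1e-9) || any(abs(cs) > 1e-9)) next
    Q[is.na(Q)] <- 0
    if (any(Q < -1e-9)) next
    best <- max(best, mean(rowSums(Q^2)))
  }
  denom <- 1 - sum(pbar^2)
  ((best) - sum(pbar^2)) / denom
}
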