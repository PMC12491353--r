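# --- Q-matrix ancestry variability (F_ST / F_ST^max) ----------------------

q_matrix_of <- function(q, q_cols = NULL) {
  if (is.matrix(q)) return(q)
  q <- as.data.frame(q)
  q_cols <- q_cols %||% names(q)[vapply(q, is.numeric, logical(1))]
  as.matrix(q[, q_cols, drop = FALSE])
}

check_simplex_rows <- function(Q, tol = 1e-6) {
  if (any(Q < -1e-12)) abort("Q entries must be non-negative")
  rs <- rowSums(Q)
  if (any(abs(rs - 1) > tol)) abort("Q rows must sum to 1")
  Q / rs
}

#' F_ST of a membership-coefficient matrix
#'
#' Treating each individual's membership vector as an allele-frequency
#' vector: with column means `pbar_k`,
#' `F_ST = (mean_i sum_k q_ik^2 - sum_k pbar_k^2) / (1 - sum_k pbar_k^2)`.
#' If all rows sit at a single vertex (denominator 0) the statistic is
#' defined as 0 and flagged via the `"degenerate"` attribute.
#'
#' @param q matrix or data frame of membership coefficients (rows on the
#'   simplex), `I >= 2` rows.
#' @param q_cols optional column selection when `q` is a data frame.
#' @return scalar F_ST in `[0, 1]`.
#' @export
fst_of_q <- function(q, q_cols = NULL) {
  Q <- check_simplex_rows(q_matrix_of(q, q_cols))
  if (nrow(Q) < 2) abort("F_ST of a Q matrix needs at least two rows")
  pbar <- colMeans(Q)
  denom <- 1 - sum(pbar^2)
  if (denom <= 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  (mean(rowSums(Q^2)) - sum(pbar^2)) / denom
}

# pour fractional remainder masses into m rows of capacity 1 in a given
# order; returns the achieved mean sum of squares contribution of those rows
pour_rows <- function(rem, m) {
  rows <- list()
  cur <- numeric(0)
  cap <- 1
  k <- 1
  while (k <= length(rem)) {
    take <- min(rem[k], cap)
    if (take > 1e-12) {
      cur <- c(cur, take)
      rem[k] <- rem[k] - take
      cap <- cap - take
    }
    if (cap <= 1e-12) {
      rows[[length(rows) + 1]] <- cur
      cur <- numeric(0)
      cap <- 1
    }
    if (rem[k] <= 1e-12) k <- k + 1
  }
  if (length(cur)) rows[[length(rows) + 1]] <- cur
  sum(vapply(rows, function(r) sum(r^2), numeric(1)))
}

#' Maximum F_ST attainable given the mean membership vector
#'
#' The maximum of [fst_of_q()] over all `I x K` row-stochastic matrices with
#' column means `pbar`, attained by concentrating rows on vertices:
#' `floor(I * pbar_k)` rows sit at vertex `k` and the remaining fractional
#' column masses are packed into as few mixed rows as possible (at most
#' `K - 1`). The packing that maximizes the sum of squares is found by
#' pouring the fractional masses in every order of the nonzero remainders
#' (falling back to the single descending order when there are more than 7).
#'
#' @param pbar mean membership vector (on the simplex).
#' @param I number of rows.
#' @return scalar `F_ST^max`; 0 (flagged degenerate) when `pbar` is a
#'   vertex.
#' @export
fst_max_of_q <- function(pbar, I) {
  pbar <- pbar / sum(pbar)
  denom <- 1 - sum(pbar^2)
  if (denom <= 1e-12) return(structure(0, degenerate = TRUE))
  cmass <- I * pbar
  fl <- floor(cmass + 1e-9)
  rem <- cmass - fl
  rem[rem < 1e-9] <- 0
  m <- round(sum(rem))
  ss_pure <- sum(fl)
  if (m == 0) {
    mean_ss <- ss_pure / I
  } else {
    nz <- rem[rem > 0]
    orders <- if (length(nz) <= 7) {
      perms(length(nz))
    } else {
      matrix(order(nz, decreasing = TRUE), nrow = 1)
    }
    best <- -Inf
    for (r in seq_len(nrow(orders))) {
      best <- max(best, pour_rows(nz[orders[r, ]], m))
    }
    mean_ss <- (ss_pure + best) / I
  }
  (mean_ss - sum(pbar^2)) / denom
}

perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' F_ST / F_ST^max variability ratio with bootstrap, per population
#'
#' For each population's block of Q-matrix rows, computes the point ratio
#' `F_ST / F_ST^max` (low values indicate homogeneous, non-admixed
#' membership; the normalization uses the block's own column means) and a
#' bootstrap sample of the ratio obtained by resampling rows with
#' replacement within the population.
#'
#' @param q data frame with a population column and K numeric membership
#'   columns (rows on the simplex), or a matrix plus `population` vector.
#' @param population column name (default `"population"`) or a vector of
#'   labels when `q` is a matrix.
#' @param q_cols optional selection of the membership columns.
#' @param B bootstrap replicates (default 100; `B = 0` gives the point
#'   estimate only).
#' @param seed RNG seed for reproducible replicates.
#' @return tibble of class `fstruct_result` with `population`, `n`, `fst`,
#'   `fst_max`, `ratio` and a `boot` list-column of replicate ratios.
#'   Populations with a single row are skipped with a warning.
#' @export
fstruct <- function(q, population = "population", q_cols = NULL, B = 100,
                    seed = NULL) {
  if (is.matrix(q)) {
    pops <- as.character(population)
    Q <- q
  } else {
    pops <- as.character(q[[population]])
    q_cols <- q_cols %||% setdiff(names(q)[vapply(q, is.numeric, logical(1))],
                                  population)
    Q <- as.matrix(as.data.frame(q)[, q_cols, drop = FALSE])
  }
  Q <- check_simplex_rows(Q)
  if (!is.null(seed)) set.seed(seed)
  upops <- unique(pops)
  small <- upops[vapply(upops, function(p) sum(pops == p) < 2, logical(1))]
  if (length(small)) {
    warn(paste0("population(s) with a single row skipped: ",
                paste(small, collapse = ", ")))
    upops <- setdiff(upops, small)
  }
  ratio_of <- function(M) {
    f <- fst_of_q(M)
    fm <- fst_max_of_q(colMeans(M), nrow(M))
    if (isTRUE(attr(fm, "degenerate")) || fm <= 0) 0 else as.numeric(f) / as.numeric(fm)
  }
  rows <- purrr::map_dfr(upops, function(p) {
    M <- Q[pops == p, , drop = FALSE]
    f <- as.numeric(fst_of_q(M))
    fm <- as.numeric(fst_max_of_q(colMeans(M), nrow(M)))
    boot <- if (B > 0) {
      vapply(seq_len(B), function(b) {
        ratio_of(M[sample(nrow(M), replace = TRUE), , drop = FALSE])
      }, numeric(1))
    } else {
      numeric(0)
    }
    tibble(population = p, n = nrow(M), fst = f, fst_max = fm,
           ratio = if (fm > 0) f / fm else 0, boot = list(boot))
  })
  structure(rows, B = B, class = c("fstruct_result", class(rows)))
}

#' Long table of bootstrap replicates
#' @param x an `fstruct_result`.
#' @param ... unused.
#' @return tibble with `population`, `replicate`, `ratio`.
#' @export
tidy.fstruct_result <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    b <- x$boot[[i]]
    if (!length(b)) return(tibble(population = character(),
                                  replicate = integer(), ratio = numeric()))
    tibble(population = x$population[i], replicate = seq_along(b), ratio = b)
  })
}

#' Kruskal-Wallis comparison of the bootstrap ratio distributions
#' @inheritParams tidy.fstruct_result
#' @return one-row tibble with the H statistic, df and p-value.
#' @export
glance.fstruct_result <- function(x, ...) {
  long <- tidy(x)
  kruskal_wallis(long$ratio, long$population)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with `groups - 1` degrees of freedom and a
#' chi-square tail p-value (via [stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups).
#' @return one-row tibble `statistic`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  if (length(unique(values)) == 1) {
    return(tibble(statistic = 0, df = nlevels(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}

#' Read a Q matrix from delimited text
#'
#' Plain CSV/TSV with optional `individual` and `population` label columns
#' followed by the K membership columns (CLUMPP/STRUCTURE-style exports
#' reduced to a rectangular table).
#'
#' @param path file path.
#' @param delim delimiter; `NULL` autodetects tab vs comma.
#' @return tibble with `individual`, `population` (if present) and `Q1..QK`.
#' @export
read_qmatrix <- function(path, delim = NULL) {
  header <- readLines(path, n = 1L)
  delim <- delim %||% if (grepl("\t", header)) "\t" else ","
  q <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  num <- names(q)[vapply(q, is.numeric, logical(1))]
  names(q)[names(q) %in% num] <- paste0("Q", seq_along(num))
  q
}

#' Haplogroup composition of a sample
#'
#' Tallies haplogroup assignments and reports each group's share of the
#' sample. `pct` is the exact percentage; `pct_label` is the conventional
#' two-decimal display, which truncates rather than rounds (76 of 128 shows
#' as "59.37").
#'
#' @param x a data frame with a `haplogroup` column (e.g.
#'   [predict_haplogroup()] output), or a character vector of labels.
#' @return tibble with `haplogroup`, `n`, `pct`, `pct_label`, sorted by
#'   decreasing count.
#' @export
haplogroup_proportions <- function(x) {
  labels <- if (is.data.frame(x)) as.character(x$haplogroup) else as.character(x)
  tt <- sort(table(labels), decreasing = TRUE)
  pct <- 100 * as.vector(tt) / length(labels)
  tibble(
    haplogroup = names(tt), n = as.integer(tt), pct = pct,
    pct_label = sprintf("%.2f", floor(pct * 100) / 100)
  )
}

# --- naive-Bayes haplogroup prediction ------------------------------------

#' Fit a naive-Bayes haplogroup model from reference haplotypes
#'
#' Per-haplogroup, per-locus allele frequencies with additive pseudocount
#' smoothing: `P(a | g, l) = (count + alpha) / (n_gl + alpha * V_l)` where
#' `V_l` is the number of distinct alleles observed at locus `l` across all
#' haplogroups. Multi-copy loci contribute both copies as observations of
#' one pooled spectrum. Priors come from the reference label counts, or are
#' uniform on request.
#'
#' @param ref a `hap_tbl` (or plain data frame accepted by [as_hap_tbl()])
#'   with an additional `haplogroup` column.
#' @param alpha additive pseudocount (default 0.5, Jeffreys-style).
#' @param priors `"empirical"` or `"uniform"`.
#' @param panel optional [locus_panel()] override.
#' @return an object of class `haplogroup_model`.
#' @export
fit_haplogroup_model <- function(ref, alpha = 0.5,
                                 priors = c("empirical", "uniform"),
                                 panel = NULL) {
  priors <- match.arg(priors)
  if (!"haplogroup" %in% names(ref)) abort("`ref` needs a haplogroup column")
  panel <- hap_panel(ref, panel)
  labels <- sort(unique(as.character(ref$haplogroup)))
  cols <- panel_columns(panel)
  present <- cols[cols %in% names(ref)]
  dropped <- setdiff(cols, present)
  if (length(dropped)) {
    warn(paste0("loci absent from the reference dropped: ",
                paste(unique(column_locus(panel, dropped)), collapse = ", ")))
  }
  loci <- unique(column_locus(panel, present))
  tabs <- lapply(loci, function(l) {
    cc <- present[column_locus(panel, present) == l]
    vals <- as.vector(as.matrix(as.data.frame(ref)[, cc, drop = FALSE]))
    hg <- rep(as.character(ref$haplogroup), length(cc))
    keep <- !is.na(vals)
    vocab <- sort(unique(vals[keep]))
    counts <- matrix(0, length(vocab), length(labels),
                     dimnames = list(format(vocab, trim = TRUE), labels))
    for (g in labels) {
      v <- vals[keep & hg == g]
      counts[, g] <- as.integer(table(factor(format(v, trim = TRUE),
                                             levels = rownames(counts))))
    }
    list(vocab = vocab, counts = counts, n = colSums(counts))
  })
  names(tabs) <- loci
  pr <- if (priors == "uniform") {
    rep(1 / length(labels), length(labels))
  } else {
    as.vector(table(factor(ref$haplogroup, levels = labels))) /
      length(ref$haplogroup)
  }
  structure(list(labels = labels, priors = setNames(pr, labels),
                 loci = loci, tabs = tabs, alpha = alpha, panel = panel),
            class = "haplogroup_model")
}

#' @export
print.haplogroup_model <- function(x, ...) {
  cat(sprintf("<haplogroup_model> %d haplogroups, %d loci, alpha = %g\n",
              length(x$labels), length(x$loci), x$alpha))
  invisible(x)
}

# smoothed log-likelihood of one allele value under one haplogroup
log_lik_allele <- function(tab, value, g, alpha) {
  key <- format(value, trim = TRUE)
  cnt <- if (key %in% rownames(tab$counts)) tab$counts[key, g] else 0
  V <- length(tab$vocab) + !(key %in% rownames(tab$counts))
  log((cnt + alpha) / (tab$n[g] + alpha * V))
}

#' Predict haplogroups for haplotype profiles
#'
#' Naive-Bayes posterior `P(g | profile) ∝ prior(g) * prod_l P(a_l | g)`
#' in log space; missing loci are skipped; ties break alphabetically. A
#' profile missing every modelled locus gets the uniform posterior and is
#' flagged.
#'
#' @param tbl a `hap_tbl`.
#' @param model a [fit_haplogroup_model()] fit.
#' @return tibble with `sample_id`, `haplogroup` (MAP label), `posterior`
#'   (its probability), `degenerate` flag, and one `p_<label>` column per
#'   haplogroup; posterior rows sum to 1.
#' @export
predict_haplogroup <- function(tbl, model) {
  panel <- model$panel
  cols <- panel_columns(panel)
  out <- purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    ll <- log(model$priors)
    used <- 0L
    for (l in model$loci) {
      cc <- cols[column_locus(panel, cols) == l]
      cc <- cc[cc %in% names(tbl)]
      for (cn in cc) {
        v <- tbl[[cn]][i]
        if (is.na(v)) next
        used <- used + 1L
        ll <- ll + vapply(model$labels,
                          function(g) log_lik_allele(model$tabs[[l]], v, g,
                                                     model$alpha),
                          numeric(1))
      }
    }
    degenerate <- used == 0L
    if (degenerate) ll <- rep(0, length(model$labels))
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    map <- model$labels[order(-post, model$labels)][1]
    row <- tibble(sample_id = tbl$sample_id[i], haplogroup = map,
                  posterior = max(post), degenerate = degenerate)
    bind_cols(row, as_tibble(as.list(setNames(post, paste0("p_", model$labels)))))
  })
  out
}
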