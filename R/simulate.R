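# --- stepwise-mutation-model haplotype simulator --------------------------

#' Default lineage configuration of the simulator
#'
#' Three founder lineages with the proportions observed in Arabian-peninsula
#' Y-STR surveys: two dominant founder lineages (59% and 21%) plus a
#' residual class, with the dominant lineage carrying a `.2` partial-repeat
#' allele at DYS458. Founder haplotypes start from a plausible modal Yfiler
#' haplotype and are separated by multi-locus repeat offsets; they are
#' configuration constants, not biological claims.
#'
#' @return tibble with `haplogroup`, `proportion` and a `founder` list-column
#'   of named allele vectors (panel columns).
#' @export
default_lineages <- function() {
  base <- c(
    DYS19 = 14, DYS389I = 13, DYS389II = 29, DYS390 = 23, DYS391 = 10,
    DYS392 = 11, DYS393 = 12, DYS385a = 13, DYS385b = 17, DYS438 = 10,
    DYS439 = 11, DYS437 = 14, DYS448 = 19, DYS456 = 15, DYS458 = 17,
    DYS635 = 21, YGATAH4 = 11
  )
  shift <- function(v, loci, by) { v[loci] <- v[loci] + by; v }
  f1 <- base
  f2 <- shift(base, c("DYS19", "DYS390", "DYS392", "DYS438", "DYS448",
                      "DYS458", "DYS635"), 3)
  f3 <- shift(base, c("DYS389I", "DYS391", "DYS393", "DYS439", "DYS456",
                      "YGATAH4", "DYS385a"), -3)
  tibble(
    haplogroup = c("J1a", "E1b1b", "J2a1"),
    proportion = c(0.59, 0.21, 0.20),
    founder = list(f1, f2, f3)
  )
}

#' Simulate Y-STR haplotype tables under the stepwise mutation model
#'
#' Each individual draws a founder lineage by proportion, copies its founder
#' haplotype, and accumulates symmetric single-step mutations: over a
#' per-individual depth of generations (geometric with the configured mean,
#' producing star-like haplotype clusters), each locus mutates with
#' probability `mu` per generation by +1 or -1 repeat. An optional
#' microvariant rule adds a partial-repeat offset (e.g. +0.2 at DYS458) to
#' configured lineages. Multiple populations first drift apart: each
#' population's founder copies receive `divergence_depth` generations of
#' their own stepwise mutations before individuals are drawn.
#'
#' @param populations named integer vector of population sizes
#'   (default `c(Yemen = 128)`).
#' @param lineages tibble as [default_lineages()] (`haplogroup`,
#'   `proportion` summing to 1, `founder` named vectors).
#' @param mu mutation probability per locus per generation, in (0, 0.1].
#' @param depth mean generational depth per individual (geometric draw), or
#'   an exact depth when `depth_model = "fixed"`.
#' @param depth_model `"geometric"` or `"fixed"`.
#' @param microvariants tibble with `locus`, `lineage`, `prob`, `offset`
#'   (default: all `J1a` chromosomes gain +0.2 at DYS458).
#' @param divergence_depth generations of founder drift separating the
#'   populations (0 = identical founder sets).
#' @param seed RNG seed; the same seed and configuration reproduce the table
#'   exactly.
#' @param panel a [locus_panel()].
#' @return list of class `ystr_sim`: `haplotypes` (a `hap_tbl`) and `truth`
#'   (tibble `sample_id`, `population`, `lineage`).
#' @export
simulate_haplotypes <- function(populations = c(Yemen = 128),
                                lineages = default_lineages(),
                                mu = 0.002, depth = 200,
                                depth_model = c("geometric", "fixed"),
                                microvariants = tibble(
                                  locus = "DYS458", lineage = "J1a",
                                  prob = 1, offset = 0.2
                                ),
                                divergence_depth = 0,
                                seed = NULL,
                                panel = yfiler_panel()) {
  depth_model <- match.arg(depth_model)
  if (abs(sum(lineages$proportion) - 1) > 1e-9) {
    abort("lineage proportions must sum to 1")
  }
  if (mu <= 0 || mu > 0.1) abort("mu must lie in (0, 0.1]")
  if (any(populations < 1)) abort("population sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cols <- panel_columns(panel)
  L <- length(cols)

  smm_steps <- function(mat, gens, mu) {
    if (gens[1] == 0 && length(unique(gens)) == 1) return(mat)
    m <- matrix(stats::rbinom(length(mat), rep(gens, ncol(mat)), mu),
                nrow = nrow(mat))
    net <- 2 * matrix(stats::rbinom(length(m), as.vector(m), 0.5),
                      nrow = nrow(m)) - m
    mat + net
  }

  rows <- list()
  truth <- list()
  for (p in seq_along(populations)) {
    pname <- names(populations)[p] %||% paste0("POP", p)
    n <- populations[[p]]
    founders <- do.call(rbind, lapply(lineages$founder, function(f) f[cols]))
    founders <- smm_steps(founders, rep(divergence_depth, nrow(founders)), mu)
    lin <- sample(seq_len(nrow(lineages)), n, replace = TRUE,
                  prob = lineages$proportion)
    gens <- if (depth_model == "geometric") {
      stats::rgeom(n, prob = 1 / (1 + depth))
    } else {
      rep(as.integer(depth), n)
    }
    haps <- founders[lin, , drop = FALSE]
    haps <- smm_steps(haps, gens, mu)
    # multi-copy pairs sorted ascending after mutation
    for (l in panel$multi_copy) {
      ab <- haps[, paste0(l, c("a", "b")), drop = FALSE]
      haps[, paste0(l, "a")] <- pmin(ab[, 1], ab[, 2])
      haps[, paste0(l, "b")] <- pmax(ab[, 1], ab[, 2])
    }
    if (!is.null(microvariants) && nrow(microvariants)) {
      for (r in seq_len(nrow(microvariants))) {
        mv <- microvariants[r, ]
        tgt <- which(lineages$haplogroup[lin] == mv$lineage &
                       stats::runif(n) < mv$prob)
        cc <- if (mv$locus %in% cols) mv$locus else paste0(mv$locus, "a")
        haps[tgt, cc] <- haps[tgt, cc] + mv$offset
      }
    }
    ids <- sprintf("%s_%03d", pname, seq_len(n))
    rows[[p]] <- bind_cols(tibble(sample_id = ids, population = pname),
                           as_tibble(haps))
    truth[[p]] <- tibble(sample_id = ids, population = pname,
                         lineage = lineages$haplogroup[lin])
  }
  tbl <- new_hap_tbl(bind_rows(rows), panel)
  structure(list(haplotypes = tbl, truth = bind_rows(truth)),
            class = "ystr_sim")
}

#' @export
print.ystr_sim <- function(x, ...) {
  cat(sprintf("<ystr_sim> %d individuals, %d population(s)\n",
              nrow(x$haplotypes), length(unique(x$haplotypes$population))))
  invisible(x)
}

#' Simulate a STRUCTURE-style Q matrix with Dirichlet rows
#'
#' Rows are drawn i.i.d. Dirichlet(alpha) within each population. Small
#' `alpha` concentrates rows near vertices (non-admixed-looking, ratio near
#' 1); large `alpha` makes rows nearly identical (ratio near 0).
#'
#' @param n named integer vector of rows per population.
#' @param K number of clusters.
#' @param alpha Dirichlet concentration: scalar, length-K vector, or a list
#'   with one entry per population.
#' @param seed RNG seed.
#' @return tibble with `individual`, `population` and `Q1..QK` columns.
#' @export
simulate_q <- function(n, K, alpha = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.list(alpha)) alpha <- rep(list(alpha), length(n))
  if (any(unlist(alpha) <= 0)) abort("alpha must be positive")
  out <- purrr::map_dfr(seq_along(n), function(p) {
    a <- alpha[[p]]
    if (length(a) == 1) a <- rep(a, K)
    g <- matrix(stats::rgamma(n[[p]] * K, shape = rep(a, each = n[[p]])),
                nrow = n[[p]])
    Q <- g / rowSums(g)
    colnames(Q) <- paste0("Q", seq_len(K))
    pname <- names(n)[p] %||% paste0("POP", p)
    bind_cols(tibble(individual = sprintf("%s_%03d", pname, seq_len(n[[p]])),
                     population = pname),
              as_tibble(Q))
  })
  out
}
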