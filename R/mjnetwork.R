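# --- median-joining networks for multistate STR haplotypes ----------------
#
# Haplotypes are integer repeat-count vectors; the mutational step distance
# between two haplotypes is the sum over loci of |a - b| (single-repeat
# steps), skipping loci missing in either. Median vectors are locus-wise
# (lower) medians of connected triples; they are added only while they lower
# the connection cost (minimum-spanning-tree length) of the node set.

#' Reduce a haplotype table to median-joining network input
#'
#' Applies the standard network preprocessing: constitutively duplicated loci
#' (DYS385 a/b) are excluded, intermediate (microvariant) alleles are rounded
#' to the nearest integer (half away from zero), missing calls stay missing
#' and are excluded locus-wise from distances and medians, and identical
#' reduced haplotypes are collapsed with their multiplicity.
#'
#' @param tbl a `hap_tbl`.
#' @param panel optional [locus_panel()] override.
#' @return list with `h` (integer haplotype matrix, rows sorted
#'   lexicographically), `mult` (multiplicities), `members` (list of sample
#'   ids per row) and `loci`.
#' @export
prepare_network_input <- function(tbl, panel = NULL) {
  panel <- hap_panel(tbl, panel)
  cols <- panel_columns(panel)
  keep <- cols[!(column_locus(panel, cols) %in% panel$multi_copy)]
  m <- as.matrix(as.data.frame(tbl)[, keep, drop = FALSE])
  m <- round_half_away(m)
  key <- apply(m, 1, function(r) paste(ifelse(is.na(r), "*", r), collapse = "|"))
  ord <- order(key)
  ukey <- unique(key[ord])
  rows <- match(ukey, key)
  h <- m[rows, , drop = FALSE]
  rownames(h) <- NULL
  list(
    h = h,
    mult = as.integer(table(key)[ukey]),
    members = lapply(ukey, function(k) tbl$sample_id[key == k]),
    loci = keep
  )
}

step_dist_matrix <- function(h) {
  n <- nrow(h)
  D <- matrix(0, n, n)
  for (k in seq_len(ncol(h))) {
    dk <- abs(outer(h[, k], h[, k], "-"))
    dk[is.na(dk)] <- 0
    D <- D + dk
  }
  D
}

mst_length <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  dmin <- D[1, ]
  total <- 0
  for (i in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(dmin[cand])]
    total <- total + dmin[j]
    in_tree[j] <- TRUE
    dmin <- pmin(dmin, D[j, ])
  }
  unname(total)
}

# epsilon-relaxed minimum spanning network: all edges whose weight does not
# exceed the grouped-Kruskal connection threshold of their endpoints + eps
msn_edge_list <- function(D, eps = 0) {
  n <- nrow(D)
  if (n < 2) return(matrix(integer(), 0, 2))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ut <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  thr <- matrix(Inf, n, n)
  for (uw in sort(unique(w))) {
    for (s in which(w == uw)) {
      a <- find(ut[s, 1]); b <- find(ut[s, 2])
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_len(n), find, integer(1))
    newly <- outer(comp, comp, "==") & !is.finite(thr)
    thr[newly] <- uw
  }
  sel <- which(upper.tri(D) & D <= thr + eps + 1e-9, arr.ind = TRUE)
  sel
}

# lower median of the non-missing values of a triple (majority value when two
# of three agree; deterministic lower value on two-way disagreement)
triple_median <- function(vals) {
  v <- sort(vals[!is.na(vals)])
  if (!length(v)) return(NA_real_)
  v[ceiling(length(v) / 2)]
}

median_candidates <- function(h, edges) {
  n <- nrow(h)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- character()
  out <- list()
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    prs <- utils::combn(sort(nb), 2)
    for (c2 in seq_len(ncol(prs))) {
      tri <- h[c(v, prs[1, c2], prs[2, c2]), , drop = FALSE]
      med <- apply(tri, 2, triple_median)
      key <- paste(ifelse(is.na(med), "*", med), collapse = "|")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- med
      }
    }
  }
  out
}

hap_key <- function(h) {
  apply(h, 1, function(r) paste(ifelse(is.na(r), "*", r), collapse = "|"))
}

#' Minimum spanning network over haplotypes
#'
#' The epsilon-relaxed minimum spanning network: the union of all minimum
#' spanning trees, plus (for `epsilon > 0`) every edge within `epsilon`
#' mutational steps of the weight at which its endpoints first become
#' connected. `epsilon` large enough yields the complete graph.
#'
#' @param h integer haplotype matrix (one row per distinct haplotype).
#' @param epsilon relaxation parameter (default 0).
#' @return tibble of edges with `from`, `to` (row indices) and `steps`.
#' @export
msn <- function(h, epsilon = 0) {
  if (nrow(h) < 2) abort("need at least two distinct haplotypes")
  D <- step_dist_matrix(h)
  e <- msn_edge_list(D, epsilon)
  tibble(from = e[, 1], to = e[, 2], steps = D[e])
}

#' Median-joining network
#'
#' Iteratively augments the haplotype set with median vectors of connected
#' triples of the current minimum spanning network, keeping a median only if
#' it lowers the connection cost (MST length) of the node set; with
#' `epsilon > 0` cost ties within `epsilon` are also admitted. Median nodes
#' that no longer shorten any connection are pruned, and the final network is
#' the epsilon-relaxed minimum spanning network over the remaining nodes.
#' All tie-breaks are lexicographic on the haplotype vectors, so the result
#' is deterministic.
#'
#' @param x a `hap_tbl` (preprocessed via [prepare_network_input()]) or the
#'   list that function returns.
#' @param epsilon relaxation parameter (default 0, the usual setting).
#' @param max_medians hard cap on added median vectors (non-termination
#'   guard); exceeding it is an error.
#' @param panel optional [locus_panel()] override when `x` is a table.
#' @return an object of class `haplo_network`: `nodes` tibble (id, kind,
#'   size, haplotype key, members), `edges` tibble, `graph` (igraph),
#'   `total_cost` (MST length of the final node set) and
#'   `mst_cost_observed` (MST length over observed haplotypes alone).
#' @export
median_joining <- function(x, epsilon = 0, max_medians = 128L, panel = NULL) {
  inp <- if (inherits(x, "hap_tbl")) prepare_network_input(x, panel) else x
  h <- inp$h
  mult <- inp$mult
  members <- inp$members %||% rep(list(character()), nrow(h))
  kind <- rep("observed", nrow(h))

  if (nrow(h) == 1) {
    return(build_haplo_network(h, kind, mult, members, epsilon,
                               mst_observed = 0))
  }

  mst_observed <- mst_length(step_dist_matrix(h))
  added <- 0L
  repeat {
    D <- step_dist_matrix(h)
    cost <- mst_length(D)
    edges <- msn_edge_list(D, epsilon)
    cands <- median_candidates(h, edges)
    keys <- hap_key(h)
    cands <- cands[!vapply(cands, function(m)
      paste(ifelse(is.na(m), "*", m), collapse = "|") %in% keys, logical(1))]
    if (!length(cands)) break
    best <- NULL
    best_cost <- Inf
    for (m in cands) {
      dm <- cand_dists(h, m)
      c2 <- mst_length(rbind(cbind(D, dm), c(dm, 0)))
      accept <- c2 < cost - 1e-9 ||
        (epsilon > 0 && c2 <= cost + epsilon + 1e-9)
      if (accept && (c2 < best_cost - 1e-9 ||
                     (abs(c2 - best_cost) <= 1e-9 && lex_less(m, best)))) {
        best <- m
        best_cost <- c2
      }
    }
    if (is.null(best)) break
    h <- rbind(h, best)
    rownames(h) <- NULL
    kind <- c(kind, "median")
    mult <- c(mult, 0L)
    members <- c(members, list(character()))
    added <- added + 1L
    if (added > max_medians) abort("median-joining did not terminate (cap reached)")
  }

  # prune median vectors whose removal does not lengthen the network
  repeat {
    D <- step_dist_matrix(h)
    cost <- mst_length(D)
    med_idx <- which(kind == "median")
    drop <- NA_integer_
    for (i in med_idx) {
      if (mst_length(D[-i, -i, drop = FALSE]) <= cost + 1e-9) {
        drop <- i
        break
      }
    }
    if (is.na(drop)) break
    h <- h[-drop, , drop = FALSE]
    kind <- kind[-drop]
    mult <- mult[-drop]
    members <- members[-drop]
  }

  build_haplo_network(h, kind, mult, members, epsilon, mst_observed)
}

cand_dists <- function(h, m) {
  dif <- abs(sweep(h, 2, m, "-"))
  dif[is.na(dif)] <- 0
  rowSums(dif)
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  a[is.na(a)] <- -Inf
  b[is.na(b)] <- -Inf
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  a[d[1]] < b[d[1]]
}

build_haplo_network <- function(h, kind, mult, members, epsilon, mst_observed) {
  n <- nrow(h)
  ids <- character(n)
  ids[kind == "observed"] <- paste0("H", seq_len(sum(kind == "observed")))
  ids[kind == "median"] <- paste0("mv", seq_len(sum(kind == "median")))
  nodes <- tibble(
    id = ids, kind = kind, size = as.integer(mult),
    haplotype = hap_key(h), members = members,
    haplogroup = NA_character_
  )
  if (n >= 2) {
    D <- step_dist_matrix(h)
    e <- msn_edge_list(D, epsilon)
    edges <- tibble(from = ids[e[, 1]], to = ids[e[, 2]], steps = D[e])
    total_cost <- mst_length(D)
  } else {
    edges <- tibble(from = character(), to = character(), steps = numeric())
    total_cost <- 0
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(
      name = nodes$id, kind = nodes$kind, size = nodes$size,
      haplotype = nodes$haplotype,
      members = vapply(nodes$members, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  )
  structure(list(
    nodes = nodes, edges = edges, graph = g, haplotypes = h,
    epsilon = epsilon, total_cost = total_cost,
    mst_cost_observed = mst_observed
  ), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes (%d observed, %d median), %d edges, cost %g\n",
              nrow(x$nodes), sum(x$nodes$kind == "observed"),
              sum(x$nodes$kind == "median"), nrow(x$edges), x$total_cost))
  invisible(x)
}

#' Node table of a median-joining network
#' @param x a `haplo_network`.
#' @param ... unused.
#' @export
tidy.haplo_network <- function(x, ...) x$nodes

#' Annotate network nodes with haplogroup labels
#'
#' Labels each observed node by the majority haplogroup of its member
#' samples; ties become a multi-label joined with `"/"`. Typically fed from
#' [predict_haplogroup()] output or simulation truth labels.
#'
#' @param net a `haplo_network`.
#' @param assignments tibble with `sample_id` and `haplogroup` columns.
#' @return the network with its `haplogroup` node column (and graph
#'   attribute) filled in.
#' @export
annotate_network <- function(net, assignments) {
  lab <- vapply(net$nodes$members, function(mm) {
    hg <- assignments$haplogroup[match(mm, assignments$sample_id)]
    hg <- hg[!is.na(hg)]
    if (!length(hg)) return(NA_character_)
    tt <- table(hg)
    paste(sort(names(tt)[tt == max(tt)]), collapse = "/")
  }, character(1))
  net$nodes$haplogroup <- lab
  net$graph <- igraph::set_vertex_attr(net$graph, "haplogroup",
                                       value = ifelse(is.na(lab), "", lab))
  net
}

#' Export a network to GraphML or DOT
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(net$graph, path, format = format)
  invisible(path)
}
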