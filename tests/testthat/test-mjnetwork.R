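net_input <- function(h) {
  list(h = h, mult = rep(1L, nrow(h)),
       members = as.list(paste0("s", seq_len(nrow(h)))),
       loci = paste0("L", seq_len(ncol(h))))
}

test_that("network preprocessing rounds microvariants, drops DYS385 and collapses", {
  df <- rbind(modal_row("S1"), modal_row("S2"), modal_row("S3"))
  df$DYS458 <- c(17.2, 17.3, 18)   # nearest integer: 17, 17, 18
  df$DYS385a <- c(13, 14, 13)      # excluded from the network entirely
  inp <- prepare_network_input(as_hap_tbl(df))
  expect_false(any(grepl("DYS385", inp$loci)))
  expect_equal(nrow(inp$h), 2)
  expect_setequal(inp$mult, c(2L, 1L))
  expect_true(all(inp$h == floor(inp$h)))
  # half rounds away from zero
  expect_equal(ystrpop:::round_half_away(c(17.5, 16.5, -2.5)), c(18, 17, -3))

  # missing call (sentinel 99 on input) excluded locus-wise from distances
  df2 <- rbind(modal_row("S1"), modal_row("S2"))
  df2$DYS392 <- c(NA, 14)
  df2$DYS19 <- c(14, 16)
  inp2 <- prepare_network_input(as_hap_tbl(df2))
  D <- ystrpop:::step_dist_matrix(inp2$h)
  expect_equal(D[1, 2], 2) # only DYS19 contributes
})

test_that("the minimum spanning network contains MST edges and relaxes with epsilon", {
  h2 <- rbind(c(10, 10), c(12, 11))
  e <- msn(h2)
  expect_equal(nrow(e), 1)
  expect_equal(e$steps, 3)

  # collinear haplotypes form a path of total length 4
  h3 <- cbind(c(10, 12, 14))
  e3 <- msn(h3)
  expect_equal(sum(e3$steps), 4)
  expect_equal(nrow(e3), 2)
  expect_false(any(e3$from == 1 & e3$to == 3))

  # large epsilon admits every edge
  e_full <- msn(h3, epsilon = 100)
  expect_equal(nrow(e_full), 3)
})

test_that("median joining adds useful medians and never exceeds the observed MST", {
  # star: the center is already observed
  net <- median_joining(net_input(rbind(c(10, 10), c(10, 12), c(12, 10))))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(net$total_cost, 4)

  # three haplotypes around an unobserved center (1,1,1): MST costs 4,
  # the median vector brings it down to the Steiner minimum 3
  h <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
  net2 <- median_joining(net_input(h))
  expect_equal(net2$mst_cost_observed, 4)
  expect_equal(net2$total_cost, 3)
  expect_equal(sum(net2$nodes$kind == "median"), 1)
  expect_equal(net2$nodes$haplotype[net2$nodes$kind == "median"], "1|1|1")

  # square: no integer median helps
  net3 <- median_joining(net_input(rbind(c(10, 10), c(12, 10),
                                         c(10, 12), c(12, 12))))
  expect_lte(net3$total_cost, net3$mst_cost_observed)

  # single distinct haplotype: one node, no edges
  net4 <- median_joining(list(h = rbind(c(10, 10)), mult = 128L,
                              members = list("all"), loci = c("L1", "L2")))
  expect_equal(nrow(net4$nodes), 1)
  expect_equal(nrow(net4$edges), 0)
  expect_equal(net4$nodes$size, 128L)
})

test_that("median joining reaches the brute-force Steiner minimum on small fixtures", {
  fixtures <- list(
    rbind(c(10, 10), c(10, 12), c(12, 10)),
    rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)),
    rbind(c(10, 10), c(12, 10), c(10, 12), c(12, 12)),
    rbind(c(0, 0, 0, 0), c(2, 1, 0, 0), c(2, 0, 1, 0), c(2, 0, 0, 1)),
    cbind(c(10, 12, 14), c(5, 5, 5))
  )
  for (h in fixtures) {
    net <- median_joining(net_input(h))
    expect_equal(net$total_cost, steiner_min_length(h),
                 info = paste("fixture", paste(dim(h), collapse = "x")))
    expect_lte(net$total_cost, net$mst_cost_observed)
  }
})

test_that("networks are connected, deterministic and observed-complete", {
  sim <- simulate_haplotypes(populations = c(Yemen = 40), seed = 21)
  net <- median_joining(sim$haplotypes)
  expect_true(igraph::is_connected(net$graph))
  inp <- prepare_network_input(sim$haplotypes)
  obs_keys <- ystrpop:::hap_key(inp$h)
  expect_true(all(obs_keys %in% net$nodes$haplotype))
  expect_true(all(net$edges$steps >= 1))
  expect_lte(net$total_cost, net$mst_cost_observed)

  shuffled <- as_hap_tbl(as.data.frame(sim$haplotypes)[rev(seq_len(nrow(sim$haplotypes))), ])
  net2 <- median_joining(shuffled)
  expect_setequal(net2$nodes$haplotype, net$nodes$haplotype)
  expect_equal(net2$total_cost, net$total_cost)
})

test_that("networks annotate and export to GraphML and DOT", {
  sim <- simulate_haplotypes(populations = c(Yemen = 25), seed = 22)
  net <- median_joining(sim$haplotypes)
  net <- annotate_network(net, dplyr::rename(sim$truth, haplogroup = lineage))
  obs <- net$nodes$kind == "observed"
  expect_true(all(!is.na(net$nodes$haplogroup[obs])))

  f1 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f1, "graphml")
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::gorder(g2), nrow(net$nodes))
  expect_equal(igraph::gsize(g2), nrow(net$edges))
  expect_true("size" %in% igraph::vertex_attr_names(g2))

  f2 <- withr::local_tempfile(fileext = ".dot")
  export_network(net, f2, "dot")
  expect_true(any(grepl("size", readLines(f2))))
  expect_error(export_network(net, f2, "gexf"))
})
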