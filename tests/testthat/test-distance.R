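test_that("haplotype distances sum squared repeat differences with DYS385 sorted", {
  a <- as_hap_tbl(modal_row("S1"))
  b <- as_hap_tbl(modal_row("S2"))
  expect_equal(haplotype_distance(a, b), 0)
  b2 <- modal_row("S2"); b2$DYS19 <- 16
  expect_equal(haplotype_distance(a, as_hap_tbl(b2)), 4)
  # DYS385 (13,17) vs (14,17): sorted positional differences -> 1
  b3 <- modal_row("S2"); b3$DYS385a <- 14
  expect_equal(haplotype_distance(a, as_hap_tbl(b3)), 1)
  # missing loci contribute zero
  b4 <- modal_row("S2"); b4$DYS19 <- NA; b4$DYS392 <- 15
  expect_equal(haplotype_distance(a, suppressWarnings(as_hap_tbl(b4))), 16)
})

test_that("pairwise differences match exhaustive pair enumeration", {
  # hand example on a single locus
  tbl <- one_locus_table(c(10, 12, 20, 20), c("A", "A", "B", "B"))
  pd <- pairwise_differences(tbl)
  expect_equal(pd$pi_x$pi_x, c(4, 0))
  expect_equal(pd$pi_xy["A", "B"], (100 + 100 + 64 + 64) / 4)
  expect_equal(pd$corrected["A", "B"], 82 - 2)
  expect_equal(diag(pd$corrected), c(A = 0, B = 0))

  # identical populations: corrected distance is zero
  sim <- simulate_haplotypes(populations = c(X = 10), seed = 2)$haplotypes
  dup <- as.data.frame(sim)
  dup$population <- "Y"
  dup$sample_id <- paste0(dup$sample_id, "y")
  both <- as_hap_tbl(rbind(as.data.frame(sim), dup))
  pd2 <- pairwise_differences(both)
  # the cross average includes each profile paired with its own copy at
  # distance zero, so PiXY = (1 - 1/n) PiX and corrected = -PiX/n exactly
  n <- 10
  expect_equal(pd2$pi_xy["X", "Y"], (1 - 1 / n) * pd2$pi_x$pi_x[1])
  expect_equal(pd2$corrected["X", "Y"], -pd2$pi_x$pi_x[1] / n)
  expect_lt(abs(pd2$corrected["X", "Y"]) / pd2$pi_x$pi_x[1], 0.11)

  # brute force on a random multi-population table
  tbl3 <- simulate_haplotypes(populations = c(A = 6, B = 5, C = 4),
                              divergence_depth = 30, seed = 9)$haplotypes
  pd3 <- pairwise_differences(tbl3)
  D <- str_distance_matrix(tbl3)
  for (p in unique(tbl3$population)) {
    i <- which(tbl3$population == p)
    acc <- c()
    for (a in i) for (b in i) if (a < b) acc <- c(acc, D[a, b])
    expect_equal(pd3$pi_x$pi_x[pd3$pi_x$population == p], mean(acc))
  }
  i <- which(tbl3$population == "A"); j <- which(tbl3$population == "B")
  acc <- c()
  for (a in i) for (b in j) acc <- c(acc, D[a, b])
  expect_equal(pd3$pi_xy["A", "B"], mean(acc))
})

test_that("population of size one yields missing within and corrected entries", {
  tbl <- one_locus_table(c(10, 12, 20), c("A", "A", "B"))
  pd <- pairwise_differences(tbl)
  expect_true(is.na(pd$pi_x$pi_x[pd$pi_x$population == "B"]))
  expect_true(is.na(pd$corrected["A", "B"]))
})

test_that("AMOVA variance components follow the two-level decomposition", {
  # no within variance: R_ST = 1
  tbl <- one_locus_table(c(10, 10, 14, 14), c("A", "A", "B", "B"))
  am <- amova_pair(tbl, "A", "B")
  expect_equal(am$sigma_w, 0)
  expect_equal(am$rst, 1)

  # two copies of the same tiny population: no among-group variance, and
  # the unbiased estimator lands at exactly -1/(n-1), slightly below zero
  tbl2 <- one_locus_table(c(10, 12, 14, 10, 12, 14), rep(c("A", "B"), each = 3))
  am2 <- amova_pair(tbl2, "A", "B")
  expect_equal(am2$rst, -1 / 2)

  # independent brute-force recomputation with explicit loops
  tbl3 <- one_locus_table(c(10, 12, 20, 20), c("A", "A", "B", "B"))
  am3 <- amova_pair(tbl3, "A", "B")
  vals <- c(10, 12, 20, 20); grp <- c("A", "A", "B", "B"); N <- 4; P <- 2
  d <- outer(vals, vals, "-")^2
  ssd_tot <- 0
  for (a in 1:3) for (b in (a + 1):4) ssd_tot <- ssd_tot + d[a, b]
  ssd_tot <- ssd_tot / N
  ssd_w <- 0
  for (p in c("A", "B")) {
    i <- which(grp == p)
    ssd_w <- ssd_w + d[i[1], i[2]] / length(i)
  }
  ms_a <- (ssd_tot - ssd_w) / (P - 1)
  ms_w <- ssd_w / (N - P)
  n_c <- (N - (2^2 + 2^2) / N) / (P - 1)
  s_a <- (ms_a - ms_w) / n_c
  expect_equal(am3$SSD_total, ssd_tot)
  expect_equal(am3$SSD_within, ssd_w)
  expect_equal(am3$rst, s_a / (s_a + ms_w))

  # SSD additivity to 1e-9 on a simulated pair
  sim <- simulate_haplotypes(populations = c(A = 15, B = 15),
                             divergence_depth = 25, seed = 4)$haplotypes
  am4 <- amova_pair(sim, "A", "B")
  expect_equal(am4$SSD_total, am4$SSD_within + am4$SSD_among, tolerance = 1e-9)
})

test_that("R_ST is invariant to allele translation, scaling and label permutation", {
  sim <- simulate_haplotypes(populations = c(A = 12, B = 12),
                             divergence_depth = 40, seed = 6)$haplotypes
  base <- amova_pair(sim, "A", "B")$rst

  shifted <- as.data.frame(sim)
  shifted$DYS19 <- shifted$DYS19 + 7
  expect_equal(amova_pair(as_hap_tbl(shifted), "A", "B")$rst, base)

  scaled <- as.data.frame(sim)
  cols <- panel_columns(yfiler_panel())
  scaled[cols] <- scaled[cols] * 2
  expect_equal(amova_pair(as_hap_tbl(scaled, validate_alleles = FALSE),
                          "A", "B")$rst, base,
               tolerance = 1e-12)

  perm <- as.data.frame(sim)[sample(nrow(sim)), ]
  expect_equal(amova_pair(as_hap_tbl(perm), "A", "B")$rst, base)

  # degenerate zero-variance input is flagged, not NaN
  flat <- one_locus_table(rep(10, 4), c("A", "A", "B", "B"))
  am0 <- amova_pair(flat, "A", "B")
  expect_true(am0$degenerate)
  expect_equal(am0$rst, 0)
})

test_that("the R_ST matrix is symmetric and respects population relabelling", {
  sim <- simulate_haplotypes(populations = c(A = 8, B = 8, C = 8),
                             divergence_depth = 30, seed = 12)$haplotypes
  R <- rst_matrix(sim)
  expect_equal(R, t(R))
  expect_equal(diag(R), c(A = 0, B = 0, C = 0))
  # relabel populations: same values under the permutation
  relab <- as.data.frame(sim)
  map <- c(A = "C", B = "A", C = "B")
  relab$population <- map[relab$population]
  R2 <- rst_matrix(as_hap_tbl(relab))
  expect_equal(R2[map["A"], map["B"]], R["A", "B"])
  expect_equal(R2[map["B"], map["C"]], R["B", "C"])

  # a single founder population split three ways: R_ST near zero
  one <- simulate_haplotypes(populations = c(A = 15, B = 15, C = 15),
                             divergence_depth = 0, seed = 13)$haplotypes
  expect_true(all(abs(rst_matrix(one)) < 0.06))
})
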