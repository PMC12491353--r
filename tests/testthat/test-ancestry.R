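test_that("Q-matrix F_ST matches hand arithmetic and its bounds", {
  # identical interior rows: no variability
  Q0 <- matrix(rep(c(0.4, 0.6), each = 5), 5)
  expect_equal(as.numeric(fst_of_q(Q0)), 0)
  # rows at distinct vertices, I = K: maximal variability
  expect_equal(as.numeric(fst_of_q(diag(3))), 1)
  # hand example
  Q <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(as.numeric(fst_of_q(Q)), ((1 + 0.5) / 2 - 0.625) / (1 - 0.625))
  # degenerate: all rows at one vertex
  Qd <- matrix(rep(c(1, 0), each = 4), 4)
  f <- fst_of_q(Qd)
  expect_equal(as.numeric(f), 0)
  expect_true(attr(f, "degenerate"))
  expect_error(fst_of_q(rbind(c(0.5, 0.6), c(0.5, 0.5))), "sum to 1")
})

test_that("closed-form F_ST^max agrees with vertex-enumeration maximization", {
  # uniform means with I divisible by K: all-vertex assignment achievable
  expect_equal(as.numeric(fst_max_of_q(c(0.5, 0.5), 4)), 1)
  expect_equal(as.numeric(fst_max_of_q(rep(1 / 3, 3), 6)), 1)
  # 1-D grid-search oracle for I = 2, pbar = (0.75, 0.25)
  grid <- seq(0.5, 1, by = 1e-4)
  ss <- (grid^2 + (1 - grid)^2 + (1.5 - grid)^2 + (grid - 0.5)^2) / 2
  ref <- (max(ss) - 0.625) / (1 - 0.625)
  expect_equal(as.numeric(fst_max_of_q(c(0.75, 0.25), 2)), ref, tolerance = 1e-6)
  # exact transportation-polytope vertex enumeration, K <= 3, I <= 6
  set.seed(91)
  cases <- list(
    list(I = 2, p = c(0.6, 0.4)),
    list(I = 3, p = c(0.5, 0.3, 0.2)),
    list(I = 4, p = c(0.7, 0.2, 0.1)),
    list(I = 5, p = c(0.45, 0.35, 0.2)),
    list(I = 6, p = c(0.55, 0.45)),
    list(I = 6, p = c(0.5, 0.3, 0.2))
  )
  for (cs in cases) {
    expect_equal(as.numeric(fst_max_of_q(cs$p, cs$I)),
                 fst_max_oracle(cs$p, cs$I), tolerance = 1e-6,
                 info = paste("I =", cs$I, "K =", length(cs$p)))
  }
  # degenerate mean at a vertex
  fm <- fst_max_of_q(c(1, 0), 4)
  expect_equal(as.numeric(fm), 0)
  expect_true(attr(fm, "degenerate"))
})

test_that("F_ST^max bounds the F_ST of random conforming Q matrices", {
  set.seed(92)
  for (r in 1:200) {
    I <- sample(2:8, 1); K <- sample(2:4, 1)
    Q <- matrix(rgamma(I * K, 0.7), I)
    Q <- Q / rowSums(Q)
    fmax <- as.numeric(fst_max_of_q(colMeans(Q), I))
    expect_gte(fmax + 1e-9, as.numeric(fst_of_q(Q)))
  }
})

test_that("bootstrap ratios hit their limits, respect seeds and order admixture", {
  ident <- data.frame(population = "p", Q1 = rep(0.3, 6), Q2 = rep(0.7, 6))
  r0 <- fstruct(ident, B = 20, seed = 1)
  expect_equal(r0$ratio, 0)
  expect_true(all(r0$boot[[1]] == 0))

  vert <- data.frame(population = "v",
                     Q1 = rep(c(1, 0), 3), Q2 = rep(c(0, 1), 3))
  rv <- fstruct(vert, B = 20, seed = 1)
  expect_equal(rv$ratio, 1)
  expect_true(all(abs(rv$boot[[1]] - 1) < 1e-9 | rv$boot[[1]] == 0))

  q <- simulate_q(c(adm = 30, drifted = 30), K = 3,
                  alpha = list(5, 0.2), seed = 93)
  fr <- fstruct(q, B = 60, seed = 94)
  expect_lt(fr$ratio[fr$population == "adm"],
            fr$ratio[fr$population == "drifted"])
  expect_lt(mean(fr$boot[[which(fr$population == "adm")]]),
            mean(fr$boot[[which(fr$population == "drifted")]]))
  # ratio stays within [0, 1] everywhere
  expect_true(all(unlist(fr$boot) >= 0 & unlist(fr$boot) <= 1 + 1e-9))

  fr2 <- fstruct(q, B = 60, seed = 94)
  expect_identical(fr$boot, fr2$boot)
  # B = 0: point estimate only
  fr3 <- fstruct(q, B = 0)
  expect_equal(lengths(fr3$boot), c(0L, 0L))
  # single-row population skipped with a warning
  qs <- rbind(q, data.frame(individual = "solo", population = "single",
                            Q1 = 0.2, Q2 = 0.3, Q3 = 0.5))
  expect_warning(fstruct(qs, B = 5, seed = 1), "single")
})

test_that("Kruskal-Wallis H follows hand-ranked arithmetic and df = groups - 1", {
  same <- kruskal_wallis(c(1, 1, 1, 1), rep(c("a", "b"), 2))
  expect_equal(same$statistic, 0)
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_equal(kw$df, 1)
  g16 <- kruskal_wallis(rnorm(160), rep(paste0("g", 1:16), each = 10))
  expect_equal(g16$df, 15)
})

test_that("the naive-Bayes predictor reproduces Bayes arithmetic on small models", {
  # single locus, P(14|A) ~ 0.9, P(14|B) ~ 0.1 via 9:1 counts, tiny alpha
  ref <- do.call(rbind, lapply(1:20, function(i) modal_row(paste0("R", i))))
  ref$haplogroup <- rep(c("A", "B"), each = 10)
  ref$DYS19 <- c(rep(14, 9), 15, 14, rep(15, 9))
  model <- fit_haplogroup_model(ref, alpha = 1e-9, priors = "uniform")
  # query profile that matches the modal haplotype except the test locus
  qdf <- modal_row("Q1"); qdf$DYS19 <- 14
  pred <- predict_haplogroup(as_hap_tbl(qdf), model)
  expect_equal(pred$haplogroup, "A")
  expect_equal(pred$p_A, 0.9, tolerance = 1e-6)
  expect_equal(pred$p_A + pred$p_B, 1)

  # allele unseen in both classes (equal class sizes): posterior = priors
  qdf2 <- modal_row("Q2"); qdf2$DYS19 <- 25
  pred2 <- predict_haplogroup(as_hap_tbl(qdf2), model)
  expect_equal(pred2$p_A, 0.5, tolerance = 1e-6)

  # alpha -> infinity washes out the likelihood toward the priors
  model3 <- fit_haplogroup_model(ref, alpha = 1e7, priors = "empirical")
  pred3 <- predict_haplogroup(as_hap_tbl(qdf), model3)
  expect_equal(pred3$p_A, 0.5, tolerance = 1e-3)
})

test_that("prediction is invariant to reference column order and flags empty profiles", {
  ref <- do.call(rbind, lapply(1:10, function(i) modal_row(paste0("R", i))))
  ref$haplogroup <- rep(c("A", "B"), each = 5)
  ref$DYS19 <- rep(c(14, 17), each = 5)
  m1 <- fit_haplogroup_model(ref)
  perm <- ref[, c(1, 2, sample(3:19), 20)]
  m2 <- fit_haplogroup_model(perm)
  q <- as_hap_tbl(modal_row("Q"))
  expect_equal(predict_haplogroup(q, m1)$p_A, predict_haplogroup(q, m2)$p_A)

  empty <- modal_row("E")
  cols <- setdiff(names(empty), c("sample_id", "population"))
  empty[cols] <- NA
  pe <- predict_haplogroup(as_hap_tbl(empty), m1)
  expect_true(pe$degenerate)
  expect_equal(pe$p_A, 0.5)
})

test_that("the predictor recovers simulated lineages from disjoint founders", {
  sim <- simulate_haplotypes(seed = 101)
  ref <- as.data.frame(sim$haplotypes)
  ref$haplogroup <- sim$truth$lineage
  model <- fit_haplogroup_model(ref)
  pred <- predict_haplogroup(sim$haplotypes, model)
  expect_gte(mean(pred$haplogroup == sim$truth$lineage), 0.95)
  # predicted share of the dominant founder lineage close to its proportion
  prop <- haplogroup_proportions(pred)
  expect_lt(abs(prop$pct[prop$haplogroup == "J1a"] - 59), 10)
})

test_that("haplogroup proportions report exact and display-truncated percentages", {
  labels <- c(rep("J1a", 76), rep("E1b1b", 27), rep("other", 25))
  hp <- haplogroup_proportions(labels)
  expect_equal(hp$pct[hp$haplogroup == "J1a"], 100 * 76 / 128)
  expect_equal(hp$pct_label[hp$haplogroup == "J1a"], "59.37")
  expect_equal(hp$pct_label[hp$haplogroup == "E1b1b"], "21.09")
})
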