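test_that("spatial lag is the weighted neighbour combination", {
  W2 <- contiguity_weights(pair_adjacency())
  expect_equal(spatial_lag(W2, c(2, 4)), c(4, 2))
  # row-standardized lag preserves constants
  expect_equal(spatial_lag(china_W, rep(3.7, 31)), rep(3.7, 31))
  # indicator of Guangdong (19): Hainan (21), whose only neighbour it is,
  # gets lag 1; regions not adjacent to Guangdong get 0
  x <- as.numeric(china_W$region_order == 19)
  lag <- spatial_lag(china_W, x)
  expect_equal(lag[21], 1)
  nbrs <- china_adj$neighbors[["19"]]
  expect_true(all(lag[!(china_W$region_order %in% c(nbrs, 19))] == 0))
  expect_error(spatial_lag(china_W, 1:5), "does not match")
})

test_that("Moran's I hits the exact values of dispersed and clustered patterns", {
  ring4 <- build_binary_weights(ring_adjacency(4))
  expect_equal(global_morans_i(c(1, -1, 1, -1), ring4)$statistic, -1,
               tolerance = 1e-12)
  # two disconnected mutual pairs, identical values within a pair
  pairs <- build_binary_weights(
    parse_adjacency_table(c("1 A 2", "2 B 1", "3 C 4", "4 D 3")))
  expect_equal(global_morans_i(c(2, 2, 7, 7), pairs)$statistic, 1,
               tolerance = 1e-12)
})

test_that("vectorized Moran equals the naive double sum on random instances", {
  set.seed(42)
  for (k in 1:50) {
    n <- sample(5:15, 1)
    W <- contiguity_weights(random_adjacency(n, seed = k))
    x <- rnorm(n)
    expect_equal(global_morans_i(x, W)$statistic, naive_moran(x, W$matrix),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I is invariant to affine maps and joint relabeling", {
  set.seed(7)
  W <- contiguity_weights(random_adjacency(9, seed = 3))
  x <- rnorm(9)
  i0 <- global_morans_i(x, W)$statistic
  expect_equal(global_morans_i(3 - 2.5 * x, W)$statistic, i0, tolerance = 1e-12)
  expect_equal(global_morans_i(1e4 * x, W)$statistic, i0, tolerance = 1e-12)
  for (k in 1:5) {
    p <- sample(9)
    Wp <- W
    Wp$matrix <- W$matrix[p, p]
    Wp$region_order <- W$region_order[p]
    expect_equal(global_morans_i(x[p], Wp)$statistic, i0, tolerance = 1e-12)
  }
})

test_that("the permutation-null mean of I is exactly -1/(n-1)", {
  for (n in c(4L, 5L, 6L)) {
    W <- contiguity_weights(random_adjacency(n, extra = 1, seed = n))
    x <- c(0.3, -1.2, 2.2, 0.5, -0.4, 1.9)[seq_len(n)]
    perms <- all_permutations(n)
    vals <- apply(perms, 1, function(p) global_morans_i(x[p], W)$statistic)
    expect_equal(mean(vals), -1 / (n - 1), tolerance = 1e-12)
  }
})

test_that("the randomization variance formula matches exhaustive permutation", {
  # brute force over all 120 permutations at n = 5 is the exact null variance
  W <- contiguity_weights(random_adjacency(5, extra = 2, seed = 11))
  x <- c(0.7, -0.9, 1.8, -0.2, 0.1)
  perms <- all_permutations(5)
  vals <- apply(perms, 1, function(p) global_morans_i(x[p], W)$statistic)
  exact_var <- mean(vals^2) - mean(vals)^2
  res <- moran_inference(x, W, method = "normal_randomization")
  expect_equal(res$variance_null, exact_var, tolerance = 1e-10)
  expect_equal(res$expected_null, -0.25)
})

test_that("permutation inference gives a seeded, valid pseudo p-value", {
  set.seed(1)
  x <- rnorm(31)
  r1 <- moran_inference(x, china_W, method = "permutation",
                        n_permutations = 199, seed = 5)
  r2 <- moran_inference(x, china_W, method = "permutation",
                        n_permutations = 199, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_lte(r1$p_value, 1)
  expect_error(moran_inference(x, china_W, method = "permutation",
                               n_permutations = 50, seed = 1), ">= 99")
  expect_error(moran_inference(x, china_W, method = "permutation",
                               n_permutations = 199), "seed")
})

test_that("strong spatial-lag dependence is detected with high power", {
  ref <- reference_params("SLM")
  cfg <- synthetic_config(family = "SLM", rho = 0.8, beta = ref$beta,
                          sigma2 = ref$sigma2)
  pvals <- vapply(1:200, function(i) {
    cfg$seed <- 5000 + i
    p <- simulate_panel(cfg, china_W)
    moran_inference(p$respdeath[p$year == 2004], china_W)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.95)
})

test_that("|I| stays within 1 for row-standardized weights on test draws", {
  set.seed(12)
  for (k in 1:30) {
    x <- rnorm(31)
    expect_lte(abs(global_morans_i(x, china_W)$statistic), 1 + 1e-9)
  }
})

test_that("degenerate and invalid Moran inputs raise errors", {
  expect_error(global_morans_i(rep(2, 31), china_W), "constant")
  Wneg <- china_W
  Wneg$matrix[1, 2] <- -0.5
  expect_error(global_morans_i(rnorm(31), Wneg), "negative")
  W3 <- contiguity_weights(ring_adjacency(3))
  expect_error(moran_inference(rnorm(3), W3), "n >= 4")
})

test_that("quadrant classification follows the scatterplot sign scheme", {
  # two mutually adjacent highs, a separate clique of lows
  adj <- parse_adjacency_table(c("1 A 2", "2 B 1", "3 C 4 5 6", "4 D 3 5 6",
                                 "5 E 3 4 6", "6 F 3 4 5"))
  W <- contiguity_weights(adj)
  qc <- quadrant_classify(c(2, 2, -1, -1, -1, -1), W)
  expect_identical(unname(qc$labels[1:2]), c("HH", "HH"))
  expect_identical(unname(qc$labels[3:6]), rep("LL", 4))
  expect_equal(sum(qc$counts), 6)

  # star: one high centre surrounded by lows -> HL; the lows see a high
  # neighbourhood -> LH
  star <- parse_adjacency_table(c("1 hub 2 3 4", "2 s 1", "3 s 1", "4 s 1"))
  Ws <- contiguity_weights(star)
  qs <- quadrant_classify(c(5, 0, 0, 0), Ws)
  expect_identical(unname(qs$labels[1]), "HL")
  expect_identical(unname(qs$labels[2:4]), rep("LH", 3))
  expect_equal(sum(qs$counts), 4)
})

test_that("exact zeros in the scatterplot fall on the low side", {
  W3 <- contiguity_weights(ring_adjacency(3))
  qc <- quadrant_classify(c(1, 0, -1), W3)
  # region 2 has standardized value 0 and lag 0: third quadrant by convention
  expect_identical(unname(qc$labels[2]), "LL")
  expect_error(quadrant_classify(rep(1, 3), W3), "constant")
})

test_that("per-year Moran tables have one row per year and detect dependence", {
  ref <- reference_params("SLM")
  cfg <- synthetic_config(family = "SLM", rho = 0.85, beta = ref$beta,
                          sigma2 = ref$sigma2, seed = 21)
  panel <- simulate_panel(cfg, china_W)
  tab <- moran_by_year(panel, "respdeath", china_W)
  expect_equal(nrow(tab), 5L)
  expect_identical(tab$year, 2004:2008)
  expect_true(all(tab$p_value < 0.05))

  # independent DGP: I fluctuates around -1/30
  cfg0 <- synthetic_config(family = "independent", beta = ref$beta,
                           sigma2 = 1, spatial_mixing = 0, seed = 8)
  means <- rowMeans(vapply(1:20, function(s) {
    cfg0$seed <- 1000 + s
    p0 <- simulate_panel(cfg0, china_W)
    moran_by_year(p0, "respdeath", china_W)$moran_i
  }, numeric(5)))
  expect_lt(max(abs(mean(means) - (-1 / 30))), 0.05)

  expect_error(moran_by_year(panel[-3, ], "respdeath", china_W), "unbalanced")
  expect_error(moran_by_year(panel, "nope", china_W), "no column")
})
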