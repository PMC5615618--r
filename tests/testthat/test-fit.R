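# one moderately sized SLM panel reused across estimation tests
slm_panel <- local({
  ref <- reference_params("SLM")
  cfg <- synthetic_config(family = "SLM", rho = ref$rho, beta = ref$beta,
                          sigma2 = ref$sigma2, seed = 314)
  simulate_panel(cfg, china_W)
})

test_that("the eigenvalue log-Jacobian equals the dense log-determinant", {
  expect_identical(log_det_jacobian(0, weights_spectrum(china_W)), 0)
  for (s in 1:5) {
    W <- contiguity_weights(random_adjacency(6, extra = 3, seed = s))
    ev <- weights_spectrum(W)
    for (r in c(-0.7, 0.1, 0.4, 0.9)) {
      dense <- determinant(diag(6) - r * W$matrix, logarithm = TRUE)
      expect_equal(log_det_jacobian(r, ev), as.numeric(dense$modulus),
                   tolerance = 1e-10)
    }
  }
})

test_that("the log-Jacobian diverges to -Inf as rho approaches 1", {
  ev <- weights_spectrum(china_W)
  vals <- vapply(c(0.9, 0.99, 0.999, 0.999999), log_det_jacobian, 0,
                 spectrum = ev)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4], -10)
  expect_error(log_det_jacobian(1.5, ev), "admissible")
  expect_error(log_det_jacobian(1 / min(ev) - 0.1, ev), "admissible")
})

test_that("the concentrated optimum matches a 2001-point grid search", {
  f <- fit_slm(slm_panel, china_W, se = FALSE)
  ev <- weights_spectrum(china_W)
  grid <- seq(1 / min(ev) + 1e-4, 1 - 1e-4, length.out = 2001)
  ll <- vapply(grid, function(r) {
    fit_slm(slm_panel, china_W, rho = r, se = FALSE)$log_likelihood
  }, numeric(1))
  expect_lt(abs(f$rho[["estimate"]] - grid[which.max(ll)]),
            diff(grid[1:2]))
})

test_that("constraining the spatial parameter to zero reproduces within-OLS", {
  ols <- fit_ols(slm_panel)
  slm0 <- fit_slm(slm_panel, china_W, rho = 0, se = FALSE)
  sem0 <- fit_sem(slm_panel, china_W, lambda = 0, se = FALSE)
  bnames <- c("pm25", "lngdp", "lnhos", "lncost", "popudens")
  get_b <- function(f) {
    stats::setNames(f$coefficients$estimate, f$coefficients$term)[bnames]
  }
  expect_equal(get_b(slm0), get_b(ols), tolerance = 1e-10)
  expect_equal(get_b(sem0), get_b(ols), tolerance = 1e-10)
})

test_that("the likelihood at the optimum dominates the zero-parameter fit", {
  for (fits in list(
    c(fit_slm(slm_panel, china_W, se = FALSE)$log_likelihood,
      fit_slm(slm_panel, china_W, rho = 0, se = FALSE)$log_likelihood),
    c(fit_sem(slm_panel, china_W, se = FALSE)$log_likelihood,
      fit_sem(slm_panel, china_W, lambda = 0, se = FALSE)$log_likelihood),
    c(fit_sdm(slm_panel, china_W, se = FALSE)$log_likelihood,
      fit_sdm(slm_panel, china_W, rho = 0, se = FALSE)$log_likelihood))) {
    expect_gte(fits[1], fits[2])
  }
})

test_that("profiling matches joint numerical optimization on a small instance", {
  W <- contiguity_weights(random_adjacency(8, extra = 4, seed = 2))
  ev <- weights_spectrum(W)
  cfg <- synthetic_config(family = "SLM", n_regions = 8, n_periods = 3,
                          rho = 0.4, beta = c(pm25 = 0.03), sigma2 = 0.05,
                          seed = 77)
  p <- simulate_panel(cfg, W)
  f <- fit_slm(p, W, covariates = "pm25", se = FALSE)

  # independent full likelihood over (rho, beta, log sigma2)
  tw <- within_transform(p, outcome = "respdeath", covariates = "pm25")
  wy_raw <- as.vector(W$matrix %*% matrix(p$respdeath[order(p$year, p$region_id)],
                                          8, 3))
  p2 <- order_panel(p); p2$wy <- wy_raw
  twl <- within_transform(p2, outcome = "respdeath",
                          covariates = c("pm25", "wy"))
  y <- twl$y; x <- twl$X[, "pm25"]; wy <- twl$X[, "wy"]
  nt <- 24
  negll <- function(th) {
    r <- th[1]
    if (r <= 1 / min(ev) + 1e-8 || r >= 1 - 1e-8) return(1e10)
    resid <- y - r * wy - th[2] * x
    s2 <- exp(th[3])
    -(-nt / 2 * log(2 * pi * s2) + 3 * sum(log(1 - r * ev)) -
        sum(resid^2) / (2 * s2))
  }
  joint <- optim(c(0.1, 0, log(0.05)), negll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(f$rho[["estimate"]] - joint$par[1]), 1e-5)
  expect_lt(abs(f$coefficients$estimate[f$coefficients$term == "pm25"] -
                  joint$par[2]), 1e-5)
})

test_that("SEM coefficients are self-consistent with the filtered regression", {
  f <- fit_sem(slm_panel, china_W, se = FALSE)
  lam <- f$lambda[["estimate"]]
  covs <- c("pm25", "lngdp", "lnhos", "lncost", "popudens")
  p <- order_panel(slm_panel)
  lag_col <- function(v) as.vector(china_W$matrix %*% matrix(v, 31, 5))
  aug <- p
  aug$.my <- lag_col(p$respdeath)
  for (cn in covs) aug[[paste0(".m.", cn)]] <- lag_col(p[[cn]])
  tw <- within_transform(aug, outcome = "respdeath",
                         covariates = c(covs, paste0(".m.", covs), ".my"))
  ys <- tw$y - lam * tw$X[, ".my"]
  Xs <- tw$X[, covs] - lam * tw$X[, paste0(".m.", covs)]
  b <- qr.coef(qr(Xs), ys)
  names(b) <- covs
  got <- stats::setNames(f$coefficients$estimate, f$coefficients$term)[covs]
  expect_equal(got, b, tolerance = 1e-10)
})

test_that("SDM collapses towards SLM when the Durbin coefficient is zero", {
  ref <- reference_params("SLM")
  cfg <- synthetic_config(family = "SLM", rho = ref$rho, beta = ref$beta,
                          sigma2 = ref$sigma2)
  set.seed(55)
  seeds <- sample.int(1e8, 50)
  agree <- vapply(seeds, function(s) {
    cfg$seed <- s
    p <- simulate_panel(cfg, china_W)
    fl <- fit_slm(p, china_W)
    fd <- fit_sdm(p, china_W, durbin_style = "common_scalar")
    d_rho <- abs(fl$rho[["estimate"]] - fd$rho[["estimate"]])
    d_b <- abs(fl$coefficients$estimate[fl$coefficients$term == "pm25"] -
                 fd$coefficients$estimate[fd$coefficients$term == "pm25"])
    d_rho <= 2 * fl$rho[["std_error"]] &&
      d_b <= 2 * fl$coefficients$std_error[fl$coefficients$term == "pm25"]
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("collinear designs raise an error naming the offending column", {
  p <- order_panel(slm_panel)
  p$dup <- 2 * p$pm25
  expect_error(fit_ols(p, covariates = c("pm25", "dup")), "dup")
  # a covariate constant across regions is annihilated by the transform
  p$flat <- rep(tapply(p$pm25, p$year, mean)[as.character(p$year)])
  expect_error(fit_sdm(p, china_W, covariates = c("pm25", "flat"),
                       durbin_style = "per_covariate"), "collinear")
})

test_that("plain least squares recovers exact coefficients without noise", {
  g <- expand.grid(region_id = 1:6, year = 1:4)
  g$x1 <- rnorm(24)
  g$respdeath <- 2 * g$x1
  f <- fit_ols(g, covariates = "x1", effects = "pooled")
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x1"], 2,
               tolerance = 1e-12)
  # pooled OLS on already-demeaned data has an intercept of (numerically) zero
  tw <- within_transform(order_panel(g), outcome = "respdeath",
                         covariates = "x1", effects = "twoway")
  g2 <- order_panel(g)
  g2$respdeath <- tw$y + 0.5 * tw$X[, "x1"] + rnorm(24, 0, 0.01)
  g2$x1 <- tw$X[, "x1"]
  fp <- fit_ols(g2, covariates = "x1", effects = "pooled")
  expect_lt(abs(fp$coefficients$estimate[fp$coefficients$term == "(Intercept)"]),
            0.02)
})

test_that("ignoring the spatial lag biases least squares more than ML", {
  ref <- reference_params("SLM")
  cfg <- synthetic_config(family = "SLM", rho = 0.5, beta = ref$beta,
                          sigma2 = ref$sigma2)
  set.seed(17)
  seeds <- sample.int(1e8, 80)
  ests <- vapply(seeds, function(s) {
    cfg$seed <- s
    p <- simulate_panel(cfg, china_W)
    c(ols = fit_ols(p)$coefficients$estimate[1],
      slm = fit_slm(p, china_W, se = FALSE)$coefficients$estimate[1])
  }, numeric(2))
  truth <- ref$beta[["pm25"]]
  expect_gt(abs(mean(ests["ols", ]) - truth), abs(mean(ests["slm", ]) - truth))
})

test_that("estimates are invariant to joint region relabeling", {
  perm <- c(5:31, 1:4)
  Wp <- china_W
  Wp$matrix <- china_W$matrix[perm, perm]
  Wp$region_order <- seq_len(31)
  Wp$spectrum <- NULL
  Wp$spectrum <- weights_spectrum(Wp)
  p <- order_panel(slm_panel)
  p$region_id <- match(p$region_id, china_W$region_order[perm])
  f0 <- fit_slm(slm_panel, china_W, se = FALSE)
  f1 <- fit_slm(p, Wp, se = FALSE)
  expect_lt(abs(f1$rho[["estimate"]] - f0$rho[["estimate"]]), 1e-6)
  expect_equal(stats::setNames(f1$coefficients$estimate, f1$coefficients$term),
               stats::setNames(f0$coefficients$estimate, f0$coefficients$term),
               tolerance = 1e-6)
})

test_that("spatial-parameter bias shrinks as the panel lengthens", {
  ref <- reference_params("SLM")
  bias <- vapply(c(5, 50), function(T_) {
    cfg <- synthetic_config(family = "SLM", n_periods = T_, rho = ref$rho,
                            beta = ref$beta, sigma2 = ref$sigma2)
    rec <- recovery_experiment(cfg, china_W, n_replicates = 50, seed = 5)
    rec$bias[rec$term == "rho"]
  }, numeric(1))
  expect_lt(abs(bias[2]), abs(bias[1]))
})

test_that("fixed spatial parameters outside the admissible interval error", {
  expect_error(fit_slm(slm_panel, china_W, rho = 1.2, se = FALSE),
               "admissible")
  expect_error(fit_sem(slm_panel, china_W, lambda = -5, se = FALSE),
               "admissible")
})

test_that("the model report mirrors the side-by-side table layout", {
  fits <- list(SDM = fit_sdm(slm_panel, china_W),
               SLM = fit_slm(slm_panel, china_W),
               SEM = fit_sem(slm_panel, china_W))
  rep_ <- model_report(fits)
  expect_true(all(c("SDM.coef", "SDM.z", "SDM.p", "SLM.coef", "SEM.coef")
                  %in% names(rep_)))
  expect_true(all(c("pm25", "delta", "rho", "lambda", "sigma2_e", "R2")
                  %in% rep_$term))
  # SEM column: lambda filled, rho empty; SLM column the reverse
  expect_true(is.na(rep_$SEM.coef[rep_$term == "rho"]))
  expect_false(is.na(rep_$SEM.coef[rep_$term == "lambda"]))
  expect_false(is.na(rep_$SLM.coef[rep_$term == "rho"]))
  expect_true(is.na(rep_$SLM.coef[rep_$term == "lambda"]))
  # a single OLS fit has no spatial-parameter rows
  rep_ols <- model_report(list(OLS = fit_ols(slm_panel)))
  expect_false(any(c("rho", "lambda") %in% rep_ols$term))
  # pseudo R2 is a squared correlation
  expect_true(all(rep_$SDM.coef[rep_$term == "R2"] >= 0 &
                    rep_$SDM.coef[rep_$term == "R2"] <= 1))
})
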