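#' Log-Jacobian of the spatial transformation
#'
#' The term \eqn{\ln|I_N - \rho W|} of the spatial likelihoods, evaluated
#' through the eigenvalues of the row-standardized weight matrix as
#' \eqn{\sum_i \ln(1 - \rho\,\omega_i)}. Callers multiply by the number of
#' periods T. \code{rho} must lie in the admissible interval
#' \eqn{(1/\omega_{min}, 1)}.
#'
#' @param rho spatial parameter.
#' @param spectrum eigenvalues of the row-standardized W (see
#'   \code{\link{weights_spectrum}}).
#' @return The log-determinant, a single number.
#' @export
log_det_jacobian <- function(rho, spectrum) {
  lo <- 1 / min(spectrum)
  if (rho <= lo || rho >= 1) {
    stop("rho = ", rho, " outside the admissible interval (",
         format(lo, digits = 6), ", 1)", call. = FALSE)
  }
  sum(log(1 - rho * spectrum))
}

# ---- internal machinery -----------------------------------------------------

# Per-period spatial lag of a panel column laid out region-major within
# period: reshape to n x T, premultiply by W, flatten.
.panel_lag <- function(v, w, n, t_) {
  as.vector(w %*% matrix(v, nrow = n, ncol = t_))
}

.check_regions_match <- function(panel, W) {
  ids <- sort(unique(panel$region_id))
  if (!identical(as.numeric(ids), as.numeric(W$region_order))) {
    stop("panel region_ids do not match the region order of W", call. = FALSE)
  }
}

.check_full_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " are linearly dependent", call. = FALSE)
  }
  qd
}

# Numerical Hessian of f at theta by central differences, relative step.
.num_hessian <- function(f, theta, h_rel = 1e-5) {
  p <- length(theta)
  h <- h_rel * (1 + abs(theta))
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(theta + ei) - 2 * f(theta) + f(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

.coef_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), std_error = unname(se),
             z = unname(z), p_value = unname(2 * pnorm(-abs(z))),
             stringsAsFactors = FALSE, row.names = NULL)
}

.new_fit <- function(family, effects, durbin_style, coefs, rho, lambda,
                     sigma2, loglik, pseudo_r2, effects_estimates,
                     n_regions, n_periods) {
  structure(list(
    coefficients = coefs, rho = rho, lambda = lambda, sigma2 = sigma2,
    log_likelihood = loglik, pseudo_r2 = pseudo_r2,
    effects_estimates = effects_estimates,
    spec = list(family = family, effects = effects,
                durbin_style = durbin_style),
    n_regions = n_regions, n_periods = n_periods),
    class = "spanel_fit")
}

# Shared concentrated-ML engine for SLM and SDM. `xlag_cols` is a matrix of
# extra regressors (spatially lagged covariates) already aligned with the
# panel ordering, or NULL for the plain SLM.
.fit_lag_family <- function(panel, W, outcome, covariates, effects, family,
                            durbin_style = NULL, xlag_raw = NULL, rho = NULL,
                            se = TRUE, boundary_tol = 1e-6) {
  .check_regions_match(panel, W)
  panel <- order_panel(panel)
  spectrum <- weights_spectrum(W)
  info <- check_panel_balance(panel)
  n <- length(info$regions); t_ <- length(info$years); nt <- n * t_
  w <- W$matrix

  # raw spatial lag of the outcome, then one common within transform
  aug <- panel
  aug$.wy <- .panel_lag(panel[[outcome]], w, n, t_)
  xl_names <- character(0)
  if (!is.null(xlag_raw)) {
    xl_names <- colnames(xlag_raw)
    for (cn in xl_names) aug[[cn]] <- xlag_raw[, cn]
  }
  tw <- within_transform(aug, outcome = outcome,
                         covariates = c(covariates, xl_names, ".wy"),
                         effects = effects)
  wy <- tw$X[, ".wy"]
  X <- tw$X[, setdiff(colnames(tw$X), ".wy"), drop = FALSE]
  y <- tw$y
  qd <- .check_full_rank(X)

  e0 <- qr.resid(qd, y)
  e1 <- qr.resid(qd, wy)
  b0 <- qr.coef(qd, y)
  b1 <- qr.coef(qd, wy)
  a0 <- sum(e0^2); a1 <- sum(e0 * e1); a2 <- sum(e1^2)

  lo <- 1 / min(spectrum)
  conc <- function(r) {
    ssr <- a0 - 2 * r * a1 + r^2 * a2
    -nt / 2 * (log(2 * pi) + 1) + t_ * sum(log(1 - r * spectrum)) -
      nt / 2 * log(ssr / nt)
  }
  if (is.null(rho)) {
    opt <- optimize(conc, interval = c(lo + 1e-6, 1 - 1e-6), maximum = TRUE,
                    tol = 1e-9)
    rho_hat <- opt$maximum
    if (rho_hat - (lo + 1e-6) < boundary_tol || (1 - 1e-6) - rho_hat < boundary_tol) {
      stop("spatial parameter estimate at the boundary of the admissible ",
           "interval: optimization did not converge to an interior optimum",
           call. = FALSE)
    }
  } else {
    if (rho != 0 && (rho <= lo || rho >= 1)) {
      stop("fixed rho outside the admissible interval", call. = FALSE)
    }
    rho_hat <- rho
  }
  beta <- b0 - rho_hat * b1
  ssr <- a0 - 2 * rho_hat * a1 + rho_hat^2 * a2
  sigma2 <- ssr / nt
  loglik <- conc(rho_hat)

  # standard errors: numerical Hessian of the full log-likelihood
  coefs <- NULL
  rho_entry <- c(estimate = rho_hat, std_error = NA_real_, z = NA_real_,
                 p_value = NA_real_)
  if (se) {
    k <- ncol(X)
    full_ll <- function(th) {
      r <- th[1L]; b <- th[2:(k + 1L)]; s2 <- th[k + 2L]
      if (r <= lo || r >= 1 || s2 <= 0) return(-Inf)
      resid <- y - r * wy - X %*% b
      -nt / 2 * log(2 * pi * s2) + t_ * sum(log(1 - r * spectrum)) -
        sum(resid^2) / (2 * s2)
    }
    th <- c(rho_hat, beta, sigma2)
    H <- .num_hessian(full_ll, th)
    vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, k + 2, k + 2))
    ses <- sqrt(pmax(diag(vc), 0))
    est <- c(beta, sigma2_e = sigma2)
    coefs <- .coef_table(stats::setNames(est, c(names(beta), "sigma2_e")),
                         c(ses[2:(k + 1L)], ses[k + 2L]))
    rho_entry <- c(estimate = rho_hat, std_error = ses[1L],
                   z = rho_hat / ses[1L],
                   p_value = 2 * pnorm(-abs(rho_hat / ses[1L])))
  } else {
    coefs <- .coef_table(stats::setNames(c(beta, sigma2), c(names(beta), "sigma2_e")),
                         rep(NA_real_, length(beta) + 1L))
  }

  # pseudo R^2: squared correlation of the reduced-form prediction with the
  # (transformed) outcome
  xb <- matrix(X %*% beta, nrow = n, ncol = t_)
  ainv <- solve(diag(n) - rho_hat * w)
  fitted <- as.vector(ainv %*% xb)
  pr2 <- if (stats::var(fitted) > 0) cor(y, fitted)^2 else 0

  # recovered effects from the raw-scale residual construct
  effs <- NULL
  if (effects != "pooled") {
    xr <- as.matrix(aug[, c(covariates, xl_names), drop = FALSE])
    rraw <- panel[[outcome]] - rho_hat * aug$.wy - as.vector(xr %*% beta[colnames(xr)])
    rm_ <- matrix(rraw, nrow = n, ncol = t_)
    effs <- list(mu = stats::setNames(rowMeans(rm_) - mean(rm_), info$regions),
                 gamma = if (effects == "twoway")
                   stats::setNames(colMeans(rm_) - mean(rm_), info$years) else NULL,
                 alpha = mean(rm_))
  }

  .new_fit(family, effects, durbin_style, coefs, rho = rho_entry,
           lambda = NULL, sigma2 = sigma2, loglik = loglik, pseudo_r2 = pr2,
           effects_estimates = effs, n_regions = n, n_periods = t_)
}

# ---- exported fitting functions ---------------------------------------------

#' Fit a fixed-effects Spatial Lag Model (SLM) by maximum likelihood
#'
#' The SLM makes the outcome of each region depend on the spatial lag of the
#' outcome in neighbouring regions:
#' \eqn{y_t = \rho W y_t + X_t\beta + \mu + \gamma_t 1 + \psi_t}. After the
#' within transformation, the scalar spatial parameter is estimated by
#' maximizing the concentrated log-likelihood
#' \deqn{\ell(\rho) = c + T\sum_i \ln(1-\rho\omega_i)
#'       - \frac{NT}{2}\ln\frac{SSR(\rho)}{NT},}
#' where \eqn{SSR(\rho)} comes from regressing \eqn{y - \rho Wy} on X.
#' Standard errors are taken from the numerical Hessian of the full
#' log-likelihood at the optimum.
#'
#' @param panel balanced panel data.frame with columns \code{region_id},
#'   \code{year}, the outcome and the covariates.
#' @param W row-standardized \code{spatial_weights} matching the panel's
#'   regions.
#' @param outcome,covariates column names.
#' @param effects \code{"twoway"} (default), \code{"individual"} or
#'   \code{"pooled"}.
#' @param rho \code{NULL} to estimate (default), or a number to hold the
#'   spatial parameter fixed (0 reduces the model to within-OLS).
#' @param se compute standard errors (set \code{FALSE} to skip the Hessian,
#'   e.g. in tight simulation loops).
#' @return An object of class \code{spanel_fit}.
#' @export
fit_slm <- function(panel, W, outcome = "respdeath",
                    covariates = c("pm25", "lngdp", "lnhos", "lncost",
                                   "popudens"),
                    effects = c("twoway", "individual", "pooled"),
                    rho = NULL, se = TRUE) {
  effects <- match.arg(effects)
  .fit_lag_family(panel, W, outcome, covariates, effects, family = "SLM",
                  rho = rho, se = se)
}

#' Fit a fixed-effects Spatial Durbin Model (SDM) by maximum likelihood
#'
#' The SDM augments the SLM with spatially lagged covariates. Two styles are
#' supported: \code{"per_covariate"} adds one lagged regressor (and one
#' coefficient) per covariate, the modern convention; \code{"common_scalar"}
#' adds the single regressor \eqn{W \sum_k x_{k}} with one coefficient
#' \eqn{\delta}, the form in which province-scale studies often report a
#' single Durbin term.
#'
#' @inheritParams fit_slm
#' @param durbin_style \code{"common_scalar"} (default) or
#'   \code{"per_covariate"}.
#' @return An object of class \code{spanel_fit}; Durbin coefficients appear
#'   in the coefficient table as \code{delta} (scalar style) or
#'   \code{W.<name>}.
#' @export
fit_sdm <- function(panel, W, outcome = "respdeath",
                    covariates = c("pm25", "lngdp", "lnhos", "lncost",
                                   "popudens"),
                    effects = c("twoway", "individual", "pooled"),
                    durbin_style = c("common_scalar", "per_covariate"),
                    rho = NULL, se = TRUE) {
  effects <- match.arg(effects)
  durbin_style <- match.arg(durbin_style)
  .check_regions_match(panel, W)
  panel <- order_panel(panel)
  info <- check_panel_balance(panel)
  n <- length(info$regions); t_ <- length(info$years)
  w <- W$matrix
  if (durbin_style == "common_scalar") {
    xsum <- rowSums(as.matrix(panel[, covariates, drop = FALSE]))
    xlag <- matrix(.panel_lag(xsum, w, n, t_), ncol = 1,
                   dimnames = list(NULL, "delta"))
  } else {
    xlag <- vapply(covariates,
                   function(cn) .panel_lag(panel[[cn]], w, n, t_),
                   numeric(n * t_))
    colnames(xlag) <- paste0("W.", covariates)
  }
  .fit_lag_family(panel, W, outcome, covariates, effects, family = "SDM",
                  durbin_style = durbin_style, xlag_raw = xlag, rho = rho,
                  se = se)
}

#' Fit a fixed-effects Spatial Error Model (SEM) by maximum likelihood
#'
#' The SEM puts the spatial dependence in the disturbances:
#' \eqn{y_t = X_t\beta + \mu + \gamma_t 1 + \varepsilon_t} with
#' \eqn{\varepsilon_t = \lambda M \varepsilon_t + \psi_t}. For each candidate
#' \eqn{\lambda} the within-transformed data are spatially filtered,
#' \eqn{y^* = y - \lambda My}, \eqn{X^* = X - \lambda MX}, and the
#' concentrated log-likelihood
#' \eqn{\ell(\lambda) = c + T\sum_i\ln(1-\lambda\omega_i)
#'      - (NT/2)\ln(SSR^*(\lambda)/NT)} is maximized.
#'
#' @inheritParams fit_slm
#' @param M weight matrix for the error process; defaults to \code{W}.
#' @param lambda \code{NULL} to estimate, or a number to hold fixed.
#' @return An object of class \code{spanel_fit}.
#' @export
fit_sem <- function(panel, W, outcome = "respdeath",
                    covariates = c("pm25", "lngdp", "lnhos", "lncost",
                                   "popudens"),
                    effects = c("twoway", "individual", "pooled"),
                    M = NULL, lambda = NULL, se = TRUE) {
  effects <- match.arg(effects)
  .check_regions_match(panel, W)
  panel <- order_panel(panel)
  if (is.null(M)) M <- W
  spectrum <- weights_spectrum(M)
  info <- check_panel_balance(panel)
  n <- length(info$regions); t_ <- length(info$years); nt <- n * t_
  m <- M$matrix

  # spatial lags on the raw data, then one common within transform: the
  # filtered fixed effects (I - lambda M) mu and (1 - lambda) gamma_t are
  # region- resp. period-constant, so demeaning the filtered data removes
  # them exactly
  aug <- panel
  aug$.my <- .panel_lag(panel[[outcome]], m, n, t_)
  mcols <- paste0(".m.", covariates)
  for (j in seq_along(covariates)) {
    aug[[mcols[j]]] <- .panel_lag(panel[[covariates[j]]], m, n, t_)
  }
  tw <- within_transform(aug, outcome = outcome,
                         covariates = c(covariates, mcols, ".my"),
                         effects = effects)
  y <- tw$y
  keep <- setdiff(colnames(tw$X), c(mcols, ".my"))
  X <- tw$X[, keep, drop = FALSE]
  .check_full_rank(X)
  my <- tw$X[, ".my"]
  mX <- tw$X[, c(if ("(Intercept)" %in% keep) NULL, mcols), drop = FALSE]
  # lagged intercept column for pooled fits: M 1 = 1
  if ("(Intercept)" %in% keep) {
    mX <- cbind(`(Intercept)` = 1, mX)
  }
  colnames(mX) <- keep

  lo <- 1 / min(spectrum)
  fit_at <- function(l) {
    ys <- y - l * my
    Xs <- X - l * mX
    b <- qr.coef(qr(Xs), ys)
    ssr <- sum((ys - Xs %*% b)^2)
    list(beta = b, ssr = ssr)
  }
  conc <- function(l) {
    ssr <- fit_at(l)$ssr
    -nt / 2 * (log(2 * pi) + 1) + t_ * sum(log(1 - l * spectrum)) -
      nt / 2 * log(ssr / nt)
  }
  if (is.null(lambda)) {
    opt <- optimize(conc, interval = c(lo + 1e-6, 1 - 1e-6), maximum = TRUE,
                    tol = 1e-9)
    lam_hat <- opt$maximum
    if (lam_hat - (lo + 1e-6) < 1e-6 || (1 - 1e-6) - lam_hat < 1e-6) {
      stop("spatial parameter estimate at the boundary of the admissible ",
           "interval: optimization did not converge to an interior optimum",
           call. = FALSE)
    }
  } else {
    if (lambda != 0 && (lambda <= lo || lambda >= 1)) {
      stop("fixed lambda outside the admissible interval", call. = FALSE)
    }
    lam_hat <- lambda
  }
  at <- fit_at(lam_hat)
  beta <- at$beta
  sigma2 <- at$ssr / nt
  loglik <- conc(lam_hat)

  lam_entry <- c(estimate = lam_hat, std_error = NA_real_, z = NA_real_,
                 p_value = NA_real_)
  if (se) {
    k <- ncol(X)
    full_ll <- function(th) {
      l <- th[1L]; b <- th[2:(k + 1L)]; s2 <- th[k + 2L]
      if (l <= lo || l >= 1 || s2 <= 0) return(-Inf)
      resid <- (y - l * my) - (X - l * mX) %*% b
      -nt / 2 * log(2 * pi * s2) + t_ * sum(log(1 - l * spectrum)) -
        sum(resid^2) / (2 * s2)
    }
    th <- c(lam_hat, beta, sigma2)
    H <- .num_hessian(full_ll, th)
    vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, k + 2, k + 2))
    ses <- sqrt(pmax(diag(vc), 0))
    coefs <- .coef_table(stats::setNames(c(beta, sigma2),
                                         c(names(beta), "sigma2_e")),
                         c(ses[2:(k + 1L)], ses[k + 2L]))
    lam_entry <- c(estimate = lam_hat, std_error = ses[1L],
                   z = lam_hat / ses[1L],
                   p_value = 2 * pnorm(-abs(lam_hat / ses[1L])))
  } else {
    coefs <- .coef_table(stats::setNames(c(beta, sigma2),
                                         c(names(beta), "sigma2_e")),
                         rep(NA_real_, length(beta) + 1L))
  }

  fitted <- as.vector(X %*% beta)
  pr2 <- if (stats::var(fitted) > 0) cor(y, fitted)^2 else 0

  effs <- NULL
  if (effects != "pooled") {
    xr <- as.matrix(panel[, covariates, drop = FALSE])
    rraw <- panel[[outcome]] - as.vector(xr %*% beta[colnames(xr)])
    rm_ <- matrix(rraw, nrow = n, ncol = t_)
    effs <- list(mu = stats::setNames(rowMeans(rm_) - mean(rm_), info$regions),
                 gamma = if (effects == "twoway")
                   stats::setNames(colMeans(rm_) - mean(rm_), info$years) else NULL,
                 alpha = mean(rm_))
  }

  .new_fit("SEM", effects, NULL, coefs, rho = NULL, lambda = lam_entry,
           sigma2 = sigma2, loglik = loglik, pseudo_r2 = pr2,
           effects_estimates = effs, n_regions = n, n_periods = t_)
}

#' Non-spatial least-squares baseline
#'
#' Pooled or within least squares with conventional standard errors, the
#' non-spatial comparison the spatial models are judged against. Under
#' spatial dependence its coefficient estimates are biased or inefficient,
#' which is the motivation for the ML spatial fits.
#'
#' @inheritParams fit_slm
#' @return An object of class \code{spanel_fit} with no spatial parameter.
#' @export
fit_ols <- function(panel, outcome = "respdeath",
                    covariates = c("pm25", "lngdp", "lnhos", "lncost",
                                   "popudens"),
                    effects = c("twoway", "individual", "pooled")) {
  effects <- match.arg(effects)
  panel <- order_panel(panel)
  tw <- within_transform(panel, outcome = outcome, covariates = covariates,
                         effects = effects)
  y <- tw$y; X <- tw$X
  qd <- .check_full_rank(X)
  beta <- qr.coef(qd, y)
  resid <- qr.resid(qd, y)
  nt <- length(y)
  dof <- nt - ncol(X) - tw$dof_correction
  s2_dof <- sum(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qd))
  ses <- sqrt(diag(XtXinv) * s2_dof)
  coefs <- .coef_table(beta, stats::setNames(ses, names(beta)))
  sigma2 <- sum(resid^2) / nt
  loglik <- -nt / 2 * (log(2 * pi * sigma2) + 1)
  fitted <- as.vector(X %*% beta)
  pr2 <- if (stats::var(fitted) > 0) cor(y, fitted)^2 else 0
  .new_fit("OLS", effects, NULL, coefs, rho = NULL, lambda = NULL,
           sigma2 = sigma2, loglik = loglik, pseudo_r2 = pr2,
           effects_estimates = NULL, n_regions = tw$n_regions,
           n_periods = tw$n_periods)
}

#' Side-by-side regression report
#'
#' Assembles one or more fitted models into the conventional comparison
#' layout of spatial regression tables: one row per coefficient plus rows
#' for the Durbin term, the spatial parameters, the residual variance and
#' the pseudo R-squared, and a (Coef., Z, p) column block per model. Cells a
#' model does not have are \code{NA}.
#'
#' @param fits a named list of \code{spanel_fit} objects (names become
#'   column-block labels; defaults to the model families).
#' @return A data.frame in the comparison layout.
#' @export
model_report <- function(fits) {
  if (inherits(fits, "spanel_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "spanel_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$spec$family, character(1))
  }
  terms <- unique(unlist(lapply(fits, function(f) {
    tt <- f$coefficients$term
    c(setdiff(tt, "sigma2_e"),
      if (!is.null(f$rho)) "rho", if (!is.null(f$lambda)) "lambda",
      "sigma2_e", "R2")
  })))
  # keep spatial/summary rows at the bottom in a stable order
  tail_rows <- intersect(c("delta", "rho", "lambda", "sigma2_e", "R2"), terms)
  terms <- c(setdiff(terms, tail_rows), tail_rows)
  out <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    coef_col <- z_col <- p_col <- rep(NA_real_, length(terms))
    ct <- f$coefficients
    for (r in seq_len(nrow(ct))) {
      k <- match(ct$term[r], terms)
      coef_col[k] <- ct$estimate[r]; z_col[k] <- ct$z[r]; p_col[k] <- ct$p_value[r]
    }
    if (!is.null(f$rho)) {
      k <- match("rho", terms)
      coef_col[k] <- f$rho[["estimate"]]; z_col[k] <- f$rho[["z"]]
      p_col[k] <- f$rho[["p_value"]]
    }
    if (!is.null(f$lambda)) {
      k <- match("lambda", terms)
      coef_col[k] <- f$lambda[["estimate"]]; z_col[k] <- f$lambda[["z"]]
      p_col[k] <- f$lambda[["p_value"]]
    }
    coef_col[match("R2", terms)] <- f$pseudo_r2
    out[[paste0(nm, ".coef")]] <- coef_col
    out[[paste0(nm, ".z")]] <- z_col
    out[[paste0(nm, ".p")]] <- p_col
  }
  out
}

#' @export
print.spanel_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s panel fit (%s effects): N = %d regions, T = %d periods\n",
              x$spec$family, x$spec$effects, x$n_regions, x$n_periods))
  if (!is.null(x$rho)) {
    cat(sprintf("  rho    = %s (z = %s)\n",
                format(x$rho[["estimate"]], digits = digits),
                format(x$rho[["z"]], digits = 3)))
  }
  if (!is.null(x$lambda)) {
    cat(sprintf("  lambda = %s (z = %s)\n",
                format(x$lambda[["estimate"]], digits = digits),
                format(x$lambda[["z"]], digits = 3)))
  }
  ct <- x$coefficients
  for (r in seq_len(nrow(ct))) {
    cat(sprintf("  %-12s % .4f  (se %s, p %s)\n", ct$term[r], ct$estimate[r],
                format(ct$std_error[r], digits = 3),
                format(ct$p_value[r], digits = 3)))
  }
  cat(sprintf("  logLik = %s, pseudo R2 = %s\n",
              format(x$log_likelihood, digits = 6),
              format(x$pseudo_r2, digits = 3)))
  invisible(x)
}
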