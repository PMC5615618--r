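#' Global Moran's I
#'
#' The cross-product statistic of global spatial autocorrelation,
#' \deqn{I = \frac{\sum_i\sum_j w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'            {S^2 \sum_i\sum_j w_{ij}},}
#' with \eqn{S^2 = n^{-1}\sum_i (x_i-\bar x)^2} the population-style sample
#' variance. Values near +1 indicate clustering of similar values, values
#' near -1 indicate checkerboard-like dispersion, and the null expectation
#' under spatial randomness is \eqn{-1/(n-1)}.
#'
#' @param x numeric vector of region observations, length n >= 3.
#' @param W a \code{spatial_weights} object (binary or row-standardized;
#'   row-standardized is the conventional working form).
#' @return An object of class \code{moran_result} carrying the statistic and
#'   the sample moments; inference fields are \code{NA} until
#'   \code{\link{moran_inference}} fills them.
#' @examples
#' W <- contiguity_weights(china_adjacency())
#' global_morans_i(rnorm(31), W)$statistic
#' @export
global_morans_i <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  w <- W$matrix
  n <- nrow(w)
  if (length(x) != n) {
    stop("length(x) = ", length(x), " does not match the ", n, " regions of W",
         call. = FALSE)
  }
  if (n < 3L) stop("Moran's I requires at least 3 regions", call. = FALSE)
  if (any(w < 0)) stop("negative spatial weights are not allowed", call. = FALSE)
  xbar <- mean(x)
  z <- x - xbar
  s2 <- sum(z^2) / n
  if (s2 == 0) {
    stop("degenerate input: x is constant (zero spatial sample variance)",
         call. = FALSE)
  }
  s0 <- sum(w)
  stat <- as.numeric(crossprod(z, w %*% z)) / (s2 * s0)
  structure(
    list(statistic = stat, n = n, sample_mean = xbar, sample_variance = s2,
         expected_null = -1 / (n - 1), variance_null = NA_real_,
         z_score = NA_real_, p_value = NA_real_,
         inference_method = NA_character_),
    class = "moran_result")
}

#' Inference for global Moran's I
#'
#' Fills the null variance, z-score and p-value of a Moran test. The default
#' \code{"normal_randomization"} method uses the exact first two moments of I
#' under random permutation of the observations (the randomization
#' assumption, with its kurtosis correction) and refers
#' \eqn{z = (I - E[I])/\sqrt{Var[I]}} to the standard normal; the
#' \code{"permutation"} method computes a pseudo p-value from seeded random
#' permutations. Two-sided p-values are reported in both cases.
#'
#' @param x numeric vector of region observations.
#' @param W a \code{spatial_weights} object.
#' @param method \code{"normal_randomization"} (default) or
#'   \code{"permutation"}.
#' @param n_permutations number of random permutations (permutation method
#'   only, at least 99).
#' @param seed integer seed (required by the permutation method).
#' @return A completed \code{moran_result}.
#' @export
moran_inference <- function(x, W,
                            method = c("normal_randomization", "permutation"),
                            n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  res <- global_morans_i(x, W)
  w <- W$matrix
  n <- res$n
  e_i <- res$expected_null
  if (method == "normal_randomization") {
    if (n < 4L) {
      stop("normal_randomization requires n >= 4 (kurtosis correction undefined)",
           call. = FALSE)
    }
    z <- x - res$sample_mean
    s0 <- sum(w)
    s1 <- 0.5 * sum((w + t(w))^2)
    s2 <- sum((rowSums(w) + colSums(w))^2)
    b2 <- n * sum(z^4) / (sum(z^2)^2)
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
    res$variance_null <- var_i
    res$z_score <- (res$statistic - e_i) / sqrt(var_i)
    res$p_value <- 2 * pnorm(-abs(res$z_score))
    res$inference_method <- "normal_randomization"
  } else {
    if (n_permutations < 99L) {
      stop("permutation inference requires n_permutations >= 99", call. = FALSE)
    }
    if (is.null(seed)) stop("permutation inference requires a seed", call. = FALSE)
    set.seed(seed)
    perm_i <- vapply(seq_len(n_permutations), function(b) {
      global_morans_i(sample(x), W)$statistic
    }, numeric(1))
    res$variance_null <- sum((perm_i - e_i)^2) / n_permutations
    res$z_score <- (res$statistic - e_i) / sqrt(res$variance_null)
    extreme <- sum(abs(perm_i - e_i) >= abs(res$statistic - e_i))
    res$p_value <- (extreme + 1) / (n_permutations + 1)
    res$inference_method <- "permutation"
  }
  res
}

#' Moran scatterplot quadrant classification
#'
#' Standardizes the observations to zero mean and unit (population) variance,
#' computes their spatial lag, and labels every region by the quadrant of the
#' Moran scatterplot it occupies: HH (high value, high-lag neighbourhood),
#' LH (low among highs), LL (low among lows) and HL (high among lows).
#' "High" means strictly positive standardized value; exact zeros fall on
#' the low side.
#'
#' @param x numeric vector of region observations.
#' @param W a row-standardized \code{spatial_weights} object.
#' @return An object of class \code{quadrant_classification} with components
#'   \code{labels} (named character vector), \code{counts} (table over HH,
#'   LH, LL, HL), \code{standardized_values}, \code{spatial_lags}.
#' @export
quadrant_classify <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "row_standardized") {
    stop("quadrant_classify expects a row-standardized W", call. = FALSE)
  }
  n <- nrow(W$matrix)
  if (length(x) != n) stop("length(x) does not match W", call. = FALSE)
  s <- sqrt(sum((x - mean(x))^2) / n)
  if (s == 0) stop("degenerate input: x is constant", call. = FALSE)
  z <- (x - mean(x)) / s
  lag <- spatial_lag(W, z)
  labels <- ifelse(z > 0 & lag > 0, "HH",
            ifelse(z <= 0 & lag > 0, "LH",
            ifelse(z > 0 & lag <= 0, "HL", "LL")))
  names(labels) <- W$region_order
  counts <- c(HH = sum(labels == "HH"), LH = sum(labels == "LH"),
              LL = sum(labels == "LL"), HL = sum(labels == "HL"))
  structure(list(labels = labels, counts = counts,
                 standardized_values = stats::setNames(z, W$region_order),
                 spatial_lags = stats::setNames(lag, W$region_order)),
            class = "quadrant_classification")
}

#' Per-year global Moran's I for a panel variable
#'
#' Applies the global Moran test year by year to one variable of a balanced
#' panel, producing the familiar year-by-year autocorrelation table of
#' exploratory spatial panel analysis.
#'
#' @param panel balanced panel data.frame with columns \code{region_id},
#'   \code{year} and the named variable.
#' @param variable name of the panel column to test.
#' @param W a \code{spatial_weights} object whose \code{region_order} matches
#'   the panel's region ids.
#' @param method,n_permutations,seed passed to \code{\link{moran_inference}}.
#' @return data.frame with columns \code{year}, \code{moran_i}, \code{z},
#'   \code{p_value}.
#' @export
moran_by_year <- function(panel, variable, W,
                          method = "normal_randomization",
                          n_permutations = 999, seed = NULL) {
  check_panel_balance(panel)
  if (!variable %in% names(panel)) {
    stop("panel has no column '", variable, "'", call. = FALSE)
  }
  years <- sort(unique(panel$year))
  rows <- lapply(seq_along(years), function(k) {
    yr <- years[k]
    slab <- panel[panel$year == yr, ]
    slab <- slab[match(W$region_order, slab$region_id), ]
    if (anyNA(slab$region_id)) {
      stop("year ", yr, " is missing regions present in W", call. = FALSE)
    }
    res <- moran_inference(slab[[variable]], W, method = method,
                           n_permutations = n_permutations,
                           seed = if (is.null(seed)) NULL else seed + k)
    data.frame(year = yr, moran_i = res$statistic, z = res$z_score,
               p_value = res$p_value)
  })
  do.call(rbind, rows)
}

#' @export
print.moran_result <- function(x, digits = 4, ...) {
  cat("Global Moran's I =", format(x$statistic, digits = digits),
      " (n =", x$n, ", E[I] =", format(x$expected_null, digits = digits), ")\n")
  if (!is.na(x$p_value)) {
    cat("  ", x$inference_method, ": z =", format(x$z_score, digits = digits),
        ", p =", format(x$p_value, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
print.quadrant_classification <- function(x, ...) {
  cat("Moran scatterplot quadrants:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}
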