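#' Check that a panel is balanced
#'
#' A balanced panel has every region observed in every year exactly once.
#'
#' @param panel data.frame with columns \code{region_id} and \code{year}.
#' @return Invisibly, a list with \code{regions} and \code{years} in sorted
#'   order; errors when the panel is unbalanced.
#' @export
check_panel_balance <- function(panel) {
  if (!all(c("region_id", "year") %in% names(panel))) {
    stop("panel must have columns region_id and year", call. = FALSE)
  }
  regions <- sort(unique(panel$region_id))
  years <- sort(unique(panel$year))
  tab <- table(panel$region_id, panel$year)
  if (nrow(panel) != length(regions) * length(years) || any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    lab <- if (nrow(bad)) {
      paste0(rownames(tab)[bad[1L, 1L]], "/", colnames(tab)[bad[1L, 2L]])
    } else "duplicated rows"
    stop("unbalanced panel: first offending region/year cell: ", lab,
         call. = FALSE)
  }
  invisible(list(regions = regions, years = years))
}

#' Order a panel region-major within period
#'
#' All estimation code assumes observations sorted by year, then by region
#' id, so that each consecutive block of N rows is one cross-section.
#'
#' @param panel balanced panel data.frame.
#' @return The reordered data.frame.
#' @export
order_panel <- function(panel) {
  check_panel_balance(panel)
  panel[order(panel$year, panel$region_id), , drop = FALSE]
}

#' Within (fixed-effects) transformation of a balanced panel
#'
#' Removes unobserved region and/or period effects by demeaning:
#' \code{"individual"} subtracts region means over time, \code{"twoway"}
#' additionally subtracts period means and adds back the grand mean, and
#' \code{"pooled"} leaves the data untouched but prepends an intercept
#' column. The returned degrees-of-freedom correction counts the absorbed
#' effect parameters.
#'
#' @param panel balanced panel data.frame, region-major within period (use
#'   \code{\link{order_panel}}).
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @param effects \code{"twoway"} (default), \code{"individual"} or
#'   \code{"pooled"}.
#' @return list with \code{y} (length NT), \code{X} (NT x k matrix),
#'   \code{dof_correction} (integer), \code{n_regions}, \code{n_periods}.
#' @export
within_transform <- function(panel, outcome = "respdeath",
                             covariates = c("pm25", "lngdp", "lnhos",
                                            "lncost", "popudens"),
                             effects = c("twoway", "individual", "pooled")) {
  effects <- match.arg(effects)
  info <- check_panel_balance(panel)
  panel <- order_panel(panel)
  missing_cols <- setdiff(c(outcome, covariates), names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- length(info$regions)
  t_ <- length(info$years)
  demean <- function(v) {
    m <- matrix(v, nrow = n, ncol = t_)  # regions x periods
    switch(effects,
      pooled = v,
      individual = as.vector(m - rowMeans(m)),
      twoway = as.vector(m - rowMeans(m) -
                           matrix(colMeans(m), n, t_, byrow = TRUE) + mean(m)))
  }
  y <- demean(panel[[outcome]])
  X <- vapply(covariates, function(cn) demean(panel[[cn]]), numeric(n * t_))
  X <- matrix(X, nrow = n * t_, dimnames = list(NULL, covariates))
  if (effects == "pooled") {
    X <- cbind(`(Intercept)` = 1, X)
  }
  dof <- switch(effects, pooled = 0L, individual = n - 1L,
                twoway = n + t_ - 2L)
  list(y = y, X = X, dof_correction = dof, n_regions = n, n_periods = t_)
}
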