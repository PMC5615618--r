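#' Log-transform the raw scale covariates of a panel
#'
#' Applies the natural logarithm to the configured raw columns (by default
#' per-capita GDP, medical expenses and hospital counts) and renames them
#' with the conventional \code{ln} prefix. PM2.5 and population density are
#' left on their raw scales.
#'
#' @param panel data.frame carrying the raw columns.
#' @param log_transform character vector of raw column names to log.
#' @return The panel with logged, renamed columns.
#' @export
apply_transforms <- function(panel, log_transform = c("gdp", "cost", "hos")) {
  for (cn in log_transform) {
    if (!cn %in% names(panel)) {
      stop("panel has no column '", cn, "' to log-transform", call. = FALSE)
    }
    bad <- which(panel[[cn]] <= 0)
    if (length(bad)) {
      stop("non-positive value in log column '", cn, "' at region ",
           panel$region_id[bad[1L]], ", year ", panel$year[bad[1L]],
           call. = FALSE)
    }
    panel[[paste0("ln", cn)]] <- log(panel[[cn]])
    panel[[cn]] <- NULL
  }
  panel
}

#' Analysis configuration
#'
#' Collects the settings of the end-to-end pipeline: data sources (or
#' in-memory objects supplied to \code{\link{run_full_analysis}} directly),
#' which raw columns to log, the Moran inference method, the model set and
#' effects treatment, the master seed and the output directory.
#'
#' @param panel_path,adjacency_path file paths (CSV panel; adjacency table
#'   or GAL file), or \code{NULL} when objects are passed directly.
#' @param log_transform raw columns to log-transform (empty vector if the
#'   panel already carries \code{lngdp} etc.).
#' @param moran_method,n_permutations Moran inference settings.
#' @param models subset of \code{c("SDM", "SLM", "SEM", "OLS")}.
#' @param effects effects treatment for the model fits.
#' @param seed master seed.
#' @param output_dir directory for the CSV/JSON artifacts, or \code{NULL}
#'   to return results in memory only.
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(panel_path = NULL, adjacency_path = NULL,
                            log_transform = character(0),
                            moran_method = "normal_randomization",
                            n_permutations = 999,
                            models = c("SDM", "SLM", "SEM", "OLS"),
                            effects = "twoway", seed = 1L,
                            output_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (length(models) == 0L) stop("models must be non-empty", call. = FALSE)
  for (p in c(panel_path, adjacency_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(panel_path = panel_path, adjacency_path = adjacency_path,
                 log_transform = log_transform, moran_method = moran_method,
                 n_permutations = n_permutations, models = models,
                 effects = effects, seed = seed, output_dir = output_dir),
            class = "analysis_config")
}

# 32-bit FNV-1a hash of a string, as 8 hex digits; used to stamp outputs
# with a fingerprint of the configuration.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)  # xor touches low byte only
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full spatial analysis pipeline
#'
#' Orchestrates the complete workflow on a balanced province panel:
#' descriptive statistics, per-year global Moran's I for the outcome and
#' PM2.5, Moran-scatterplot quadrant classification of the period-averaged
#' outcome and PM2.5, estimation of the configured model set, and a
#' machine-readable run log (seed, configuration hash, package version).
#' When \code{output_dir} is set, each table is written as CSV plus a JSON
#' sidecar for the log; a failure in any stage removes the partial outputs
#' and aborts with the stage name.
#'
#' @param config an \code{analysis_config}.
#' @param panel optional in-memory panel (overrides \code{panel_path}).
#' @param adj optional in-memory \code{adjacency_list} (overrides
#'   \code{adjacency_path}); defaults to the packaged China graph when
#'   neither is given.
#' @return A list with components \code{descriptives}, \code{moran},
#'   \code{quadrants}, \code{models} (a \code{\link{model_report}} table),
#'   \code{fits} and \code{log}.
#' @export
run_full_analysis <- function(config, panel = NULL, adj = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  written <- character(0)
  emit <- function(name, df) {
    if (!is.null(config$output_dir)) {
      if (!dir.exists(config$output_dir)) {
        dir.create(config$output_dir, recursive = TRUE)
      }
      path <- file.path(config$output_dir, paste0(name, ".csv"))
      write.csv(df, path, row.names = FALSE)
      written <<- c(written, path)
    }
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  # ---- load ----
  out <- list()
  panel <- stage("load", {
    if (is.null(panel)) {
      if (is.null(config$panel_path)) stop("no panel supplied")
      read.csv(config$panel_path, stringsAsFactors = FALSE)
    } else panel
  })
  adj <- stage("load", {
    if (!is.null(adj)) adj
    else if (!is.null(config$adjacency_path)) {
      if (grepl("\\.gal$", config$adjacency_path, ignore.case = TRUE)) {
        read_gal(config$adjacency_path)
      } else {
        parse_adjacency_table(config$adjacency_path)
      }
    } else china_adjacency()
  })
  W <- stage("weights", contiguity_weights(adj))
  panel <- stage("transform", {
    p <- apply_transforms(panel, config$log_transform)
    order_panel(p)
  })

  covars <- c("pm25", "lngdp", "lnhos", "lncost", "popudens")
  vars <- c("respdeath", covars)

  out$descriptives <- stage("descriptives", {
    do.call(rbind, lapply(vars, function(v) {
      x <- panel[[v]]
      data.frame(variable = v, obs = length(x), mean = mean(x), sd = sd(x),
                 min = min(x), max = max(x), stringsAsFactors = FALSE)
    }))
  })
  emit("descriptives", out$descriptives)

  out$moran <- stage("moran", {
    tabs <- lapply(c("respdeath", "pm25"), function(v) {
      tb <- moran_by_year(panel, v, W, method = config$moran_method,
                          n_permutations = config$n_permutations,
                          seed = config$seed)
      cbind(variable = v, tb)
    })
    do.call(rbind, tabs)
  })
  emit("moran_by_year", out$moran)

  out$quadrants <- stage("quadrants", {
    tabs <- lapply(c("respdeath", "pm25"), function(v) {
      avg <- tapply(panel[[v]], panel$region_id, mean)
      avg <- avg[as.character(W$region_order)]
      qc <- quadrant_classify(as.numeric(avg), W)
      data.frame(variable = v, region_id = W$region_order,
                 standardized = unname(qc$standardized_values),
                 spatial_lag = unname(qc$spatial_lags),
                 quadrant = unname(qc$labels), stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
  emit("quadrants", out$quadrants)

  out$fits <- stage("models", {
    fits <- list()
    for (mdl in config$models) {
      fits[[mdl]] <- switch(mdl,
        SDM = fit_sdm(panel, W, covariates = covars, effects = config$effects),
        SLM = fit_slm(panel, W, covariates = covars, effects = config$effects),
        SEM = fit_sem(panel, W, covariates = covars, effects = config$effects),
        OLS = fit_ols(panel, covariates = covars, effects = config$effects))
    }
    fits
  })
  out$models <- stage("models", model_report(out$fits))
  emit("model_comparison", out$models)

  out$log <- stage("log", {
    cfg_string <- paste(deparse(config[setdiff(names(config), "output_dir")]),
                        collapse = "")
    list(seed = config$seed, config_hash = .fnv1a(cfg_string),
         package_version = as.character(packageVersion("spanel")),
         models = config$models, effects = config$effects,
         moran_method = config$moran_method,
         n_regions = length(W$region_order),
         n_periods = length(unique(panel$year)))
  })
  if (!is.null(config$output_dir)) {
    path <- file.path(config$output_dir, "run_log.json")
    jsonlite::write_json(out$log, path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, path)
  }
  out
}
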