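#' Build a binary Rook-contiguity weight matrix
#'
#' Converts a validated adjacency list into the binary spatial weight matrix
#' of the Rook rule: entry (i, j) is 1 when regions i and j are adjacent and
#' 0 otherwise, with a zero diagonal. Rows and columns follow the numeric
#' region order of the adjacency list. A region with no neighbours (an
#' island) is an error: islands make the matrix non-standardizable and, in a
#' curated table, signal bad input rather than a modelling choice.
#'
#' @param adj an \code{adjacency_list}.
#' @return An object of class \code{spatial_weights} with components
#'   \code{matrix}, \code{style} (\code{"binary"}), \code{region_order} and
#'   \code{spectrum} (\code{NULL} until computed).
#' @examples
#' W <- build_binary_weights(china_adjacency())
#' sum(W$matrix)  # 140 directed contiguities
#' @export
build_binary_weights <- function(adj) {
  validate_adjacency(adj)
  numbers <- adj$regions$number
  ord <- order(numbers)
  numbers <- numbers[ord]
  n <- length(numbers)
  isolated <- numbers[vapply(as.character(numbers),
                             function(k) length(adj$neighbors[[k]]) == 0L,
                             logical(1))]
  if (length(isolated)) {
    stop("island region(s) with no neighbors: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  idx <- seq_len(n)
  names(idx) <- numbers
  m <- matrix(0, n, n, dimnames = list(numbers, numbers))
  for (i in numbers) {
    m[idx[as.character(i)], idx[as.character(adj$neighbors[[as.character(i)]])]] <- 1
  }
  structure(list(matrix = m, style = "binary", region_order = numbers,
                 spectrum = NULL),
            class = "spatial_weights")
}

#' Row-standardize a binary weight matrix
#'
#' Divides each row by its row sum so the spatial lag operator becomes an
#' average over neighbours. Rows of a standardized matrix sum to one; the
#' zero pattern is unchanged.
#'
#' @param W a \code{spatial_weights} object with \code{style = "binary"}.
#' @return A \code{spatial_weights} object with \code{style =
#'   "row_standardized"} and the eigenvalue spectrum precomputed.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "binary") {
    stop("row_standardize expects a binary-style weights object", call. = FALSE)
  }
  rs <- rowSums(W$matrix)
  if (any(rs == 0)) {
    stop("island region(s) with zero row sum: ",
         paste(W$region_order[rs == 0], collapse = ", "), call. = FALSE)
  }
  out <- W
  out$matrix <- W$matrix / rs
  out$style <- "row_standardized"
  out$spectrum <- weights_spectrum(out)
  out
}

#' Eigenvalue spectrum of a standardized weight matrix
#'
#' Returns all eigenvalues of the row-standardized matrix, sorted ascending.
#' When the binary base is symmetric, the standardized matrix D^-1 B is
#' similar to the symmetric matrix D^-1/2 B D^-1/2, so the spectrum is real
#' and is computed through the symmetric eigenproblem for numerical
#' stability. The largest eigenvalue of a row-stochastic matrix is 1; the
#' interval (1/min(spectrum), 1) is the admissible range for the spatial
#' parameters of the likelihoods.
#'
#' @param W a \code{spatial_weights} object, \code{style = "row_standardized"}.
#' @param tol tolerance on imaginary parts when the base is not symmetric.
#' @return Numeric vector of n eigenvalues, ascending.
#' @export
weights_spectrum <- function(W, tol = 1e-8) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "row_standardized") {
    stop("weights_spectrum expects a row-standardized weights object",
         call. = FALSE)
  }
  if (!is.null(W$spectrum)) return(W$spectrum)
  m <- W$matrix
  rs <- rowSums(m)
  # recover the binary base: standardized row i is base row / rs_i
  base <- m * rs  # only valid if base was 0/1; check symmetry of the result
  if (isTRUE(all.equal(base, t(base), tolerance = 1e-10))) {
    d <- rowSums(base)
    s <- 1 / sqrt(d)
    sym <- base * outer(s, s)
    ev <- eigen((sym + t(sym)) / 2, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(m, only.values = TRUE)$values
    if (any(abs(Im(ev)) > tol)) {
      stop("complex eigenvalues beyond tolerance: weight matrix base is not symmetric",
           call. = FALSE)
    }
    ev <- Re(ev)
  }
  sort(ev)
}

#' Spatial lag of a vector
#'
#' Computes W x, the vector whose i-th entry is the weighted combination of
#' the values of region i's neighbours. Under a row-standardized W this is
#' the neighbour average.
#'
#' @param W a \code{spatial_weights} object.
#' @param x numeric vector of length n (the number of regions).
#' @return Numeric vector of length n.
#' @export
spatial_lag <- function(W, x) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(x) != nrow(W$matrix)) {
    stop("length(x) = ", length(x), " does not match the ", nrow(W$matrix),
         " regions of W", call. = FALSE)
  }
  as.vector(W$matrix %*% x)
}

#' Build a row-standardized contiguity matrix in one step
#'
#' Convenience wrapper: binary Rook weights from the adjacency list, then
#' row standardization with the spectrum cached.
#'
#' @param adj an \code{adjacency_list}.
#' @return A row-standardized \code{spatial_weights} object.
#' @export
contiguity_weights <- function(adj) {
  row_standardize(build_binary_weights(adj))
}

#' @export
print.spatial_weights <- function(x, ...) {
  n <- nrow(x$matrix)
  cat("Spatial weights:", n, "x", n, sprintf("(%s)", x$style),
      "-", sum(x$matrix != 0), "nonzero entries\n")
  invisible(x)
}
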