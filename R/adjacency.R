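#' Parse a printed adjacency table into an adjacency list
#'
#' Reads a whitespace-delimited region adjacency table with one record per
#' region: a numeric region code, a region name (no embedded whitespace), and
#' zero or more neighbour codes. Lines starting with \code{#} and blank lines
#' are ignored. The result is validated: codes must be unique, every
#' neighbour code must refer to a listed region, no region may neighbour
#' itself, and the neighbour relation must be symmetric.
#'
#' @param source path to a file, or a character vector of lines.
#' @return An object of class \code{adjacency_list} with components
#'   \code{regions} (data.frame with columns \code{number}, \code{name}) and
#'   \code{neighbors} (named list of integer vectors, keyed by region number).
#' @examples
#' adj <- parse_adjacency_table(c("1 A 2", "2 B 1 3", "3 C 2"))
#' adj$neighbors[["2"]]
#' @export
parse_adjacency_table <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("adjacency table is empty", call. = FALSE)
  }
  tok <- strsplit(lines, "[ \t]+")
  numbers <- vapply(tok, function(t) suppressWarnings(as.integer(t[1L])), integer(1))
  if (anyNA(numbers)) {
    stop("malformed record: region number is not an integer", call. = FALSE)
  }
  if (anyDuplicated(numbers)) {
    stop("duplicate region number: ",
         paste(unique(numbers[duplicated(numbers)]), collapse = ", "),
         call. = FALSE)
  }
  names_ <- vapply(tok, function(t) {
    if (length(t) < 2L) stop("malformed record: missing region name", call. = FALSE)
    t[2L]
  }, character(1))
  neighbors <- lapply(tok, function(t) {
    nb <- suppressWarnings(as.integer(t[-(1:2)]))
    if (anyNA(nb)) stop("malformed record: non-integer neighbor code", call. = FALSE)
    sort(unique(nb))
  })
  names(neighbors) <- numbers
  adj <- structure(
    list(regions = data.frame(number = numbers, name = names_,
                              stringsAsFactors = FALSE),
         neighbors = neighbors),
    class = "adjacency_list")
  validate_adjacency(adj)
  adj
}

#' Validate an adjacency list
#'
#' Checks referential integrity (every neighbour code names a listed region),
#' irreflexivity (no region is its own neighbour) and symmetry of the
#' neighbour relation. Violations raise errors naming the offending regions.
#'
#' @param adj an \code{adjacency_list}.
#' @return \code{adj}, invisibly, if valid.
#' @export
validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "adjacency_list"))
  numbers <- adj$regions$number
  for (i in numbers) {
    key <- as.character(i)
    nb <- adj$neighbors[[key]]
    if (i %in% nb) {
      stop("region ", i, " lists itself as a neighbor", call. = FALSE)
    }
    unknown <- setdiff(nb, numbers)
    if (length(unknown)) {
      stop("region ", i, " references unknown neighbor code(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (i in numbers) {
    for (j in adj$neighbors[[as.character(i)]]) {
      if (!(i %in% adj$neighbors[[as.character(j)]])) {
        stop("asymmetric adjacency: region ", i, " lists ", j,
             " but region ", j, " does not list ", i, call. = FALSE)
      }
    }
  }
  invisible(adj)
}

#' The 31-province China contiguity fixture
#'
#' Returns the packaged Rook-contiguity adjacency list for the 31 provinces,
#' autonomous regions and municipalities of mainland China, with the island
#' province Hainan assigned its nearest neighbour Guangdong so that the
#' weight matrix has no zero rows. The table is part of the package data, not
#' derived from geometry at run time.
#'
#' @return An \code{adjacency_list} with 31 regions.
#' @examples
#' adj <- china_adjacency()
#' adj$neighbors[["21"]]  # Hainan -> Guangdong
#' @export
china_adjacency <- function() {
  path <- system.file("extdata", "china_adjacency.txt", package = "spanel",
                      mustWork = TRUE)
  parse_adjacency_table(path)
}

#' Write an adjacency list in GAL contiguity format
#'
#' GAL is the plain-text contiguity interchange format used by spatial
#' econometrics tools: a header line with the region count, then for each
#' region a line \code{"<id> <n_neighbors>"} followed by a line listing the
#' neighbour ids.
#'
#' @param adj an \code{adjacency_list}.
#' @param path output file path; if \code{NULL}, the lines are returned as a
#'   character vector.
#' @return The GAL lines, invisibly when written to a file.
#' @export
write_gal <- function(adj, path = NULL) {
  validate_adjacency(adj)
  n <- nrow(adj$regions)
  if (n == 0L) stop("empty region set", call. = FALSE)
  out <- character(1L + 2L * n)
  out[1L] <- as.character(n)
  k <- 2L
  for (i in adj$regions$number) {
    nb <- adj$neighbors[[as.character(i)]]
    out[k] <- paste(i, length(nb))
    out[k + 1L] <- paste(nb, collapse = " ")
    k <- k + 2L
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' Read a GAL contiguity file into an adjacency list
#'
#' Region names are not part of the GAL format; they are synthesised as
#' \code{"region_<id>"} unless a lookup table is supplied.
#'
#' @param source path to a GAL file or a character vector of GAL lines.
#' @param region_names optional named character vector mapping region number
#'   to name.
#' @return An \code{adjacency_list}.
#' @export
read_gal <- function(source, region_names = NULL) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty GAL input", call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(lines[1L], "[ \t]+")[[1L]][1L]))
  if (is.na(n) || n < 1L) stop("malformed GAL header", call. = FALSE)
  if (length(lines) != 1L + 2L * n) {
    stop("GAL body has ", length(lines) - 1L, " lines, expected ", 2L * n,
         call. = FALSE)
  }
  numbers <- integer(n)
  neighbors <- vector("list", n)
  for (r in seq_len(n)) {
    hdr <- as.integer(strsplit(lines[2L * r], "[ \t]+")[[1L]])
    if (length(hdr) != 2L || anyNA(hdr)) stop("malformed GAL record line ", 2L * r, call. = FALSE)
    nb <- if (hdr[2L] == 0L) integer(0) else as.integer(strsplit(lines[2L * r + 1L], "[ \t]+")[[1L]])
    if (length(nb) != hdr[2L] || anyNA(nb)) {
      stop("GAL neighbor count mismatch for region ", hdr[1L], call. = FALSE)
    }
    numbers[r] <- hdr[1L]
    neighbors[[r]] <- sort(unique(nb))
  }
  names(neighbors) <- numbers
  nm <- if (is.null(region_names)) paste0("region_", numbers) else unname(region_names[as.character(numbers)])
  adj <- structure(
    list(regions = data.frame(number = numbers, name = nm,
                              stringsAsFactors = FALSE),
         neighbors = neighbors),
    class = "adjacency_list")
  validate_adjacency(adj)
  adj
}

#' @export
print.adjacency_list <- function(x, ...) {
  cat("Adjacency list:", nrow(x$regions), "regions,",
      sum(lengths(x$neighbors)) / 2, "undirected edges\n")
  invisible(x)
}
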