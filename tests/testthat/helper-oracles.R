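# Shared fixtures and independent oracles for the test suite.

# ring graph on n regions (each region adjacent to its two cyclic neighbours)
ring_adjacency <- function(n) {
  lines <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) n else i - 1L
    right <- if (i == n) 1L else i + 1L
    paste(i, paste0("r", i), min(left, right), max(left, right))
  }, character(1))
  parse_adjacency_table(lines)
}

# two regions, mutually adjacent
pair_adjacency <- function() parse_adjacency_table(c("1 A 2", "2 B 1"))

# ring plus a few random chords: connected, symmetric, no islands
random_adjacency <- function(n, extra = n %/% 2, seed = 1) {
  set.seed(seed)
  nb <- lapply(seq_len(n), function(i) {
    c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)
  })
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    if (abs(ij[1] - ij[2]) > 1) {
      nb[[ij[1]]] <- union(nb[[ij[1]]], ij[2])
      nb[[ij[2]]] <- union(nb[[ij[2]]], ij[1])
    }
  }
  lines <- vapply(seq_len(n), function(i) {
    paste(i, paste0("r", i), paste(sort(nb[[i]]), collapse = " "))
  }, character(1))
  parse_adjacency_table(lines)
}

# naive double-sum evaluation of the global Moran statistic
naive_moran <- function(x, w) {
  n <- length(x)
  xbar <- mean(x)
  s2 <- sum((x - xbar)^2) / n
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xbar) * (x[j] - xbar)
    }
  }
  num / (s2 * sum(w))
}

# all permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

# the packaged China graph, built once per test session
china_W <- contiguity_weights(china_adjacency())
china_adj <- china_adjacency()
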