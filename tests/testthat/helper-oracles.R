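# Naive-loop reference implementations of the four distances, kept
# deliberately independent of the package's vectorized code paths.

oracle_euclidean <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s)
}

oracle_scaled <- function(x, y, m2) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2 / m2[i]
  sqrt(s)
}

oracle_pearson <- function(x, y) {
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + x[i] * y[i]
    sxx <- sxx + x[i]^2
    syy <- syy + y[i]^2
  }
  1 - sxy / (sqrt(sxx) * sqrt(syy))
}

oracle_mahalanobis <- function(x, y, sinv) {
  q <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      q <- q + (x[i] - y[i]) * sinv[i, j] * (x[j] - y[j])
    }
  }
  sqrt(q)
}

# Per-gene scale by explicit loops.
oracle_gene_scale <- function(mat) {
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    s <- 0
    for (j in seq_len(ncol(mat))) s <- s + mat[i, j]^2
    out[i] <- s / ncol(mat)
  }
  out
}
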