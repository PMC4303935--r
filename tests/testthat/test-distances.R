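test_that("Euclidean distance matches hand-computed values", {
  expect_equal(dist_euclidean(c(0, 0), c(3, 4)), 5)
  expect_equal(dist_euclidean(c(2.5, 7, 0.1), c(2.5, 7, 0.1)), 0)
  expect_equal(dist_euclidean(c(1, 2, 3), c(4, 6, 3)), 5)
})

test_that("misaligned gene identifiers are rejected by name", {
  x <- c(a = 1, b = 2)
  y <- c(a = 1, c = 2)
  expect_error(dist_euclidean(x, y), "misaligned.*c", ignore.case = TRUE)
  expect_error(dist_euclidean(1:3, 1:2), "different lengths")
})

test_that("gene_scale is the per-gene mean squared expression", {
  expect_equal(as.numeric(gene_scale(cbind(c(1, 0), c(3, 4)))), c(5, 8))
  expect_equal(as.numeric(gene_scale(matrix(c(2, 2, 2), ncol = 1))),
               c(4, 4, 4))
  expect_equal(as.numeric(gene_scale(matrix(0, 3, 4))), c(0, 0, 0))
})

test_that("scaled distance matches direct evaluation and flags zero scales", {
  expect_equal(dist_scaled(c(1, 0), c(3, 4), c(5, 8)), sqrt(2.8))
  expect_equal(dist_scaled(c(7, 1), c(7, 1), c(2, 3)), 0)
  expect_equal(dist_scaled(c(1, 2), c(0, 0), c(1, 1)), sqrt(5))
  expect_error(dist_scaled(c(1, 2), c(0, 0), c(1, 0)), "all-zero genes")
})

test_that("Pearson distance is the uncentered cosine dissimilarity", {
  expect_equal(dist_pearson(c(5, 5, 5), c(1, 1, 1)), 0)
  expect_equal(dist_pearson(c(1, 0), c(0, 1)), 1)
  expect_equal(dist_pearson(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(dist_pearson(c(0, 0), c(1, 1)), "zero-norm")
  # centered variant differs (it is the classical correlation distance)
  expect_equal(dist_pearson(c(1, 2, 3), c(2, 4, 6), centered = TRUE), 0)
})

test_that("covariance matrix honors centered and uncentered modes", {
  d <- cbind(c(1, 0), c(-1, 0))
  cc <- expr_covariance(d, centered = TRUE)
  cu <- expr_covariance(d, centered = FALSE)
  expect_equal(cc$s, matrix(c(1, 0, 0, 0), 2), ignore_attr = TRUE)
  expect_equal(cu$s, matrix(c(1, 0, 0, 0), 2), ignore_attr = TRUE)
  expect_true(cc$centered)
  expect_false(cu$centered)
  same <- cbind(c(2, 3), c(2, 3), c(2, 3))
  expect_equal(max(abs(expr_covariance(same)$s)), 0)
  expect_error(expr_covariance(matrix(1:2, ncol = 1), centered = TRUE),
               "at least 2 samples")
  # uncentered mode differs from centered when means are non-zero
  d2 <- cbind(c(1, 2), c(3, 4))
  expect_false(isTRUE(all.equal(expr_covariance(d2, centered = TRUE)$s,
                                expr_covariance(d2, centered = FALSE)$s)))
})

test_that("covariance is symmetric and positive semi-definite", {
  set.seed(42)
  d <- matrix(rand_pos(8 * 6), nrow = 8)
  s <- expr_covariance(d)$s
  expect_equal(s, t(s))
  expect_true(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
              > -1e-10)
})

test_that("Mahalanobis distance handles exact, singular and ridge cases", {
  id <- structure(list(s = diag(2), centered = TRUE, inverse_mode = "pseudo",
                       lambda = 0, inv = NULL), class = "expr_cov")
  expect_equal(dist_mahalanobis(c(0, 0), c(3, 4), id), 5)
  dg <- structure(list(s = diag(c(4, 1)), centered = TRUE,
                       inverse_mode = "pseudo", lambda = 0, inv = NULL),
                  class = "expr_cov")
  expect_equal(dist_mahalanobis(c(2, 0), c(0, 0), dg), 1)
  expect_equal(dist_mahalanobis(c(1, 2), c(1, 2), dg), 0)
  # singular covariance (p > n): pseudo-inverse projects onto the data span
  set.seed(7)
  d <- matrix(rand_pos(10 * 3), nrow = 10)
  cv <- expr_covariance(d)
  expect_true(is.finite(dist_mahalanobis(d[, 1], d[, 2], cv)))
  cvr <- expr_covariance(d, inverse = "ridge", lambda = 0.5)
  expect_true(dist_mahalanobis(d[, 1], d[, 2], cvr) > 0)
  expect_error(expr_covariance(d, inverse = "ridge", lambda = 0),
               "positive lambda")
  expect_error(dist_mahalanobis(c(1, 2, 3), c(0, 0, 0), dg),
               "does not match")
})

test_that("all four distances are symmetric with zero self-distance", {
  set.seed(1)
  for (rep in 1:25) {
    x <- rand_pos(6)
    y <- rand_pos(6)
    d <- matrix(rand_pos(6 * 8), nrow = 6)
    m2 <- as.numeric(gene_scale(d))
    cv <- expr_covariance(d, inverse = "ridge", lambda = 0.1)
    for (f in list(dist_euclidean,
                   function(a, b) dist_scaled(a, b, m2),
                   dist_pearson,
                   function(a, b) dist_mahalanobis(a, b, cv))) {
      expect_equal(f(x, y), f(y, x), tolerance = 1e-12)
      expect_equal(f(x, x), 0, tolerance = 1e-12)
    }
  }
})

test_that("Euclidean, scaled, Mahalanobis obey the triangle inequality", {
  set.seed(2)
  for (rep in 1:50) {
    x <- rand_pos(5); y <- rand_pos(5); z <- rand_pos(5)
    d <- matrix(rand_pos(5 * 10), nrow = 5)
    m2 <- as.numeric(gene_scale(d))
    cv <- expr_covariance(d, inverse = "ridge", lambda = 0.1)
    for (f in list(dist_euclidean,
                   function(a, b) dist_scaled(a, b, m2),
                   function(a, b) dist_mahalanobis(a, b, cv))) {
      expect_lte(f(x, z), f(x, y) + f(y, z) + 1e-9 * (f(x, y) + f(y, z)))
    }
  }
})

test_that("Pearson distance is in [0,1] and scale-invariant for non-negative data", {
  set.seed(3)
  for (rep in 1:50) {
    x <- rand_pos(7); y <- rand_pos(7)
    d <- dist_pearson(x, y)
    expect_gte(d, 0)
    expect_lte(d, 1)
    a <- stats::runif(1, 0.01, 100)
    expect_equal(dist_pearson(a * x, y), d, tolerance = 1e-12)
    expect_equal(dist_pearson(x, a * y), d, tolerance = 1e-12)
  }
})

test_that("scaled and Mahalanobis reduce to Euclidean in trivial geometry", {
  set.seed(4)
  x <- rand_pos(9); y <- rand_pos(9)
  expect_identical(dist_scaled(x, y, rep(1, 9)), dist_euclidean(x, y))
  id <- structure(list(s = diag(9), centered = TRUE, inverse_mode = "pseudo",
                       lambda = 0, inv = NULL), class = "expr_cov")
  expect_equal(dist_mahalanobis(x, y, id), dist_euclidean(x, y),
               tolerance = 1e-9)
})

test_that("vectorized distances match naive-loop oracles", {
  set.seed(5)
  for (rep in 1:30) {
    x <- rand_pos(5); y <- rand_pos(5)
    d <- matrix(rand_pos(5 * 12), nrow = 5)
    m2 <- as.numeric(gene_scale(d))
    expect_equal(dist_euclidean(x, y), oracle_euclidean(x, y),
                 tolerance = 1e-12)
    expect_equal(dist_scaled(x, y, m2), oracle_scaled(x, y, m2),
                 tolerance = 1e-12)
    expect_equal(dist_pearson(x, y), oracle_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(as.numeric(gene_scale(d)), oracle_gene_scale(d),
                 tolerance = 1e-12)
    cv <- exprdrift:::.cov_with_inverse(
      expr_covariance(d, inverse = "ridge", lambda = 0.2))
    expect_equal(dist_mahalanobis(x, y, cv),
                 oracle_mahalanobis(x, y, cv$inv), tolerance = 1e-12)
  }
})
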