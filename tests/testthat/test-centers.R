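test_that("centroids are arithmetic means of group members", {
  m <- toy_matrix(cbind(c(0, 0), c(2, 2), c(1, 0), c(0, 1), c(2, 2)))
  meta <- toy_metadata(c("a", "a", "b", "b", "b"))
  cs <- compute_centers(m, meta, metric = "euclidean")
  expect_equal(unname(cs$centroids[, "a"]), c(1, 1))
  expect_equal(unname(cs$centroids[, "b"]), c(1, 1))
  expect_equal(cs$labels, c("a", "b"))
})

test_that("single-sample groups warn and use the sample as centroid", {
  m <- toy_matrix(cbind(c(5, 1), c(0, 0), c(2, 2)))
  meta <- toy_metadata(c("solo", "pair", "pair"))
  expect_warning(cs <- compute_centers(m, meta, metric = "euclidean"),
                 "single sample")
  expect_equal(unname(cs$centroids[, "solo"]), c(5, 1))
})

test_that("samples missing from the matrix are reported by id", {
  m <- toy_matrix(cbind(c(1, 2), c(3, 4)))
  meta <- data.frame(sample_id = c("s01", "s02", "ghost"),
                     group = c("a", "a", "b"))
  expect_error(compute_centers(m, meta), "ghost")
})

test_that("compute_centers is invariant to sample order", {
  set.seed(10)
  m <- toy_matrix(matrix(rand_pos(4 * 6), nrow = 4))
  meta <- toy_metadata(rep(c("a", "b"), 3))
  cs1 <- compute_centers(m, meta, metric = "euclidean")
  perm <- sample(nrow(meta))
  cs2 <- compute_centers(m[, perm], meta[perm, ], metric = "euclidean")
  expect_equal(cs1$centroids, cs2$centroids)
})

test_that("the centroid minimizes the sum of squared Euclidean distances", {
  set.seed(11)
  pts <- matrix(rand_pos(2 * 5), nrow = 2)
  m <- toy_matrix(pts)
  meta <- toy_metadata(rep("g", 5))
  suppressWarnings(cs <- compute_centers(m, meta, metric = "euclidean"))
  ssq <- function(c) sum(colSums((pts - c)^2))
  opt <- stats::optim(c(1, 1), function(c) ssq(c), method = "BFGS")
  expect_equal(unname(cs$centroids[, "g"]), opt$par, tolerance = 1e-4)
  expect_lte(ssq(cs$centroids[, "g"]), opt$value + 1e-8)
})

test_that("distance profiles follow the chosen metric", {
  # 1-gene toy: sample at 2 equidistant from centers at 0 and 4
  m <- toy_matrix(matrix(c(0, 4, 2), nrow = 1))
  meta <- toy_metadata(c("a", "b", "q"))
  suppressWarnings(
    cs <- compute_centers(m[, 1:2, drop = FALSE], meta[1:2, ],
                          metric = "euclidean"))
  prof <- distance_profiles(m[, 3, drop = FALSE], cs)
  expect_equal(prof$r_a, 2)
  expect_equal(prof$r_b, 2)

  # Pearson toy: (1,1) vs centers (1,0) and (0,1)
  m2 <- toy_matrix(cbind(c(1, 0), c(0, 1), c(1, 1)))
  suppressWarnings(
    cs2 <- compute_centers(m2[, 1:2], toy_metadata(c("a", "b", "x"))[1:2, ],
                           metric = "pearson"))
  prof2 <- distance_profiles(m2[, 3, drop = FALSE], cs2)
  expect_equal(prof2$r_a, 1 - 1 / sqrt(2))
  expect_equal(prof2$r_b, 1 - 1 / sqrt(2))

  # a sample equal to a centroid has zero distance to it
  prof3 <- distance_profiles(m2[, 1, drop = FALSE], cs2)
  expect_equal(prof3$r_a, 0)
})

test_that("nearest_center picks the minimum and breaks ties lexicographically", {
  r <- c(normal = 0.1, tumor = 0.5)
  nc <- nearest_center(r)
  expect_equal(nc$label, "normal")
  expect_equal(nc$margin, 0.4)
  expect_false(nc$tie)

  tie <- nearest_center(c(b = 0.3, a = 0.3))
  expect_equal(tie$label, "a")
  expect_true(tie$tie)

  three <- nearest_center(c(x = 0.5, y = 0.2, z = 0.4))
  expect_equal(three$label, "y")
  expect_equal(three$margin, 0.2, tolerance = 1e-12)
})

test_that("leave-one-out centroids exclude the sample itself", {
  m <- toy_matrix(matrix(c(0, 2, 5, 7), nrow = 1))
  meta <- toy_metadata(c("a", "a", "b", "b"))
  loo <- leave_one_out_profiles(m, meta, metric = "euclidean")
  # sample (0): own-group LOO centroid is (2) -> distance 2
  expect_equal(loo$r_a[1], 2)
  expect_equal(loo$r_a[2], 2)
  # other-group distances still use the naive centroid (6)
  expect_equal(loo$r_b[1], 6)
  expect_error(suppressWarnings(leave_one_out_profiles(
    m, toy_metadata(c("a", "a", "a", "solo")), metric = "euclidean")),
    "solo")
})

test_that("LOO within-group distance is never below the naive one (Euclidean)", {
  set.seed(12)
  m <- toy_matrix(matrix(rand_pos(6 * 12), nrow = 6))
  meta <- toy_metadata(rep(c("a", "b"), each = 6))
  cs <- compute_centers(m, meta, metric = "euclidean")
  naive <- distance_profiles(m, cs)
  loo <- leave_one_out_profiles(m, meta, metric = "euclidean")
  for (i in seq_len(nrow(meta))) {
    g <- meta$group[i]
    expect_gte(loo[[paste0("r_", g)]][i] + 1e-12,
               naive[[paste0("r_", g)]][i])
  }
})

test_that("LOO and naive centroids converge as the group grows", {
  set.seed(13)
  n <- 100
  m <- toy_matrix(matrix(stats::runif(3 * n, 0, 10), nrow = 3))
  meta <- toy_metadata(rep("g", n))
  suppressWarnings(cs <- compute_centers(m, meta, metric = "euclidean"))
  for (j in c(1, 50)) {
    loo_centroid <- (n * cs$centroids[, "g"] - m[, j]) / (n - 1)
    expect_true(all(abs(loo_centroid - cs$centroids[, "g"]) <= 10 / n))
  }
})

test_that("well-separated synthetic groups are recovered by LOO classification", {
  des <- simulation_design(
    n_genes = 300L,
    groups = list(list(label = "normal", n = 30L, drift = 0,
                       dispersion = 0.05),
                  list(label = "tumor", n = 30L, drift = 0.5,
                       dispersion = 0.05)),
    seed = 21L)
  coh <- generate_cohort(des)
  cls <- classify_profiles(leave_one_out_profiles(coh$matrix, coh$metadata))
  expect_gte(mean(cls$assigned_label == cls$group), 0.99)
})
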