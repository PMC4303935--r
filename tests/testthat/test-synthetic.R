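small_design <- function(...) {
  simulation_design(n_genes = 200L, ...)
}

test_that("a fixed seed reproduces the cohort exactly", {
  d <- small_design(seed = 60L)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$matrix, c2$matrix)
  expect_identical(c1$metadata, c2$metadata)
  c3 <- generate_cohort(small_design(seed = 61L))
  expect_false(identical(c1$matrix, c3$matrix))
})

test_that("expression values are non-negative so Pearson stays in [0,1]", {
  coh <- generate_cohort(small_design(seed = 62L))
  expect_true(all(coh$matrix >= 0))
  cs <- compute_centers(coh$matrix, coh$metadata, metric = "pearson")
  prof <- distance_profiles(coh$matrix, cs)
  r <- as.matrix(prof[grep("^r_", names(prof))])
  expect_true(all(r >= 0 & r <= 1))
})

test_that("the noise-free limit collapses samples onto their centroid", {
  d <- simulation_design(n_genes = 200L,
                         groups = list(list(label = "g", n = 5L, drift = 0,
                                            dispersion = 1e-6)),
                         seed = 63L)
  coh <- generate_cohort(d)
  dists <- apply(coh$matrix, 2L,
                 function(x) dist_euclidean(x, coh$centroids[, "g"]))
  expect_true(all(dists < 1e-3))
})

test_that("design validation rejects impossible parameters", {
  expect_error(simulation_design(n_genes = 0), "n_genes")
  expect_error(simulation_design(groups = list(list(label = "a", n = 1L,
                                                    drift = -1,
                                                    dispersion = 0.1))),
               "drift")
  expect_error(simulation_design(groups = list(list(label = "a", n = 1L,
                                                    drift = 0,
                                                    dispersion = 0))),
               "dispersion")
  expect_error(simulation_design(groups = list(
    list(label = "a", n = 1L, drift = 0, dispersion = 1),
    list(label = "a", n = 1L, drift = 0, dispersion = 1))), "duplicate")
})

test_that("median distance-to-normal increases with drift", {
  groups <- c(list(list(label = "normal", n = 20L, drift = 0,
                        dispersion = 0.05)),
              lapply(1:3, function(i)
                list(label = paste0("g", i), n = 20L, drift = 0.15 * i,
                     dispersion = 0.05)))
  coh <- generate_cohort(simulation_design(n_genes = 300L, groups = groups,
                                           seed = 64L))
  cs <- compute_centers(coh$matrix, coh$metadata, metric = "pearson")
  prof <- distance_profiles(coh$matrix, cs)
  med <- tapply(prof$r_normal, coh$metadata$group, stats::median)
  expect_lt(med[["normal"]], med[["g1"]])
  expect_lt(med[["g1"]], med[["g2"]])
  expect_lt(med[["g2"]], med[["g3"]])
})

test_that("noise-free survival recovers the planted line exactly", {
  d <- simulation_design(
    n_genes = 200L,
    groups = list(list(label = "normal", n = 10L, drift = 0,
                       dispersion = 0.05),
                  list(label = "tumor", n = 20L, drift = 0.3,
                       dispersion = 0.1)),
    survival_noise_sd = 0, seed = 65L)
  coh <- generate_cohort(d)
  cs <- compute_centers(coh$matrix, coh$metadata)
  prof <- distance_profiles(coh$matrix, cs)
  meta <- attach_survival(coh$metadata, prof, d)
  expect_true(all(is.na(meta$survival_days[meta$group == "normal"])))
  ok <- !is.na(meta$survival_days)
  fit <- suppressWarnings(  # lm warns on a perfect fit
    fit_survival(prof$r_normal[match(meta$sample_id[ok], prof$sample_id)],
                 meta$survival_days[ok]))
  expect_equal(fit$slope, d$survival_slope, tolerance = 1e-9)
  expect_equal(fit$intercept, d$survival_intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("noise calibration hits the requested population R-squared", {
  set.seed(66)
  r <- stats::runif(5000, 0.01, 0.05)
  slope <- -1.35e4
  sd_noise <- survival_noise_for_r2(slope, r, 0.09)
  y <- 1940 + slope * r + stats::rnorm(length(r), 0, sd_noise)
  expect_lt(abs(stats::cor(r, y)^2 - 0.09), 0.02)
  expect_error(survival_noise_for_r2(slope, r, 1.2), "in \\(0, 1\\)")
})

test_that("survival attachment needs a distance-to-normal column", {
  d <- small_design(seed = 67L)
  coh <- generate_cohort(d)
  prof <- data.frame(sample_id = coh$metadata$sample_id, r_other = 1)
  expect_error(attach_survival(coh$metadata, prof, d), "r_normal")
})
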