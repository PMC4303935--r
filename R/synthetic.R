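# Synthetic cohort generator.
#
# Emulates the structure the distance method assumes: k sample groups
# scattered around distinct centroids in gene-expression space, with a
# "normal" group at the baseline (drift 0) and diseased groups displaced
# from it, and optionally survival times linearly coupled to the distance
# from the normal centroid.

#' Describe a synthetic cohort
#'
#' A design records everything needed to generate a cohort reproducibly.
#' Per-gene baseline expression is log-normal (heavy right tail, all values
#' positive, FPKM-like). Each group's centroid is the baseline displaced
#' along a random unit direction by `drift * ||baseline||` — drift is thus a
#' dimensionless fraction of the overall profile magnitude, and no gene
#' subset is privileged. Samples are the group centroid with multiplicative
#' log-normal noise: `x = centroid * exp(N(0, dispersion))` per gene, which
#' keeps all values non-negative and makes the spread scale-proportional.
#'
#' Survival is attached separately (see [attach_survival()]) as
#' `intercept + slope * r_normal + N(0, noise_sd)`, truncated at zero.
#'
#' @param n_genes Number of genes.
#' @param groups List of group descriptors, each a list with `label`,
#'   `n` (samples), `drift` (non-negative, fraction of baseline magnitude)
#'   and `dispersion` (positive, log-scale noise sd). The default design is
#'   a three-group normal / tumor / metastasis cohort of 8 matched samples
#'   each, the layout of a small paired colorectal RNA-seq study.
#' @param base_meanlog,base_sdlog Log-mean and log-sd of the per-gene
#'   log-normal baseline.
#' @param survival_slope Days per unit distance (default -13500, a strong
#'   negative drift-survival coupling in Pearson-distance units).
#' @param survival_intercept Days at zero distance (default 1940).
#' @param survival_noise_sd Additive noise sd in days; `NULL` means derive
#'   it from `survival_r2` when survival is attached.
#' @param survival_r2 Target population R-squared of the survival-distance
#'   relationship (used only when `survival_noise_sd` is `NULL`).
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return Object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_genes = 2000L,
                              groups = list(
                                list(label = "normal", n = 8L,
                                     drift = 0, dispersion = 0.05),
                                list(label = "tumor", n = 8L,
                                     drift = 0.3, dispersion = 0.15),
                                list(label = "metastasis", n = 8L,
                                     drift = 0.25, dispersion = 0.12)),
                              base_meanlog = 1, base_sdlog = 1,
                              survival_slope = -1.35e4,
                              survival_intercept = 1.94e3,
                              survival_noise_sd = NULL,
                              survival_r2 = 0.09,
                              seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  for (g in groups) {
    if (!all(c("label", "n", "drift", "dispersion") %in% names(g))) {
      stop("each group needs label, n, drift, dispersion", call. = FALSE)
    }
    if (g$n < 1L) stop("group sizes must be >= 1", call. = FALSE)
    if (g$drift < 0) stop("drift must be non-negative", call. = FALSE)
    if (g$dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  }
  labs <- vapply(groups, `[[`, character(1L), "label")
  if (anyDuplicated(labs)) stop("duplicate group labels", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 survival_slope = survival_slope,
                 survival_intercept = survival_intercept,
                 survival_noise_sd = survival_noise_sd,
                 survival_r2 = survival_r2,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Generate a synthetic expression cohort
#'
#' Draws the baseline profile, displaces each group's centroid, and samples
#' expression values as described in [simulation_design()]. Values are
#' non-negative throughout, so the Pearson distance stays in `[0, 1]`
#' end-to-end.
#'
#' @param design A `"simulation_design"`.
#' @return List with `matrix` (genes x samples, gene ids `g0001`... and
#'   sample ids `<label>_<i>`), `metadata` (data frame `sample_id`, `group`,
#'   `survival_days` all `NA` until [attach_survival()]), and `centroids`
#'   (the true genes x groups centroids, for diagnostics).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  p <- design$n_genes
  gene_ids <- sprintf("g%05d", seq_len(p))
  baseline <- stats::rlnorm(p, design$base_meanlog, design$base_sdlog)
  base_norm <- sqrt(sum(baseline^2))
  cols <- list()
  meta <- list()
  centroids <- list()
  for (g in design$groups) {
    centroid <- baseline
    if (g$drift > 0) {
      u <- stats::rnorm(p)
      u <- u / sqrt(sum(u^2))
      centroid <- pmax(baseline + g$drift * base_norm * u, 0)
    }
    noise <- matrix(stats::rnorm(p * g$n, 0, g$dispersion), nrow = p)
    samples <- centroid * exp(noise)
    ids <- sprintf("%s_%02d", g$label, seq_len(g$n))
    colnames(samples) <- ids
    cols[[g$label]] <- samples
    centroids[[g$label]] <- centroid
    meta[[g$label]] <- data.frame(sample_id = ids, group = g$label,
                                  survival_days = NA_real_,
                                  stringsAsFactors = FALSE)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- gene_ids
  centroids <- do.call(cbind, centroids)
  rownames(centroids) <- gene_ids
  list(matrix = mat,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       centroids = centroids)
}

#' Noise level achieving a target population R-squared
#'
#' For the linear model `y = a + b r + e`, the population R-squared is
#' `b^2 var(r) / (b^2 var(r) + sd^2)`; solving for the noise sd gives
#' `|b| sd(r) sqrt(1/R2 - 1)`.
#'
#' @param slope Linear coupling `b`.
#' @param r Distances whose sample sd stands in for `sd(r)`.
#' @param r2 Target R-squared in (0, 1).
#' @return Noise standard deviation (days).
#' @export
survival_noise_for_r2 <- function(slope, r, r2) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)", call. = FALSE)
  abs(slope) * stats::sd(r) * sqrt(1 / r2 - 1)
}

#' Attach survival times coupled to distance-from-normal
#'
#' Plants the linear drift-survival relationship:
#' `survival = intercept + slope * r_normal + N(0, noise_sd)`, truncated at
#' zero. When the design's `survival_noise_sd` is `NULL`, the noise is
#' calibrated so the population R-squared equals the design's
#' `survival_r2`, given the observed spread of `r_normal` among the samples
#' receiving survival.
#'
#' @param metadata Cohort metadata (data frame with `sample_id`, `group`).
#' @param profiles Distance-profile table containing an `r_<normal_label>`
#'   column for every sample in `metadata`.
#' @param design The `"simulation_design"` used to generate the cohort.
#' @param normal_label Label of the normal group whose centroid anchors the
#'   distance (default `"normal"`).
#' @param labels Groups to receive survival times (default: all groups
#'   except the normal one, matching cohorts where only patients have
#'   outcomes). Other samples keep `NA`.
#' @param seed Seed for the survival noise (default `design$seed + 1`).
#' @return `metadata` with `survival_days` filled in.
#' @export
attach_survival <- function(metadata, profiles, design,
                            normal_label = "normal", labels = NULL,
                            seed = design$seed + 1L) {
  rcol <- paste0("r_", normal_label)
  if (!rcol %in% names(profiles)) {
    stop("profiles lack a distance-to-normal column '", rcol, "'",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- setdiff(unique(metadata$group), normal_label)
  take <- metadata$group %in% labels
  idx <- match(metadata$sample_id[take], profiles$sample_id)
  if (anyNA(idx)) {
    stop("profiles missing sample(s): ",
         paste(metadata$sample_id[take][is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  r <- profiles[[rcol]][idx]
  noise_sd <- design$survival_noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- survival_noise_for_r2(design$survival_slope, r,
                                      design$survival_r2)
  }
  set.seed(seed)
  y <- design$survival_intercept + design$survival_slope * r +
    stats::rnorm(length(r), 0, noise_sd)
  metadata$survival_days[take] <- pmax(y, 0)
  metadata
}
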