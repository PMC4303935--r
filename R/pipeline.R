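# End-to-end pipeline: matrix + metadata in, tables / report / plots out.

#' Pipeline configuration
#'
#' Collects every knob of the analysis in one record, which is written
#' verbatim into the provenance file next to the outputs.
#'
#' @param normal_label Metadata label of the group whose centroid anchors
#'   the distance-to-normal axis. Required; never guessed.
#' @param metric Distance metric (default `"pearson"`, the magnitude-free
#'   choice used as a rule for arbitrarily normalized expression data).
#' @param transform Input transform, `"none"` or `"log2p1"`.
#' @param centroid_mode `"naive"` (sample included in its own group mean) or
#'   `"loo"` (leave-one-out, recommended for accuracy claims).
#' @param covariance,inverse,lambda Mahalanobis options, see
#'   [expr_covariance()].
#' @param test Group-comparison test, `"welch"` or `"mannwhitney"`.
#' @param seed Integer seed recorded in provenance (the analysis itself is
#'   deterministic; the seed matters when simulating).
#' @param out_dir Output directory, created if missing.
#' @param plots Write PDF plots? Default `TRUE`.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(normal_label,
                       metric = c("pearson", "euclidean", "scaled",
                                  "mahalanobis"),
                       transform = c("none", "log2p1"),
                       centroid_mode = c("naive", "loo"),
                       covariance = c("centered", "uncentered"),
                       inverse = c("pseudo", "ridge"), lambda = 0,
                       test = c("welch", "mannwhitney"),
                       seed = 1L, out_dir = ".", plots = TRUE) {
  if (missing(normal_label) || !nzchar(normal_label)) {
    stop("normal_label is required: name the metadata group that anchors ",
         "the distance-to-normal axis", call. = FALSE)
  }
  structure(list(normal_label = normal_label,
                 metric = match.arg(metric),
                 transform = match.arg(transform),
                 centroid_mode = match.arg(centroid_mode),
                 covariance = match.arg(covariance),
                 inverse = match.arg(inverse), lambda = lambda,
                 test = match.arg(test),
                 seed = as.integer(seed), out_dir = out_dir, plots = plots),
            class = "run_config")
}

.write_provenance <- function(config, inputs, path) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # outputs already live there; keep tables location-free
  lines <- c("# exprdrift run provenance",
             paste0("version=", as.character(utils::packageVersion("exprdrift"))),
             paste0(names(cfg), "=",
                    vapply(cfg, function(x)
                      paste(as.character(x), collapse = ","), character(1L))))
  for (nm in names(inputs)) {
    if (file.exists(inputs[[nm]])) {
      lines <- c(lines, paste0("md5_", nm, "=",
                               unname(tools::md5sum(inputs[[nm]]))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.pipeline_plots <- function(profiles, bary, surv_data, fit, config, out_dir) {
  rcols <- grep("^r_", names(profiles), value = TRUE)
  grp <- factor(profiles$group)
  pal <- grDevices::hcl.colors(max(3L, nlevels(grp)), "Dark 3")[seq_len(nlevels(grp))]
  col <- pal[as.integer(grp)]
  if (length(rcols) >= 2L) {
    grDevices::pdf(file.path(out_dir, "r1_vs_r2.pdf"), width = 5, height = 5)
    plot(profiles[[rcols[1L]]], profiles[[rcols[2L]]], col = col, pch = 19,
         xlab = rcols[1L], ylab = rcols[2L],
         main = "Distance to one center vs. another")
    graphics::legend("topleft", legend = levels(grp), col = pal, pch = 19,
                     bty = "n")
    grDevices::dev.off()
  }
  rnorm_col <- paste0("r_", config$normal_label)
  grDevices::pdf(file.path(out_dir, "distance_to_normal.pdf"),
                 width = 5, height = 5)
  graphics::boxplot(profiles[[rnorm_col]] ~ grp, xlab = "group",
                    ylab = paste("distance to", config$normal_label,
                                 "center"),
                    main = "Drift from the normal center", border = pal)
  graphics::stripchart(profiles[[rnorm_col]] ~ grp, vertical = TRUE,
                       method = "jitter", add = TRUE, pch = 19, col = col)
  grDevices::dev.off()
  if (!is.null(bary)) {
    Dcols <- grep("^D_", names(bary), value = TRUE)
    xy <- ternary_to_cartesian(as.matrix(bary[Dcols]))
    grDevices::pdf(file.path(out_dir, "ternary.pdf"), width = 5, height = 5)
    plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 0.95), asp = 1,
         axes = FALSE, xlab = "", ylab = "",
         main = "Barycentric plot (vertex-proximity convention)")
    tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
    graphics::lines(tri)
    graphics::text(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                   labels = sub("^D_", "", Dcols), pos = c(1, 1, 3))
    graphics::points(xy, col = col, pch = 19)
    grDevices::dev.off()
  }
  if (!is.null(fit)) {
    grDevices::pdf(file.path(out_dir, "survival_vs_distance.pdf"),
                   width = 5, height = 5)
    plot(surv_data$r, surv_data$survival_days,
         xlab = paste("distance to", config$normal_label, "center"),
         ylab = "survival (days)", pch = 19,
         main = "Survival vs. drift from the normal center")
    graphics::abline(fit$lm, col = "red", lwd = 2)
    grDevices::dev.off()
  }
}

#' Run the full distance-analysis pipeline
#'
#' Reads (or accepts) an expression matrix and sample metadata, computes
#' subset centroids and per-sample distance profiles, classifies samples by
#' nearest center, and writes: `profiles.tsv` (distances + assignment),
#' `barycentric.tsv` (iff exactly 3 groups), `comparisons.tsv` (pairwise
#' group tests on distance-to-normal), `survival_fit.txt` (iff survival
#' present), `provenance.txt`, and data-faithful PDF plots.
#'
#' @param config A [run_config()].
#' @param matrix Path to an expression file (read with the config's
#'   transform) or a genes-by-samples numeric matrix.
#' @param metadata Path to a metadata file or a data frame with `sample_id`
#'   and `group` (optionally `survival_days`).
#' @return Invisibly, a list with `profiles`, `barycentric`, `comparisons`,
#'   `survival_fit`, and `files` (paths written).
#' @export
run_pipeline <- function(config, matrix, metadata) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()
  if (is.character(matrix)) {
    inputs$matrix <- matrix
    matrix <- read_expression(matrix, transform = config$transform)
  }
  if (is.character(metadata)) {
    inputs$metadata <- metadata
    metadata <- read_metadata(metadata)
  }
  if (!config$normal_label %in% metadata$group) {
    stop("normal_label '", config$normal_label,
         "' is not a group in the metadata", call. = FALSE)
  }
  files <- character()

  if (config$centroid_mode == "loo") {
    profiles <- leave_one_out_profiles(matrix, metadata,
                                       metric = config$metric,
                                       covariance = config$covariance,
                                       inverse = config$inverse,
                                       lambda = config$lambda)
  } else {
    centers <- compute_centers(matrix, metadata, metric = config$metric,
                               covariance = config$covariance,
                               inverse = config$inverse,
                               lambda = config$lambda)
    profiles <- distance_profiles(matrix[, metadata$sample_id, drop = FALSE],
                                  centers)
    profiles$group <- metadata$group[match(profiles$sample_id,
                                           metadata$sample_id)]
  }
  profiles <- classify_profiles(profiles)
  profiles <- profiles[c("sample_id", "group",
                         grep("^r_", names(profiles), value = TRUE),
                         "assigned_label", "margin", "tie")]
  f <- file.path(config$out_dir, "profiles.tsv")
  write_profiles(profiles, f)
  files <- c(files, f)

  n_groups <- length(unique(metadata$group))
  bary <- NULL
  if (n_groups == 3L) {
    bary <- to_barycentric(profiles)
    f <- file.path(config$out_dir, "barycentric.tsv")
    write_barycentric(bary, f)
    files <- c(files, f)
  } else {
    message("barycentric step skipped: ", n_groups,
            " groups present (needs exactly 3)")
  }

  rnorm_col <- paste0("r_", config$normal_label)
  comparisons <- NULL
  if (n_groups >= 2L) {
    comparisons <- compare_all_groups(profiles[[rnorm_col]], profiles$group,
                                      test = config$test)
    f <- file.path(config$out_dir, "comparisons.tsv")
    utils::write.table(.fmt6(comparisons), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  fit <- NULL
  surv_data <- NULL
  has_surv <- "survival_days" %in% names(metadata) &&
    any(is.finite(metadata$survival_days))
  if (has_surv) {
    idx <- match(metadata$sample_id, profiles$sample_id)
    surv_data <- data.frame(r = profiles[[rnorm_col]][idx],
                            survival_days = metadata$survival_days)
    surv_data <- surv_data[is.finite(surv_data$survival_days), ]
    fit <- fit_survival(surv_data$r, surv_data$survival_days)
    f <- file.path(config$out_dir, "survival_fit.txt")
    con <- file(f, "w")
    sink(con)
    print(fit)
    sink()
    close(con)
    files <- c(files, f)
  } else {
    message("no survival data: association step reports comparisons only")
  }

  if (isTRUE(config$plots)) {
    .pipeline_plots(profiles, bary, surv_data, fit, config, config$out_dir)
  }
  f <- file.path(config$out_dir, "provenance.txt")
  .write_provenance(config, inputs, f)
  files <- c(files, f)
  invisible(list(profiles = profiles, barycentric = bary,
                 comparisons = comparisons, survival_fit = fit,
                 files = files))
}
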