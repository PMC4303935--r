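# Subset centroids and per-sample distance profiles.

.metrics <- c("euclidean", "scaled", "pearson", "mahalanobis")

.check_metadata <- function(metadata) {
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata must be a data.frame with columns sample_id and group",
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
    stop("duplicate sample ids in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute subset centroids of an expression matrix
#'
#' For each group in the metadata, the centroid is the simple arithmetic mean
#' of the member samples' expression vectors, gene by gene. The centroid of
#' the normal group plays the role of the homeostatic center: distance from
#' it measures a sample's drift away from the healthy state.
#'
#' For the `scaled` metric the per-gene scale is computed from the whole
#' matrix and genes with zero scale (zero in every sample) are dropped with a
#' warning; for `mahalanobis` the dataset covariance is computed here
#' (zero-variance genes dropped likewise) and carried in the result.
#'
#' @param matrix Genes-by-samples numeric matrix with gene ids as rownames
#'   and sample ids as colnames.
#' @param metadata Data frame with columns `sample_id` and `group`, covering
#'   the samples to use (samples absent from the matrix are an error).
#' @param metric One of `"pearson"` (default), `"euclidean"`, `"scaled"`,
#'   `"mahalanobis"`.
#' @param covariance For `mahalanobis`: `"centered"` (default) or
#'   `"uncentered"` second-moment matrix.
#' @param inverse,lambda Passed to [expr_covariance()] for `mahalanobis`.
#' @return An object of class `"center_set"`: list with `labels` (sorted
#'   group names), `centroids` (genes x groups matrix), `metric`, `gene_ids`,
#'   `scale` (for scaled), `cov` (for mahalanobis), `sizes`.
#' @export
compute_centers <- function(matrix, metadata,
                            metric = c("pearson", "euclidean", "scaled",
                                       "mahalanobis"),
                            covariance = c("centered", "uncentered"),
                            inverse = c("pseudo", "ridge"), lambda = 0) {
  metric <- match.arg(metric)
  covariance <- match.arg(covariance)
  inverse <- match.arg(inverse)
  .check_metadata(metadata)
  missing <- setdiff(metadata$sample_id, colnames(matrix))
  if (length(missing)) {
    stop("samples in metadata absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- split(as.character(metadata$sample_id),
                  as.character(metadata$group))
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  labels <- sort(names(groups))
  groups <- groups[labels]
  mat <- matrix[, metadata$sample_id, drop = FALSE]

  scale <- NULL
  cov <- NULL
  if (metric == "scaled") {
    scale <- gene_scale(mat)
    drop_genes <- scale == 0
    if (any(drop_genes)) {
      warning(sum(drop_genes), " all-zero gene(s) dropped before scaled ",
              "distance computation", call. = FALSE)
      mat <- mat[!drop_genes, , drop = FALSE]
      scale <- gene_scale(mat)
    }
  } else if (metric == "mahalanobis") {
    v <- apply(mat, 1L, stats::var)
    drop_genes <- v == 0
    if (any(drop_genes)) {
      warning(sum(drop_genes), " zero-variance gene(s) dropped before ",
              "Mahalanobis distance computation", call. = FALSE)
      mat <- mat[!drop_genes, , drop = FALSE]
    }
    cov <- expr_covariance(mat, centered = covariance == "centered",
                           inverse = inverse, lambda = lambda)
    cov <- .cov_with_inverse(cov)
  }

  centroids <- vapply(groups, function(ids) {
    rowMeans(mat[, ids, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(centroids))) {
    centroids <- matrix(centroids, ncol = length(labels),
                        dimnames = list(rownames(mat), labels))
  }
  singles <- labels[lengths(groups) == 1L]
  if (length(singles)) {
    warning("group(s) with a single sample use that sample as centroid: ",
            paste(singles, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, centroids = centroids, metric = metric,
                 gene_ids = rownames(mat), scale = scale, cov = cov,
                 sizes = lengths(groups), members = groups),
            class = "center_set")
}

#' @export
print.center_set <- function(x, ...) {
  cat("center_set:", length(x$labels), "centers over", length(x$gene_ids),
      "genes; metric =", x$metric, "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", x$labels, x$sizes),
                         collapse = ", "), "\n")
  invisible(x)
}

# distance from every column of mat to a single centroid
.dist_to_center <- function(mat, centroid, centers) {
  switch(centers$metric,
    euclidean = sqrt(colSums((mat - centroid)^2)),
    scaled = sqrt(colSums((mat - centroid)^2 / as.numeric(centers$scale))),
    pearson = {
      nc <- sqrt(sum(centroid^2))
      if (nc == 0) stop("Pearson distance undefined: zero-norm centroid",
                        call. = FALSE)
      ns <- sqrt(colSums(mat^2))
      if (any(ns == 0)) stop("Pearson distance undefined: zero-norm sample(s)",
                             call. = FALSE)
      d <- 1 - colSums(mat * centroid) / (ns * nc)
      pmin(pmax(d, 0), 2)
    },
    mahalanobis = {
      d <- mat - centroid
      q <- colSums(d * (centers$cov$inv %*% d))
      sqrt(pmax(q, 0))
    })
}

.align_to_centers <- function(matrix, centers) {
  if (is.null(rownames(matrix))) {
    if (nrow(matrix) != length(centers$gene_ids)) {
      stop("matrix has ", nrow(matrix), " genes but centers use ",
           length(centers$gene_ids), call. = FALSE)
    }
    return(matrix)
  }
  missing <- setdiff(centers$gene_ids, rownames(matrix))
  if (length(missing)) {
    stop("matrix lacks genes required by the centers: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  matrix[centers$gene_ids, , drop = FALSE]
}

#' Distance profile of every sample to every center
#'
#' For each sample (column of the matrix) computes its distance, under the
#' center set's metric, to each subset centroid. The columns `r_<label>` are
#' ordered as `centers$labels`.
#'
#' @param matrix Genes-by-samples numeric matrix.
#' @param centers A `"center_set"` from [compute_centers()].
#' @return Data frame with `sample_id` and one `r_<label>` column per center.
#' @export
distance_profiles <- function(matrix, centers) {
  if (!inherits(centers, "center_set")) {
    stop("centers must be a center_set", call. = FALSE)
  }
  mat <- .align_to_centers(matrix, centers)
  r <- vapply(centers$labels, function(lab) {
    .dist_to_center(mat, centers$centroids[, lab], centers)
  }, numeric(ncol(mat)))
  if (is.null(dim(r))) r <- matrix(r, ncol = length(centers$labels))
  out <- data.frame(sample_id = colnames(mat), r,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("sample_id", paste0("r_", centers$labels))
  out
}

#' Nearest-center assignment for a single distance profile
#'
#' Returns the label of the smallest distance and the margin (second-smallest
#' minus smallest). Exact ties are broken by lexicographic label order and
#' flagged.
#'
#' @param r Numeric vector of distances, named by center label (or `labels`
#'   supplied separately).
#' @param labels Center labels aligned with `r` (defaults to `names(r)`).
#' @return List with `label`, `margin`, `tie`.
#' @export
nearest_center <- function(r, labels = names(r)) {
  if (length(r) < 1L) stop("empty distance profile", call. = FALSE)
  if (is.null(labels) || length(labels) != length(r)) {
    stop("labels must align with distances", call. = FALSE)
  }
  ord <- order(r, labels)  # ties resolved lexicographically
  best <- ord[1L]
  tie <- sum(r == r[best]) > 1L
  margin <- if (length(r) > 1L) r[ord[2L]] - r[best] else NA_real_
  list(label = labels[best], margin = unname(margin), tie = tie)
}

#' Classify every sample in a profile table by nearest center
#'
#' @param profiles Data frame from [distance_profiles()] (columns
#'   `sample_id`, `r_<label>`...).
#' @return The input with columns `assigned_label`, `margin`, `tie` appended.
#' @export
classify_profiles <- function(profiles) {
  rcols <- grep("^r_", names(profiles), value = TRUE)
  if (!length(rcols)) stop("no r_<label> columns found", call. = FALSE)
  labels <- sub("^r_", "", rcols)
  rmat <- as.matrix(profiles[rcols])
  res <- apply(rmat, 1L, function(r) nearest_center(r, labels))
  profiles$assigned_label <- vapply(res, `[[`, character(1L), "label")
  profiles$margin <- vapply(res, `[[`, numeric(1L), "margin")
  profiles$tie <- vapply(res, `[[`, logical(1L), "tie")
  profiles
}

#' Leave-one-out distance profiles
#'
#' Like [distance_profiles()], but each sample's distance to its own group's
#' centroid is computed with that sample excluded from the group mean. This
#' removes the self-inclusion bias of naive centroids (a sample pulls its own
#' group's centroid toward itself), and is the basis for honest
#' classification-accuracy estimates.
#'
#' The per-gene scale and the covariance (for the scaled and Mahalanobis
#' metrics) are kept at their full-dataset values; only the centroid is
#' recomputed.
#'
#' @inheritParams compute_centers
#' @return Data frame as [distance_profiles()], plus a `group` column.
#' @export
leave_one_out_profiles <- function(matrix, metadata,
                                   metric = c("pearson", "euclidean",
                                              "scaled", "mahalanobis"),
                                   ...) {
  metric <- match.arg(metric)
  centers <- compute_centers(matrix, metadata, metric = metric, ...)
  small <- centers$labels[centers$sizes < 2L]
  if (length(small)) {
    stop("leave-one-out requires every group to have >= 2 samples; ",
         "offending group(s): ", paste(small, collapse = ", "), call. = FALSE)
  }
  mat <- .align_to_centers(matrix[, metadata$sample_id, drop = FALSE], centers)
  prof <- distance_profiles(mat, centers)
  group_of <- stats::setNames(as.character(metadata$group),
                              metadata$sample_id)
  for (lab in centers$labels) {
    ids <- centers$members[[lab]]
    n <- length(ids)
    cols <- mat[, ids, drop = FALSE]
    centroid <- centers$centroids[, lab]
    # mean-update identity: loo centroid = (n*c - x) / (n - 1)
    loo_centroids <- (n * centroid - cols) / (n - 1)
    rloo <- vapply(seq_len(n), function(j) {
      .dist_to_center(cols[, j, drop = FALSE], loo_centroids[, j], centers)
    }, numeric(1L))
    prof[match(ids, prof$sample_id), paste0("r_", lab)] <- rloo
  }
  prof$group <- unname(group_of[prof$sample_id])
  prof
}
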