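# Distance metrics on expression vectors.
#
# All functions operate on aligned numeric vectors (one value per gene, same
# gene order on both sides). Alignment is checked by name when both vectors
# are named; length is always checked.

.check_aligned <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors have different lengths (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  nx <- names(x)
  ny <- names(y)
  if (!is.null(nx) && !is.null(ny) && !identical(nx, ny)) {
    bad <- unique(c(setdiff(nx, ny), setdiff(ny, nx),
                    nx[nx != ny], ny[nx != ny]))
    stop("gene identifiers are misaligned; offending ids: ",
         paste(utils::head(unique(bad), 5L), collapse = ", "),
         if (length(unique(bad)) > 5L) ", ..." else "",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance between two expression vectors
#'
#' Plain Euclidean distance `sqrt(sum((x - y)^2))`, treating every gene
#' equally and ignoring correlations between genes.
#'
#' @param x,y Numeric vectors of expression values, aligned gene-by-gene.
#'   If both are named the names must match in order.
#' @return A single non-negative number.
#' @examples
#' dist_euclidean(c(0, 0), c(3, 4))  # 5
#' @export
dist_euclidean <- function(x, y) {
  .check_aligned(x, y)
  sqrt(sum((x - y)^2))
}

#' Per-gene scale of a dataset
#'
#' For each gene, the mean over all samples of the squared expression value.
#' This is the per-gene normalizer used by [dist_scaled()]: dividing squared
#' coordinate differences by it makes the scaled distance insensitive to
#' genes' absolute expression magnitudes.
#'
#' A value of exactly zero occurs only for genes that are zero in every
#' sample; such genes must be removed before computing scaled distances.
#'
#' @param dataset A genes-by-samples numeric matrix (genes in rows).
#' @return A named numeric vector of per-gene mean squared expression,
#'   class `"gene_scale"`.
#' @examples
#' m <- cbind(s1 = c(1, 0), s2 = c(3, 4))
#' gene_scale(m)  # 5, 8
#' @export
gene_scale <- function(dataset) {
  if (is.null(dim(dataset))) dataset <- matrix(dataset, ncol = 1L)
  if (ncol(dataset) < 1L || nrow(dataset) < 1L) {
    stop("dataset must contain at least one sample and one gene", call. = FALSE)
  }
  m2 <- rowMeans(dataset^2)
  structure(m2, class = c("gene_scale", "numeric"))
}

#' Scaled distance between two expression vectors
#'
#' Euclidean distance with each gene's squared difference divided by the
#' dataset-wide mean squared expression of that gene (see [gene_scale()]):
#' `sqrt(sum((x - y)^2 / m2))`. Reduces to [dist_euclidean()] when all
#' scales are 1.
#'
#' @inheritParams dist_euclidean
#' @param scale Per-gene scale from [gene_scale()], computed on a dataset
#'   sharing the gene order of `x` and `y`. All entries must be positive.
#' @return A single non-negative number.
#' @export
dist_scaled <- function(x, y, scale) {
  .check_aligned(x, y)
  if (length(scale) != length(x)) {
    stop("scale length (", length(scale), ") does not match vectors (",
         length(x), ")", call. = FALSE)
  }
  if (any(scale <= 0)) {
    stop("scale contains zero entries; remove all-zero genes ",
         "(see gene_scale) before computing scaled distances", call. = FALSE)
  }
  sqrt(sum((x - y)^2 / scale))
}

#' Pearson (cosine) distance between two expression vectors
#'
#' One minus the uncentered cosine of the angle between the two vectors:
#' `1 - sum(x*y) / (|x| |y|)`. This is the correlation-style distance used
#' as the default metric throughout the package: it ignores the overall
#' magnitude of each profile (expression values are arbitrarily normalized
#' across platforms), and for vectors with non-negative components it always
#' lies in `[0, 1]`.
#'
#' Note this is the plain cosine dissimilarity, not the mean-centered Pearson
#' correlation; set `centered = TRUE` for the mean-centered variant (whose
#' range guarantee no longer holds for non-negative data).
#'
#' @inheritParams dist_euclidean
#' @param centered If `TRUE`, subtract each vector's mean first (classical
#'   correlation distance). Default `FALSE`.
#' @return A single number; in `[0, 1]` for non-negative inputs when
#'   `centered = FALSE`.
#' @examples
#' dist_pearson(c(5, 5, 5), c(1, 1, 1))  # 0: collinear
#' dist_pearson(c(1, 0), c(0, 1))        # 1: orthogonal
#' @export
dist_pearson <- function(x, y, centered = FALSE) {
  .check_aligned(x, y)
  if (centered) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("Pearson distance is undefined for zero-norm vectors", call. = FALSE)
  }
  d <- 1 - sum(x * y) / (nx * ny)
  # cosine of identical vectors can land at 1 + eps in floating point
  if (d < 0 && d > -1e-12) d <- 0
  d
}

#' Covariance matrix of an expression dataset
#'
#' Gene-by-gene covariance averaged over all samples, as needed by
#' [dist_mahalanobis()]. In `centered` mode (the default) the sample means
#' are subtracted and the divisor is the number of samples `n`; in
#' `uncentered` mode the literal second-moment matrix `<x_i y_j>` is
#' returned. The mode, and later the way the inverse was obtained, are
#' recorded in the result.
#'
#' In the common regime where genes far outnumber samples the matrix is
#' singular; [dist_mahalanobis()] then uses a Moore-Penrose pseudo-inverse
#' (default) or a ridge inverse `(S + lambda I)^-1`.
#'
#' @param dataset A genes-by-samples numeric matrix.
#' @param centered Subtract per-gene means first? Default `TRUE`.
#' @param inverse How the inverse will be formed: `"pseudo"` (Moore-Penrose,
#'   singular values below `1e-10` of the largest truncated) or `"ridge"`.
#' @param lambda Ridge regularizer (same units as the covariance entries);
#'   required positive when `inverse = "ridge"`.
#' @return An object of class `"expr_cov"` with elements `s` (the matrix),
#'   `centered`, `inverse_mode`, and `lambda`.
#' @export
expr_covariance <- function(dataset, centered = TRUE,
                            inverse = c("pseudo", "ridge"), lambda = 0) {
  inverse <- match.arg(inverse)
  if (is.null(dim(dataset))) dataset <- matrix(dataset, ncol = 1L)
  n <- ncol(dataset)
  if (centered && n < 2L) {
    stop("centered covariance needs at least 2 samples", call. = FALSE)
  }
  if (!centered && n < 1L) stop("dataset is empty", call. = FALSE)
  if (inverse == "ridge" && lambda <= 0) {
    stop("ridge inverse requires a positive lambda", call. = FALSE)
  }
  x <- dataset
  if (centered) x <- x - rowMeans(x)
  s <- tcrossprod(x) / n
  s <- (s + t(s)) / 2  # enforce exact symmetry
  rownames(s) <- colnames(s) <- rownames(dataset)
  structure(list(s = s, centered = centered, inverse_mode = inverse,
                 lambda = lambda, inv = NULL),
            class = "expr_cov")
}

# Compute and attach the (pseudo/ridge) inverse; idempotent.
.cov_with_inverse <- function(cov) {
  if (!inherits(cov, "expr_cov")) stop("not an expr_cov object", call. = FALSE)
  if (!is.null(cov$inv)) return(cov)
  if (cov$inverse_mode == "ridge") {
    cov$inv <- solve(cov$s + diag(cov$lambda, nrow(cov$s)))
  } else {
    cov$inv <- MASS::ginv(cov$s, tol = 1e-10)
  }
  cov
}

#' Mahalanobis distance between two expression vectors
#'
#' `sqrt((x - y)' S^-1 (x - y))` with `S` the dataset covariance from
#' [expr_covariance()]. Accounts for all gene-gene correlations in the data;
#' with identity covariance it reduces to [dist_euclidean()]. When `S` is
#' singular (genes outnumber samples) the inverse is the Moore-Penrose
#' pseudo-inverse or a ridge inverse, per the covariance object's
#' `inverse_mode`.
#'
#' @inheritParams dist_euclidean
#' @param cov An `"expr_cov"` object built on the same gene order.
#' @return A single non-negative number.
#' @export
dist_mahalanobis <- function(x, y, cov) {
  .check_aligned(x, y)
  if (!inherits(cov, "expr_cov")) stop("cov must be an expr_cov object", call. = FALSE)
  if (nrow(cov$s) != length(x) || ncol(cov$s) != length(x)) {
    stop("covariance dimension (", nrow(cov$s), "x", ncol(cov$s),
         ") does not match vector length (", length(x), ")", call. = FALSE)
  }
  cov <- .cov_with_inverse(cov)
  d <- x - y
  q <- drop(crossprod(d, cov$inv %*% d))
  if (q < 0) {
    if (q < -1e-8 * max(1, sum(d^2))) {
      stop("negative Mahalanobis quadratic form (", q,
           "); covariance inverse is numerically invalid", call. = FALSE)
    }
    q <- 0
  }
  sqrt(q)
}
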