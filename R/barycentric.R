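# Barycentric (ternary) coordinates for three-center distance profiles.
#
# Two conventions coexist. Convention "d" is distance-proportional:
# d_i = r_i / (r_1 + r_2 + r_3), so a sample sitting exactly at center i has
# d_i = 0. Convention "D" is the vertex-proximity convention used by most
# ternary-plot software: D_i = (1 - d_i) / 2 for normalized d, so D_i is
# maximal (1/2) when the sample is at center i. Both triples are
# non-negative and sum to one, and the map d <-> D is affine and invertible.

#' Normalized barycentric coordinates from three distances
#'
#' @param r Numeric vector of exactly three non-negative distances, not all
#'   zero.
#' @return Numeric vector `d` with `d_i = r_i / sum(r)`.
#' @export
bary_d <- function(r) {
  if (length(r) != 3L) {
    stop("barycentric coordinates require exactly 3 distances, got ",
         length(r), call. = FALSE)
  }
  s <- sum(r)
  if (s == 0) {
    stop("degenerate profile: all three distances are zero", call. = FALSE)
  }
  r / s
}

#' Plot-convention coordinates from distance-proportional ones
#'
#' Converts `d` to the ternary-mixture convention `D_i = (1 - d_i/sum(d))/2`.
#'
#' @param d Numeric vector of three barycentric coordinates.
#' @return Numeric vector `D`, non-negative and summing to one.
#' @export
bary_D <- function(d) {
  if (length(d) != 3L) stop("expected 3 coordinates", call. = FALSE)
  (1 - d / sum(d)) / 2
}

#' Invert the plot convention back to distance-proportional coordinates
#'
#' @param D Numeric vector of three plot-convention coordinates summing to 1.
#' @return Numeric vector `d = 1 - 2 D`.
#' @export
bary_d_from_D <- function(D) {
  if (length(D) != 3L) stop("expected 3 coordinates", call. = FALSE)
  1 - 2 * D
}

#' Barycentric coordinates for a three-center profile table
#'
#' Adds both coordinate conventions to a distance-profile table with exactly
#' three `r_<label>` columns: `d_<label>` (distance-proportional) and
#' `D_<label>` (ternary-plot convention).
#'
#' @param profiles Data frame from [distance_profiles()] with exactly three
#'   `r_<label>` columns.
#' @return The input data frame with six coordinate columns appended.
#' @export
to_barycentric <- function(profiles) {
  rcols <- grep("^r_", names(profiles), value = TRUE)
  if (length(rcols) != 3L) {
    stop("barycentric coordinates require exactly 3 centers, found ",
         length(rcols), call. = FALSE)
  }
  labels <- sub("^r_", "", rcols)
  rmat <- as.matrix(profiles[rcols])
  s <- rowSums(rmat)
  if (any(s == 0)) {
    stop("degenerate profile(s) with all three distances zero: ",
         paste(profiles$sample_id[s == 0], collapse = ", "), call. = FALSE)
  }
  d <- rmat / s
  D <- (1 - d) / 2
  colnames(d) <- paste0("d_", labels)
  colnames(D) <- paste0("D_", labels)
  cbind(profiles, as.data.frame(d), as.data.frame(D))
}

#' Planar embedding of ternary coordinates
#'
#' Maps barycentric triples into the standard equilateral triangle with
#' vertices `(0,0)`, `(1,0)`, `(1/2, sqrt(3)/2)`:
#' `xy = c1*v1 + c2*v2 + c3*v3`.
#'
#' @param coords Numeric vector of 3 coordinates or an n-by-3 matrix/data
#'   frame of them (each row summing to 1).
#' @return An n-by-2 matrix of `x`, `y` plot coordinates.
#' @export
ternary_to_cartesian <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("expected 3 columns", call. = FALSE)
  vertices <- rbind(c(0, 0), c(1, 0), c(1 / 2, sqrt(3) / 2))
  xy <- coords %*% vertices
  colnames(xy) <- c("x", "y")
  xy
}
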