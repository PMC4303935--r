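# Statistics layer: group separation tests and survival-vs-distance fit.

#' Compare distance distributions between two groups
#'
#' Two-sided test of whether two groups of distances (typically
#' distance-to-normal) differ. The default is Welch's unequal-variance
#' t-test; the Mann-Whitney rank test is the distribution-free alternative.
#' The statistic is signed so that it is positive when group `a` exceeds
#' group `b` (mean under Welch, rank shift under Mann-Whitney).
#'
#' @param distances_a,distances_b Numeric vectors with at least 2 finite
#'   values each.
#' @param test `"welch"` (default) or `"mannwhitney"`.
#' @param group_a,group_b Optional group labels recorded in the result.
#' @return Object of class `"group_comparison"`: list with `group_a`,
#'   `group_b`, `statistic`, `p_value`, `test_name`, `n_a`, `n_b`.
#' @export
compare_groups <- function(distances_a, distances_b,
                           test = c("welch", "mannwhitney"),
                           group_a = "a", group_b = "b") {
  test <- match.arg(test)
  a <- distances_a[is.finite(distances_a)]
  b <- distances_b[is.finite(distances_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (test == "welch") {
    ht <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) {
                     stop("Welch test failed (", conditionMessage(e),
                          "); if both groups have zero variance, use the ",
                          "Mann-Whitney rank test instead", call. = FALSE)
                   })
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    name <- "welch"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    # center W so the sign says which group is larger
    statistic <- unname(ht$statistic) - length(a) * length(b) / 2
    p <- ht$p.value
    name <- "mannwhitney"
  }
  structure(list(group_a = group_a, group_b = group_b, statistic = statistic,
                 p_value = p, test_name = name,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): statistic = %.4g, p = %.3g (n = %d, %d)\n",
              x$group_a, x$group_b, x$test_name, x$statistic, x$p_value,
              x$n_a, x$n_b))
  invisible(x)
}

#' All pairwise group comparisons of distance-to-normal
#'
#' Runs [compare_groups()] on every pair of groups and reports raw p-values
#' alongside Benjamini-Hochberg adjusted ones (raw values are primary; the
#' adjustment is informational when several pairs are tested).
#'
#' @param distances Numeric vector of distances (e.g. the `r_<normal>`
#'   column of a profile table).
#' @param groups Group label per distance.
#' @param test Passed to [compare_groups()].
#' @return Data frame with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `statistic`, `p_value`, `p_adjusted`, `test`.
#' @export
compare_all_groups <- function(distances, groups,
                               test = c("welch", "mannwhitney")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  if (length(labs) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(labs, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    cmp <- compare_groups(distances[groups == pr[1L]],
                          distances[groups == pr[2L]],
                          test = test, group_a = pr[1L], group_b = pr[2L])
    data.frame(group_a = cmp$group_a, group_b = cmp$group_b,
               n_a = cmp$n_a, n_b = cmp$n_b, statistic = cmp$statistic,
               p_value = cmp$p_value, test = cmp$test_name,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[c("group_a", "group_b", "n_a", "n_b", "statistic",
        "p_value", "p_adjusted", "test")]
}

#' Linear fit of survival time on distance-to-normal
#'
#' Ordinary least squares of observed survival time on the distance of each
#' tumor profile from the normal centroid:
#' `survival = intercept + slope * distance`. A negative slope means samples
#' that have drifted farther from the homeostatic center survive shorter.
#' The p-value is the two-sided test of zero slope; `r_squared` is the
#' squared sample correlation, i.e. the fraction of survival variance the
#' drift explains.
#'
#' Censoring, if any, is ignored: this is a plain linear model of observed
#' times, not a survival-analysis model.
#'
#' @param distances Numeric vector of distances.
#' @param survival_days Numeric vector of survival times (days), same
#'   length; pairs with a missing value are dropped.
#' @return Object of class `"survival_fit"`: list with `slope`, `intercept`,
#'   `p_value`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_survival <- function(distances, survival_days) {
  if (length(distances) != length(survival_days)) {
    stop("distances and survival_days must have equal length", call. = FALSE)
  }
  ok <- is.finite(distances) & is.finite(survival_days)
  x <- distances[ok]
  y <- survival_days[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: distances are constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p_value = p, r_squared = sm$r.squared,
                 n = length(x), lm = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("survival ~ distance (ordinary least squares)\n")
  cat(sprintf("  slope     = %.6g days per unit distance\n", x$slope))
  cat(sprintf("  intercept = %.6g days\n", x$intercept))
  cat(sprintf("  p (slope) = %.3g\n", x$p_value))
  cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  cat(sprintf("  n         = %d\n", x$n))
  invisible(x)
}

#' 95% confidence interval for the fitted slope
#'
#' @param fit A `"survival_fit"` object.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
slope_confint <- function(fit, level = 0.95) {
  ci <- stats::confint(fit$lm, "x", level = level)
  c(lower = ci[1L], upper = ci[2L])
}
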