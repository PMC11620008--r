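#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2|A & B| / (|A| + |B|)`. Two empty
#' masks agree perfectly by convention (`1`, with attribute
#' `both_empty = TRUE`).
#'
#' @param maskA,maskB logical arrays of identical shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)) || length(maskA) != length(maskB))
    stop("dice: mask shapes differ", call. = FALSE)
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) return(structure(1, both_empty = TRUE))
  2 * sum(maskA & maskB) / (a + b)
}

#' Two-way absolute-agreement single-measure ICC
#'
#' Intraclass correlation ICC(A,1) of McGraw & Wong: a two-way model with
#' subjects (rows) and raters/devices (columns), absolute agreement, single
#' measure. From the two-way ANOVA mean squares (`MSR` rows, `MSC` columns,
#' `MSE` error):
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' The two-sided 95% confidence interval uses the standard F-based interval
#' for absolute agreement with Satterthwaite degrees of freedom; the lower
#' bound can legitimately be negative and is not clipped.
#'
#' Because absolute agreement penalizes systematic offsets between raters,
#' adding a constant to one rater's column strictly decreases ICC(A,1) (the
#' consistency version ICC(C,1), also returned, is unchanged).
#'
#' @param table numeric matrix, `n` subjects x `k` raters, `n >= 3`,
#'   `k >= 2`, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `agreement_report`: `icc_estimate`, `ci_low`,
#'   `ci_high`, `category`, `n_subjects`, `n_raters`, `icc_consistency`, and
#'   the mean squares `ms` (MSR, MSC, MSE).
#' @export
icc_a1 <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("icc_a1: missing cells", call. = FALSE)
  n <- nrow(table); k <- ncol(table)
  if (n < 3L || k < 2L)
    stop("icc_a1: need at least 3 subjects and 2 raters", call. = FALSE)
  gm <- mean(table)
  rm <- rowMeans(table)
  cm <- colMeans(table)
  SSR <- k * sum((rm - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((table - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (denom <= 0 && MSR - MSE == 0)
    stop("icc_a1: zero total variance, ICC undefined", call. = FALSE)
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  # degenerate case (zero residual and rater variance): the interval collapses
  if (!is.finite(lo)) lo <- icc
  if (!is.finite(hi)) hi <- icc

  icc_c <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  structure(list(icc_estimate = icc, ci_low = lo, ci_high = hi,
                 category = icc_category(icc),
                 n_subjects = n, n_raters = k,
                 icc_consistency = icc_c,
                 conf_level = conf_level,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> ICC(A,1) = %.3f (%.0f%% CI, %.3f to %.3f), %s\n",
              x$icc_estimate, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$category))
  cat(sprintf("  n = %d subjects x %d raters\n", x$n_subjects, x$n_raters))
  invisible(x)
}

#' Reliability category of an ICC value
#'
#' Conventional bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to
#' 0.90 good, above 0.90 excellent (the 0.90 boundary counts as good).
#'
#' @param value ICC in `[-1, 1]`.
#' @return `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @export
icc_category <- function(value) {
  stopifnot(value >= -1, value <= 1)
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value <= 0.90) "good"
  else "excellent"
}

#' Mean and SD of absolute differences
#'
#' Summary used to report pairwise device differences: mean and sample
#' standard deviation (n - 1 denominator) of `|x - y|`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return named numeric `(mean, sd)`.
#' @export
abs_diff_stats <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- abs(x - y)
  c(mean = mean(d), sd = stats::sd(d))
}

#' Circular moving average of an angular profile
#'
#' Centered wrap-around moving average over an angular window (default 9
#' degrees, wide enough to suppress focal vessel dips without distorting
#' sector structure). On a regular grid of step `s` the window spans the
#' largest odd number of samples whose total span does not exceed
#' `window_deg` (e.g. 9 samples for a 1-degree grid and a 9-degree window).
#' Equal-weight circular averaging preserves the profile mean exactly and
#' commutes with rotation.
#'
#' @param profile an [angular_profile()] on a regular angular grid.
#' @param window_deg window width in degrees (< 360).
#' @return smoothed [angular_profile()].
#' @export
smooth_profile <- function(profile, window_deg = 9) {
  stopifnot(inherits(profile, "angular_profile"))
  if (window_deg >= 360) stop("window must be < 360 degrees", call. = FALSE)
  n <- length(profile$values)
  s <- 360 / n
  step_ok <- all(abs(diff(profile$angles_deg) - s) < 1e-8)
  if (!step_ok)
    stop("smooth_profile requires a regular angular grid", call. = FALSE)
  m <- floor((window_deg / s - 1) / 2)
  if (m < 1) return(profile)
  v <- profile$values
  out <- v
  for (off in seq_len(m)) {
    out <- out + v[(seq_len(n) - 1 + off) %% n + 1] +
      v[(seq_len(n) - 1 - off) %% n + 1]
  }
  angular_profile(profile$angles_deg, out / (2 * m + 1))
}

#' Pointwise difference of two angular profiles
#'
#' `A - B` on a common angular grid, with the scalar overall mean difference
#' attached as attribute `mean_difference`. Antisymmetric:
#' `difference_profile(A, B)` is the negation of `difference_profile(B, A)`.
#'
#' @param profileA,profileB [angular_profile()]s on identical grids.
#' @return [angular_profile()] of differences.
#' @export
difference_profile <- function(profileA, profileB) {
  stopifnot(inherits(profileA, "angular_profile"),
            inherits(profileB, "angular_profile"))
  if (length(profileA$angles_deg) != length(profileB$angles_deg) ||
      any(abs(profileA$angles_deg - profileB$angles_deg) > 1e-9))
    stop("profiles are on incompatible angular grids", call. = FALSE)
  d <- profileA$values - profileB$values
  out <- angular_profile(profileA$angles_deg, d)
  attr(out, "mean_difference") <- mean(d[is.finite(d)])
  out
}
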