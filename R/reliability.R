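#' Intra-rater reliability of repeated measurements
#'
#' Intraclass correlation for a subjects-by-repeats matrix of one rater's
#' repeated measurements, in the two-way mixed-effects, consistency form.
#' Mean squares come from the two-way ANOVA (subject + repeat, fitted with
#' [stats::aov()]); the single-measures coefficient (the usual intra-rater
#' choice, reported by default) is
#' \deqn{ICC(3,1) = (MS_B - MS_E) / (MS_B + (k-1) MS_E)}
#' and the averaged-measures variant is
#' \eqn{ICC(3,k) = (MS_B - MS_E)/MS_B}, where \eqn{MS_B} is the
#' between-subjects mean square, \eqn{MS_E} the residual mean square and k
#' the number of repeats. Confidence limits use the F distribution of
#' \eqn{MS_B/MS_E}.
#'
#' @param x Numeric matrix, subjects in rows, repeats in columns (at least
#'   2 of each), no missing cells.
#' @param level Confidence level (default 0.95).
#' @return List of class `"icc_result"`: `icc`, `ci_low`, `ci_high`
#'   (single measures), `icc_avg`, `ci_avg_low`, `ci_avg_high` (averaged
#'   measures), `ms_subject`, `ms_error`, `n_subjects`, `n_repeats`,
#'   `level`. With zero between-subject variance the coefficient is
#'   undefined and returned as `NA` with a warning.
#' @export
#' @examples
#' x <- matrix(rep(1:10, 3), 10, 3) # identical repeats -> ICC 1
#' icc_intra_rater(x)$icc
icc_intra_rater <- function(x, level = 0.95) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) < 2L || ncol(x) < 2L || anyNA(x)) {
    stop("'x' must be a complete numeric matrix with >= 2 subjects and >= 2 repeats",
         call. = FALSE)
  }
  n <- nrow(x)
  k <- ncol(x)
  long <- data.frame(y = as.vector(x),
                     subject = factor(rep(seq_len(n), times = k)),
                     repeat_ = factor(rep(seq_len(k), each = n)))
  # only the mean squares are consumed, so the F-test warning anova.lm
  # emits on a (near-)perfect fit is irrelevant here
  ms <- suppressWarnings(
    as.data.frame(stats::anova(stats::aov(y ~ subject + repeat_,
                                          data = long))))
  msb <- ms["subject", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  if (msb <= .Machine$double.eps * max(1, mse)) {
    warning("zero between-subject variance: ICC is undefined")
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          icc_avg = NA_real_, ci_avg_low = NA_real_,
                          ci_avg_high = NA_real_, ms_subject = msb,
                          ms_error = mse, n_subjects = n, n_repeats = k,
                          level = level),
                     class = "icc_result"))
  }
  icc1 <- (msb - mse) / (msb + (k - 1) * mse)
  icck <- (msb - mse) / msb
  alpha <- 1 - level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fobs <- msb / mse
  fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
  structure(list(
    icc = icc1,
    ci_low = (fl - 1) / (fl + k - 1),
    ci_high = (fu - 1) / (fu + k - 1),
    icc_avg = icck,
    ci_avg_low = 1 - 1 / fl,
    ci_avg_high = 1 - 1 / fu,
    ms_subject = msb, ms_error = mse,
    n_subjects = n, n_repeats = k, level = level
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Intra-rater ICC (two-way mixed, consistency), %d subjects x %d repeats\n",
    x$n_subjects, x$n_repeats))
  cat(sprintf("  single measures:   %.*f (%.0f%% CI %.*f-%.*f)\n",
              digits, x$icc, 100 * x$level, digits, x$ci_low,
              digits, x$ci_high))
  cat(sprintf("  averaged measures: %.*f (%.0f%% CI %.*f-%.*f)\n",
              digits, x$icc_avg, 100 * x$level, digits, x$ci_avg_low,
              digits, x$ci_avg_high))
  invisible(x)
}

#' Standard error of measurement
#'
#' \eqn{SEM = SD \sqrt{1 - ICC}}, in the units of the measurement, where
#' SD is the pooled standard deviation of all observations (between and
#' within subjects combined).
#'
#' @param x Numeric matrix of measurements, subjects in rows, repeats in
#'   columns.
#' @param icc Reliability coefficient in \[0, 1\], typically the
#'   single-measures value from [icc_intra_rater()].
#' @return SEM in the units of `x`.
#' @export
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' fit <- icc_intra_rater(x)
#' standard_error_of_measurement(x, fit$icc)
standard_error_of_measurement <- function(x, icc) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), is.numeric(icc), length(icc) == 1L)
  if (is.na(icc) || icc < 0 || icc > 1) {
    stop("'icc' must be in [0, 1]", call. = FALSE)
  }
  stats::sd(as.vector(x)) * sqrt(1 - icc)
}
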