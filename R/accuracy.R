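#' Published cut-off accuracy of the screening tool
#'
#' Sensitivity/specificity (as proportions) and likelihood ratios of the
#' 14-item screening tool at every cut-off "score >= k", as reported in the
#' validation study against the radiographic reference standard (135
#' participants with chronic low back pain, 113 STLI-positive, 22
#' negative). Undefined likelihood ratios (division by zero) are `NA`.
#'
#' Together with the group sizes this table determines the per-group score
#' histograms up to rounding; see [reconstruct_counts()].
#'
#' @return Data frame `cutoff`, `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, with attributes `n_pos` (113) and `n_neg` (22).
#' @export
#' @examples
#' stli_reference_accuracy()
stli_reference_accuracy <- function() {
  path <- system.file("extdata", "stli_reference_accuracy.csv",
                      package = "stliscreen", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "n_pos") <- 113L
  attr(out, "n_neg") <- 22L
  out
}

check_labeled_scores <- function(score, stli) {
  if (length(score) != length(stli)) {
    stop("'score' and 'stli' must have equal length", call. = FALSE)
  }
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("'score' must be finite numeric", call. = FALSE)
  }
  if (is.numeric(stli)) {
    if (!all(stli %in% c(0, 1))) stop("numeric 'stli' must be 0/1", call. = FALSE)
    stli <- stli == 1
  }
  if (!is.logical(stli) || anyNA(stli)) {
    stop("'stli' must be logical (or 0/1) with no missing values",
         call. = FALSE)
  }
  if (sum(stli) == 0L || sum(!stli) == 0L) {
    stop("both the STLI-positive and the negative group must be nonempty",
         call. = FALSE)
  }
  list(score = as.numeric(score), stli = stli,
       n_pos = sum(stli), n_neg = sum(!stli))
}

#' 2x2 accuracy statistics at one cut-off
#'
#' Dichotomises scores at "score >= cutoff" (ties screen positive) and
#' derives the 2x2 table statistics against the radiographic reference
#' labels: sensitivity Se = TP / n_pos, specificity Sp = TN / n_neg,
#' LR+ = Se / (1 - Sp) and LR- = (1 - Se) / Sp. A likelihood ratio whose
#' denominator is zero (LR+ at Sp = 1, LR- at Sp = 0) is returned as `NA`,
#' never as infinity.
#'
#' @param score Numeric questionnaire scores.
#' @param stli Logical (or 0/1) reference labels, `TRUE` = STLI-positive.
#' @param cutoff The cut-off value k of the rule "score >= k".
#' @return One-row data frame: `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`.
#' @export
#' @examples
#' confusion_at_cutoff(c(2, 3, 8, 9), c(FALSE, FALSE, TRUE, TRUE), 6)
confusion_at_cutoff <- function(score, stli, cutoff) {
  d <- check_labeled_scores(score, stli)
  pos <- d$score >= cutoff
  tp <- sum(pos & d$stli)
  fp <- sum(pos & !d$stli)
  fn <- d$n_pos - tp
  tn <- d$n_neg - fp
  se <- tp / d$n_pos
  sp <- tn / d$n_neg
  data.frame(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = se, specificity = sp,
             lr_pos = if (sp < 1) se / (1 - sp) else NA_real_,
             lr_neg = if (sp > 0) (1 - se) / sp else NA_real_)
}

#' Full cut-off accuracy table
#'
#' One [confusion_at_cutoff()] row per cut-off. The default range 5..15
#' mirrors the reported table: informative cut-offs 5..14 plus a degenerate
#' top row (cutoff 15, above the maximum possible score) at which nobody
#' screens positive, so Se = 0 and Sp = 1.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Integer vector of cut-offs, ascending.
#' @return Data frame of class `"stli_accuracy_table"`, one row per
#'   cut-off. `print()` renders percentages to 2 decimal places (half-up)
#'   with undefined likelihood ratios blank.
#' @export
accuracy_table <- function(score, stli, cutoffs = 5:15) {
  stopifnot(length(cutoffs) >= 1L, !is.unsorted(cutoffs))
  rows <- lapply(cutoffs, function(k) confusion_at_cutoff(score, stli, k))
  out <- do.call(rbind, rows)
  class(out) <- c("stli_accuracy_table", "data.frame")
  out
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero, the convention used for
#' rendering percentages and reconstructing counts from rounded published
#' proportions (base `round()` rounds ties to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
#' @examples
#' round_half_up(2.5) # 3, where round(2.5) is 2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.stli_accuracy_table <- function(x, digits = 2, ...) {
  fmt <- function(v) ifelse(is.na(v), "",
                            formatC(round_half_up(v, digits),
                                    format = "f", digits = digits))
  shown <- data.frame(
    cutoff = paste0(">=", x$cutoff),
    sensitivity_pct = fmt(100 * x$sensitivity),
    specificity_pct = fmt(100 * x$specificity),
    lr_pos = fmt(x$lr_pos), lr_neg = fmt(x$lr_neg),
    stringsAsFactors = FALSE
  )
  cat("Screening-tool accuracy by cut-off (score >= k)\n")
  print(shown, row.names = FALSE)
  invisible(x)
}

mann_whitney_auc <- function(score, stli) {
  d <- check_labeled_scores(score, stli)
  r <- rank(d$score)
  (sum(r[d$stli]) - d$n_pos * (d$n_pos + 1) / 2) / (d$n_pos * d$n_neg)
}

#' ROC curve and AUC
#'
#' Builds the empirical ROC curve over all observed thresholds (plus the
#' degenerate endpoints (0,0) and (1,1)) and computes the area under it by
#' the trapezoidal rule. The trapezoidal area is verified internally
#' against the Mann-Whitney statistic (probability that a random positive
#' outscores a random negative, ties counted half), to which it is
#' identically equal for threshold-derived curves; a disagreement beyond
#' numerical tolerance aborts. A Hanley-McNeil confidence interval is
#' attached via [auc_confidence_interval()].
#'
#' @inheritParams confusion_at_cutoff
#' @param ci_level Confidence level for the AUC interval.
#' @return Object of class `"stli_roc"`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, sorted by increasing `fpr`), `auc`,
#'   `ci_low`, `ci_high`, `ci_level`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_and_auc(c(1, 2, 5, 8, 9), c(0, 0, 1, 1, 1))
roc_and_auc <- function(score, stli, ci_level = 0.95) {
  d <- check_labeled_scores(score, stli)
  thr <- sort(unique(d$score))
  # thresholds "score >= t": t above max gives (0,0); t = min gives (1,1)
  tpr <- vapply(thr, function(t) mean(d$score[d$stli] >= t), 0)
  fpr <- vapply(thr, function(t) mean(d$score[!d$stli] >= t), 0)
  pts <- data.frame(threshold = c(Inf, rev(thr), -Inf),
                    fpr = c(0, rev(fpr), 1), tpr = c(0, rev(tpr), 1))
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), ]
  auc_trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                     utils::tail(pts$tpr, -1)) / 2)
  auc_mw <- mann_whitney_auc(score, stli)
  if (abs(auc_trap - auc_mw) > 1e-10) {
    stop("internal check failed: trapezoidal AUC (", auc_trap,
         ") differs from the Mann-Whitney statistic (", auc_mw, ")",
         call. = FALSE)
  }
  ci <- auc_confidence_interval(auc_trap, d$n_pos, d$n_neg, level = ci_level)
  structure(list(points = pts, auc = auc_trap,
                 ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
                 n_pos = d$n_pos, n_neg = d$n_neg),
            class = "stli_roc")
}

#' @export
print.stli_roc <- function(x, digits = 2, ...) {
  cat(sprintf("ROC: AUC %.*f (%.0f%% CI %.*f-%.*f), %d positives / %d negatives\n",
              digits, x$auc, 100 * x$ci_level, digits, x$ci_low,
              digits, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Wald interval based on the Hanley-McNeil standard error
#' \deqn{SE^2 = [A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)] / (n_+ n_-)}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, truncated to
#' \[0, 1\]. At a degenerate AUC of exactly 0 or 1 the standard error
#' collapses to zero and a warning is issued.
#'
#' @param auc Area under the curve, in \[0, 1\].
#' @param n_pos,n_neg Group sizes.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' auc_confidence_interval(0.73, 113, 22)
auc_confidence_interval <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(is.numeric(auc), length(auc) == 1L, auc >= 0, auc <= 1,
            n_pos >= 1, n_neg >= 1, level > 0, level < 1)
  if (auc == 0 || auc == 1) {
    warning("degenerate AUC of ", auc, ": interval collapses to a point")
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Screening cut-off selection
#'
#' Selects the cut-off with maximum sensitivity among cut-offs whose
#' specificity is strictly positive, breaking ties toward the higher
#' cut-off. The specificity constraint excludes the degenerate rule under
#' which everybody screens positive (Se = 100%, Sp = 0%), which has no
#' screening value.
#'
#' @param table An [accuracy_table()] (or data frame with columns
#'   `cutoff`, `sensitivity`, `specificity`).
#' @return The selected cut-off (integer).
#' @export
#' @examples
#' acc <- stli_reference_accuracy()
#' select_cutoff(acc) # 6
select_cutoff <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L,
            all(c("cutoff", "sensitivity", "specificity") %in% names(table)))
  feasible <- table[table$specificity > 0, ]
  if (nrow(feasible) == 0L) {
    stop("no cut-off has strictly positive specificity", call. = FALSE)
  }
  best <- feasible[feasible$sensitivity == max(feasible$sensitivity), ]
  max(best$cutoff)
}

#' Reconstruct per-group score histograms from accuracy columns
#'
#' A published cut-off table reports, for each cut-off k, the rounded
#' proportions of each group scoring >= k. With the group sizes these
#' determine the underlying counts: positives scoring >= k is
#' `round(Se_k * n_pos)` and negatives scoring >= k is
#' `round((1 - Sp_k) * n_neg)` (half-up rounding). Successive differencing
#' then recovers the per-score histograms; participants below the lowest
#' cut-off are pooled into a single bottom bin, labelled one score unit
#' below it.
#'
#' @param sensitivity,specificity Proportions per cut-off (not percent).
#' @param cutoffs Ascending integer cut-offs, same length.
#' @param n_pos,n_neg Group sizes.
#' @return List of class `"score_histograms"`: `pos` and `neg`, named
#'   integer count vectors over score values, plus `cutoffs`. An
#'   inconsistent table (negative count after differencing, or cumulative
#'   counts that are not nonincreasing) is an error.
#' @seealso [histogram_scores()] to expand histograms back into per-subject
#'   score vectors.
#' @export
#' @examples
#' acc <- stli_reference_accuracy()
#' reconstruct_counts(acc$sensitivity, acc$specificity, acc$cutoff, 113, 22)
reconstruct_counts <- function(sensitivity, specificity, cutoffs,
                               n_pos, n_neg) {
  stopifnot(length(sensitivity) == length(cutoffs),
            length(specificity) == length(cutoffs),
            !is.unsorted(cutoffs), n_pos >= 1, n_neg >= 1,
            all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  cum_pos <- round_half_up(sensitivity * n_pos)
  cum_neg <- round_half_up((1 - specificity) * n_neg)
  hist_from_cum <- function(cum, n, group) {
    counts <- c(n - cum[1], -diff(cum), cum[length(cum)])
    if (any(counts < 0)) {
      stop("inconsistent accuracy table: differencing the ", group,
           "-group cumulative counts yields a negative bin", call. = FALSE)
    }
    names(counts) <- c(cutoffs[1] - 1L, cutoffs)
    as.integer(counts)
  }
  pos <- hist_from_cum(cum_pos, n_pos, "positive")
  neg <- hist_from_cum(cum_neg, n_neg, "negative")
  names(pos) <- names(neg) <- c(cutoffs[1] - 1L, cutoffs)
  structure(list(pos = pos, neg = neg, cutoffs = cutoffs),
            class = "score_histograms")
}

#' @export
print.score_histograms <- function(x, ...) {
  cat("Reconstructed score histograms (bottom bin pools scores below",
      paste0(min(x$cutoffs), "):\n"))
  print(rbind(`STLI-positive` = x$pos, negative = x$neg))
  invisible(x)
}

#' Expand score histograms into per-subject scores and labels
#'
#' @param histograms A [reconstruct_counts()] result.
#' @return Data frame `score`, `stli` with one row per reconstructed
#'   participant.
#' @export
histogram_scores <- function(histograms) {
  stopifnot(inherits(histograms, "score_histograms"))
  vals <- as.numeric(names(histograms$pos))
  data.frame(
    score = c(rep(vals, histograms$pos), rep(vals, histograms$neg)),
    stli = rep(c(TRUE, FALSE),
               c(sum(histograms$pos), sum(histograms$neg)))
  )
}

#' Required sample size for estimating sensitivity
#'
#' Buderer-type sample size for a diagnostic accuracy study whose
#' precision requirement is on sensitivity:
#' \deqn{n = \lceil z_{1-\alpha/2}^2 \, P(1-P) / (e^2 \, prev) \rceil}
#' where P is the anticipated sensitivity, e the half-width of its
#' confidence interval and prev the anticipated prevalence (the divisor
#' inflates the estimation sample to yield enough disease-positive
#' subjects).
#'
#' @param alpha Two-sided significance level.
#' @param sensitivity Anticipated sensitivity P, in (0, 1).
#' @param precision Precision of estimation e, in (0, 1).
#' @param prevalence Anticipated prevalence, in (0, 1].
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(0.05, 0.5, 0.05, 1)      # 385, the classic formula
#' required_sample_size(0.01, 0.80, 0.10, 0.78)  # 137
required_sample_size <- function(alpha, sensitivity, precision, prevalence) {
  stopifnot(alpha > 0, alpha < 1, sensitivity > 0, sensitivity < 1,
            precision > 0, precision < 1)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1) {
    stop("'prevalence' must be in (0, 1]", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * sensitivity * (1 - sensitivity) /
                       (precision^2 * prevalence)))
}
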