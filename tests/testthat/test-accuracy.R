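test_that("2x2 statistics at a cut-off, including undefined likelihood ratios", {
  # perfectly separated groups
  row <- confusion_at_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 1)
  expect_equal(row$lr_neg, 0)
  expect_true(is.na(row$lr_pos))  # Sp = 1: LR+ undefined, not Inf
  # everyone screens positive
  all_pos <- confusion_at_cutoff(c(6, 7, 8, 9), c(0, 0, 1, 1), 5)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$lr_pos, 1)
  expect_true(is.na(all_pos$lr_neg))  # Sp = 0: LR- undefined
  expect_error(confusion_at_cutoff(1:3, c(1, 1, 1), 2), "nonempty")
})

test_that("accuracy table matches hand enumeration on toy data", {
  score <- c(2, 5, 5, 7)
  stli <- c(FALSE, FALSE, TRUE, TRUE)
  tab <- accuracy_table(score, stli, cutoffs = 4:8)
  # hand enumeration: cutoffs 4..8 over scores {neg: 2, 5; pos: 5, 7}
  expect_equal(tab$sensitivity, c(1, 1, 0.5, 0.5, 0))
  expect_equal(tab$specificity, c(0.5, 0.5, 1, 1, 1))
  expect_equal(tab$tp + tab$fn, rep(2L, 5))
  expect_equal(tab$fp + tab$tn, rep(2L, 5))
  # above the maximum observed score
  top <- tab[tab$cutoff == 8, ]
  expect_equal(top$sensitivity, 0)
  expect_equal(top$specificity, 1)
})

test_that("Se is nonincreasing and Sp nondecreasing in the cut-off; LR+ >= 1 when Se >= 1 - Sp", {
  set.seed(301)
  for (i in 1:20) {
    score <- sample(0:14, 60, replace = TRUE)
    stli <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.7, 0.3))
    if (sum(stli) == 0 || sum(!stli) == 0) next
    tab <- accuracy_table(score, stli, cutoffs = 0:15)
    expect_true(all(diff(tab$sensitivity) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
    ok <- !is.na(tab$lr_pos) & tab$sensitivity >= 1 - tab$specificity
    expect_true(all(tab$lr_pos[ok] >= 1 - 1e-12))
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic on fuzzed inputs", {
  set.seed(302)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    score <- sample(0:14, n, replace = TRUE)
    stli <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(stli) == 0 || sum(!stli) == 0) next
    r <- roc_and_auc(score, stli)  # aborts internally on any disagreement
    expect_equal(r$auc, oracle_auc(score, stli), tolerance = 1e-12)
  }
})

test_that("ROC/AUC degenerate and cross-checked cases", {
  # identical distributions: no discrimination
  expect_equal(roc_and_auc(c(1, 2, 3, 1, 2, 3),
                           c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # perfect separation (warns that the AUC interval degenerates)
  expect_warning(perfect <- roc_and_auc(c(1, 2, 8, 9), c(0, 0, 1, 1)),
                 "degenerate")
  expect_equal(perfect$auc, 1)
  expect_error(roc_and_auc(c(1, 2), c(1, 1)), "nonempty")
  # label inversion mirrors the AUC
  set.seed(303)
  score <- sample(0:14, 40, replace = TRUE)
  stli <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_and_auc(score, !stli)$auc, 1 - roc_and_auc(score, stli)$auc)
  # independent reference implementation
  skip_if_not_installed("pROC")
  r <- roc_and_auc(score, stli)
  ref <- pROC::roc(response = stli, predictor = score, quiet = TRUE,
                   direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Hanley-McNeil interval matches its closed form and is symmetric under label inversion", {
  a <- 0.73; n_pos <- 113; n_neg <- 22
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  ci <- auc_confidence_interval(a, n_pos, n_neg)
  expect_equal(ci, c(a - qnorm(0.975) * se, a + qnorm(0.975) * se))
  # label inversion (AUC -> 1 - AUC, group sizes swapped) mirrors the
  # interval exactly about 0.5
  ci_inv <- auc_confidence_interval(1 - a, n_neg, n_pos)
  expect_equal(sort(1 - ci_inv), ci)
  # huge n collapses toward the point estimate
  wide <- auc_confidence_interval(0.5, 1e6, 1e6)
  expect_lt(wide[2] - wide[1], 1e-2)
  expect_warning(auc_confidence_interval(1, 10, 10), "degenerate")
})

test_that("cut-off selection: max sensitivity with strictly positive specificity, ties to the higher cut-off", {
  tab <- data.frame(cutoff = 5:7,
                    sensitivity = c(1, 0.9, 0.9),
                    specificity = c(0, 0.2, 0.4))
  expect_equal(select_cutoff(tab), 7)  # tie at Se 0.9 broken upward
  one <- data.frame(cutoff = 3, sensitivity = 0.5, specificity = 0.5)
  expect_equal(select_cutoff(one), 3)
  none <- data.frame(cutoff = 5, sensitivity = 1, specificity = 0)
  expect_error(select_cutoff(none), "positive specificity")
})

test_that("count reconstruction from rounded accuracy columns", {
  acc <- stli_reference_accuracy()
  h <- reconstruct_counts(acc$sensitivity, acc$specificity, acc$cutoff,
                          113, 22)
  expect_equal(sum(h$pos), 113L)
  expect_equal(sum(h$neg), 22L)
  # round(0.9912 * 113) = 112 positives scoring >= 6
  expect_equal(sum(h$pos[as.integer(names(h$pos)) >= 6]), 112L)
  # round(0.0455 * 22) = 1 negative scoring >= 10
  expect_equal(sum(h$neg[as.integer(names(h$neg)) >= 10]), 1L)
  # Se column of all ones piles every positive into the cumulative chain
  h1 <- reconstruct_counts(rep(1, 3), c(0, 0.5, 1), 5:7, 10, 4)
  expect_equal(unname(h1$pos), c(0L, 0L, 0L, 10L))
  # inconsistent (non-monotone) table is an error
  expect_error(reconstruct_counts(c(0.5, 0.9), c(0.5, 0.6), 5:6, 10, 10),
               "inconsistent")
})

test_that("reconstructed histograms round-trip through the accuracy engine to every printed cell", {
  acc <- stli_reference_accuracy()
  d <- reference_scores()
  tab <- accuracy_table(d$score, d$stli, cutoffs = acc$cutoff)
  expect_equal(round_half_up(100 * tab$sensitivity, 2),
               round_half_up(100 * acc$sensitivity, 2))
  expect_equal(round_half_up(100 * tab$specificity, 2),
               round_half_up(100 * acc$specificity, 2))
  defined <- !is.na(acc$lr_pos)
  expect_equal(round_half_up(tab$lr_pos[defined], 2), acc$lr_pos[defined])
  defined_n <- !is.na(acc$lr_neg)
  expect_equal(round_half_up(tab$lr_neg[defined_n], 2), acc$lr_neg[defined_n])
})

test_that("sensitivity-driven sample size formula", {
  expect_equal(required_sample_size(0.05, 0.5, 0.05, 1), 385L)
  expect_equal(required_sample_size(0.01, 0.80, 0.10, 0.78), 137L)
  # n decreases as the precision requirement relaxes
  e_grid <- c(0.05, 0.1, 0.2)
  n_grid <- vapply(e_grid, function(e) {
    required_sample_size(0.01, 0.8, e, 0.78)
  }, 0L)
  expect_true(all(diff(n_grid) < 0))
  expect_error(required_sample_size(0.01, 0.8, 0.1, 0), "prevalence")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
})
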