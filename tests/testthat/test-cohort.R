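test_that("Poisson-binomial pmf matches binomial and convolution facts", {
  expect_equal(dpoisbinom(rep(0.5, 2)), c(0.25, 0.5, 0.25))
  p <- c(0.1, 0.5, 0.9, 0.3)
  expect_equal(dpoisbinom(p), dpoisbinom(rev(p)))  # permutation invariance
  expect_equal(sum(dpoisbinom(p)), 1)
  expect_equal(sum(0:4 * dpoisbinom(p)), sum(p))   # mean identity
})

test_that("item calibration recovers known probabilities and handles degenerate targets", {
  truth <- c(0.9735, 0.5, 0.9646, 0.2, 0.2, 0.7, 0.2, 0.9558, 0.7, 0.2,
             0.5, 0.2, 0.7, 0.5)
  target <- dpoisbinom(truth)
  cal <- calibrate_item_probs(target,
                              pinned = c("1" = 0.9735, "3" = 0.9646,
                                         "8" = 0.9558))
  expect_lt(cal$tv, 0.01)
  # the pmf is matched tightly; the item parameters themselves are only
  # weakly identified (near-flat least-squares surface), so parameter
  # recovery is asserted coarsely
  expect_equal(sort(cal$probs[-c(1, 3, 8)]), sort(truth[-c(1, 3, 8)]),
               tolerance = 0.15)
  # all mass at the maximum score forces all probabilities to one
  top <- c(rep(0, 14), 1)
  cal_top <- calibrate_item_probs(top)
  expect_equal(cal_top$probs, rep(1, 14), tolerance = 1e-3)
})

test_that("default item probabilities pin the reported rates and report their misfit", {
  p_stli <- default_item_probs("STLI")
  expect_equal(p_stli[3], 0.9735)
  expect_equal(p_stli[8], 0.9646)
  expect_equal(p_stli[9], 0.9558)
  expect_true(all(p_stli >= 0 & p_stli <= 1))
  # independence caps the achievable fit; the distance must be reported
  expect_true(is.numeric(attr(p_stli, "tv")))
  p_ctrl <- default_item_probs("control")
  expect_true(all(p_ctrl >= 0 & p_ctrl <= 1))
  # controls endorse the dominant symptoms too, but score lower overall
  expect_lt(sum(p_ctrl), sum(p_stli))
})

test_that("constructive kinematics sampling always satisfies its label", {
  set.seed(501)
  for (i in 1:200) {
    lbl <- sample(c("normal", "STLI"), 1)
    kin <- sample_kinematics(lbl)
    expect_equal(classify_participant(kin)$label, lbl)
  }
  # bands with an empty STLI band are rejected up front
  bad <- default_band_table()
  bad$translation_stli_low <- bad$translation_li + 1
  expect_error(sample_kinematics("STLI", bands = bad), "infeasible")
})

test_that("response sampling reproduces its item probabilities", {
  set.seed(502)
  expect_equal(sample_responses("STLI", item_probs = rep(0, 14)),
               rep(0L, 14))
  expect_equal(sample_responses("STLI", item_probs = rep(1, 14)),
               rep(1L, 14))
  draws <- replicate(4000, sample_responses("STLI")[3])
  expect_equal(mean(draws), 0.9735, tolerance = 0.01)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n_participants = 30, seed = 99))
  b <- generate_cohort(cohort_spec(n_participants = 30, seed = 99))
  expect_identical(a$participants, b$participants)
  expect_identical(a$kinematics, b$kinematics)
  expect_identical(a$responses, b$responses)
  c2 <- generate_cohort(cohort_spec(n_participants = 30, seed = 100))
  expect_false(identical(a$participants, c2$participants))
})

test_that("an empty cohort keeps its schemas", {
  co <- generate_cohort(cohort_spec(n_participants = 0, seed = 1))
  expect_equal(nrow(co$participants), 0L)
  expect_equal(nrow(co$kinematics), 0L)
  expect_named(co$responses, c("participant", paste0("q", 1:14)))
})

test_that("generated labels, prevalence and demographics match the target population", {
  co <- generate_cohort(cohort_spec(n_participants = 1350, seed = 7))
  p <- co$participants
  # classifier on noise-free kinematics reproduces every generated label
  cls <- classify_cohort(co$kinematics)
  expect_equal(cls$label[match(p$participant, cls$participant)], p$label)
  expect_false(any(cls$label == "LI"))
  # binomial tolerance at n = 1350
  expect_equal(mean(p$label == "STLI"), 0.837, tolerance = 0.025)
  expect_equal(mean(p$age), 35.58, tolerance = 0.02)
  expect_equal(mean(p$sex == "female"), 0.6074, tolerance = 0.05)
  expect_equal(mean(p$bmi), 22.16, tolerance = 0.01)
  expect_true(all(p$age > 20 & p$age < 60))
  expect_true(all(p$duration_months > 0))
  expect_true(all(p$nrs %in% 4:7))
})

test_that("cohort score distributions close the loop with the calibrated model", {
  co <- generate_cohort(cohort_spec(n_participants = 1350, seed = 13))
  p <- co$participants
  for (grp in c("STLI", "normal")) {
    probs <- default_item_probs(if (grp == "STLI") "STLI" else "control")
    implied <- dpoisbinom(as.numeric(probs))
    scores <- p$score[p$label == grp]
    n <- length(scores)
    # per-cutoff empirical exceedance vs the model's implied exceedance,
    # within binomial sampling tolerance
    for (k in c(6, 8, 10)) {
      model <- sum(implied[(k + 1):15])
      tol <- max(4 * sqrt(model * (1 - model) / n), 0.01)
      expect_lt(abs(mean(scores >= k) - model), tol)
    }
  }
})

test_that("landmark emission round-trips through the measurement pathway", {
  co <- generate_cohort(cohort_spec(n_participants = 4, seed = 3),
                        include_landmarks = TRUE)
  measured <- measure_landmark_table(co$landmarks)
  key <- paste(co$kinematics$participant, co$kinematics$level)
  mkey <- paste(measured$participant, measured$level)
  expect_equal(measured$rotation[match(key, mkey)], co$kinematics$rotation,
               tolerance = 1e-9)
  expect_equal(measured$translation[match(key, mkey)],
               co$kinematics$translation, tolerance = 1e-9)
})
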