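test_that("endplate angle is zero for parallel baselines and tracks rigid rotation", {
  lm <- sample_landmarks(rotation = 0, translation = 0, level = "L1L2",
                         pose = list(flexion = list(angle = 0, shift = c(0, 0)),
                                     extension = list(angle = 0, shift = c(0, 0))))
  expect_equal(endplate_angle(lm$flexion), 0)
  lm10 <- sample_landmarks(rotation = 20, translation = 0, level = "L1L2",
                           pose = list(flexion = list(angle = 0, shift = c(0, 0)),
                                       extension = list(angle = 0, shift = c(0, 0))))
  # the 20-degree arc splits evenly: +10 on the flexion film
  expect_equal(endplate_angle(lm10$flexion), 10)
  expect_equal(endplate_angle(lm10$extension), -10)
})

test_that("posterior offset is the along-endplate projection distance", {
  pose0 <- list(flexion = list(angle = 0, shift = c(0, 0)),
                extension = list(angle = 0, shift = c(0, 0)))
  lm <- sample_landmarks(rotation = 0, translation = 0, level = "L3L4",
                         pose = pose0)
  expect_equal(posterior_offset(lm$flexion), 0)
  lm5 <- sample_landmarks(rotation = 0, translation = 5, level = "L3L4",
                          pose = pose0)
  expect_equal(posterior_offset(lm5$flexion), 2.5)
  # offset read correctly when the whole film is tilted 15 degrees
  tilted <- sample_landmarks(rotation = 0, translation = 6.4, level = "L3L4",
                             pose = list(flexion = list(angle = 15, shift = c(3, -7)),
                                         extension = list(angle = 15, shift = c(3, -7))))
  expect_equal(posterior_offset(tilted$flexion), 3.2, tolerance = 1e-9)
})

test_that("excursion formulas combine the two film measurements", {
  expect_equal(segment_rotation(0, 0), 0)
  expect_equal(segment_rotation(8, 6), 14)
  expect_equal(segment_translation(0, 0), 0)
  expect_equal(segment_translation(2.5, 1.5), 4.0)
  expect_error(segment_rotation(NaN, 1), "finite")
})

test_that("rigid-motion round trip recovers imposed kinematics to 1e-9", {
  set.seed(101)
  for (i in 1:50) {
    theta <- runif(1, 0, 25)
    trans <- runif(1, 0, 5)
    lvl <- sample(lumbar_levels(), 1)
    lm <- sample_landmarks(rotation = theta, translation = trans, level = lvl)
    m <- measure_segment(lm$flexion, lm$extension)
    expect_equal(m$rotation, theta, tolerance = 1e-9)
    expect_equal(m$translation, trans, tolerance = 1e-9)
  }
})

test_that("per-film measurements are invariant under a global rigid motion", {
  set.seed(102)
  for (i in 1:20) {
    theta <- runif(1, -15, 15)
    trans <- runif(1, -4, 4)
    base <- list(angle = 0, shift = c(0, 0))
    moved <- list(angle = runif(1, -180, 180), shift = runif(2, -100, 100))
    lm0 <- sample_landmarks(theta, trans, pose = list(flexion = base,
                                                      extension = base))
    lm1 <- sample_landmarks(theta, trans, pose = list(flexion = moved,
                                                      extension = moved))
    expect_equal(endplate_angle(lm1$flexion), endplate_angle(lm0$flexion),
                 tolerance = 1e-9)
    expect_equal(posterior_offset(lm1$flexion), posterior_offset(lm0$flexion),
                 tolerance = 1e-9)
  }
})

test_that("degenerate landmark geometry is an error, not a zero", {
  expect_error(
    vertebral_landmarks("L1L2", "flexion",
                        upper_endplate_anterior = c(1, 1),
                        upper_endplate_posterior = c(1, 1),
                        lower_endplate_anterior = c(1, 0),
                        lower_endplate_posterior = c(0, 0),
                        upper_posterior_corner = c(1, 1),
                        lower_posterior_corner = c(0, 0)),
    "degenerate")
  expect_error(
    vertebral_landmarks("L1L2", "flexion",
                        upper_endplate_anterior = c(1, NA),
                        upper_endplate_posterior = c(0, 1),
                        lower_endplate_anterior = c(1, 0),
                        lower_endplate_posterior = c(0, 0),
                        upper_posterior_corner = c(1, 1),
                        lower_posterior_corner = c(0, 0)),
    "finite")
})

test_that("triplicate measurement averages the three repeats exactly", {
  lm <- sample_landmarks(rotation = 12, translation = 3, level = "L4L5",
                         pose = list(flexion = list(angle = 0, shift = c(0, 0)),
                                     extension = list(angle = 0, shift = c(0, 0))))
  exact <- measure_segment_triplicate(lm$flexion, lm$extension)
  expect_equal(exact$rotation, 12)
  expect_equal(exact$n_repeats, 3L)
  noisy <- measure_segment_triplicate(lm$flexion, lm$extension,
                                      rotation_noise = c(0, 0, 0),
                                      translation_noise = c(-0.1, 0, 0.1))
  expect_equal(noisy$translation, 3.0)
  # mean of three equals the average of the single-repeat measurements
  singles <- vapply(c(-0.2, 0.05, 0.3), function(eps) {
    measure_segment_triplicate(lm$flexion, lm$extension,
                               rotation_noise = eps,
                               translation_noise = 0)$rotation
  }, 0)
  trip <- measure_segment_triplicate(lm$flexion, lm$extension,
                                     rotation_noise = c(-0.2, 0.05, 0.3),
                                     translation_noise = c(0, 0, 0))
  expect_equal(trip$rotation, mean(singles))
  expect_error(measure_segment_triplicate(lm$flexion, lm$extension,
                                          rotation_noise = numeric(0),
                                          translation_noise = numeric(0)),
               "at least one")
})

test_that("repeat noise propagates as sigma and sigma/sqrt(3) (Monte Carlo)", {
  set.seed(103)
  lm <- sample_landmarks(rotation = 10, translation = 3, level = "L2L3",
                         pose = list(flexion = list(angle = 0, shift = c(0, 0)),
                                     extension = list(angle = 0, shift = c(0, 0))))
  sigma <- 0.043
  singles <- numeric(1000)
  means <- numeric(1000)
  for (i in 1:1000) {
    noise <- rnorm(3, 0, sigma)
    m <- measure_segment_triplicate(lm$flexion, lm$extension,
                                    rotation_noise = c(0, 0, 0),
                                    translation_noise = noise)
    singles[i] <- 3 + noise[1]
    means[i] <- m$translation
  }
  expect_equal(sd(singles), sigma, tolerance = 0.1)
  expect_equal(sd(means), sigma / sqrt(3), tolerance = 0.1)
})
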