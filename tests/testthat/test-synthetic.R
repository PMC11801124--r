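test_that("same truth seed regenerates bit-identical datasets", {
  tr <- synthetic_truth(seed = 13)
  ds1 <- generate_dataset(2, 4, 20, tr)
  ds2 <- generate_dataset(2, 4, 20, tr)
  expect_identical(ds1$features$single$features$spectrogram,
                   ds2$features$single$features$spectrogram)
  expect_identical(ds1$responses$multi[[2]]$data, ds2$responses$multi[[2]]$data)
  expect_identical(ds1$behavior, ds2$behavior)
  expect_identical(ds1$subject_gains, ds2$subject_gains)
})

test_that("noiseless responses equal the feature-kernel convolution sum exactly", {
  tr <- synthetic_truth(noise_sd = 0, seed = 17)
  ds <- generate_dataset(2, 4, 15, tr)
  for (cond in ds$conditions)
    expect_identical(ds$responses[[cond]][[1]]$data, truth_response(ds, cond, 1))
})

test_that("realized envelope-lip correlation hits the target", {
  for (target in c(0.25, 0.4, 0.55)) {
    tr <- synthetic_truth(av_correlation = target, seed = 19)
    ds <- generate_dataset(1, 1, 60, tr)
    for (cond in ds$conditions) {
      env <- colMeans(ds$features[[cond]]$features$spectrogram)
      lip <- ds$features[[cond]]$features$lip[1, ]
      expect_equal(cor(env, lip), target, tolerance = 0.05)
    }
  }
})

test_that("dataset generator enforces its preconditions", {
  tr <- synthetic_truth(seed = 1)
  expect_error(generate_dataset(2, 4, 5, tr), "10 s")
  expect_error(generate_dataset(2, 0, 20, tr), "n_channels")
  expect_error(synthetic_truth(condition_gains = list(a = -1, b = 1)), "positive")
  expect_error(synthetic_truth(noise_df = 0), "noise_df")
  expect_error(synthetic_truth(noise_sd = -1), "noise_sd")
  tr_bad <- synthetic_truth(kernel_lags_ms = seq(500, 700, 10),
                            kernels = list(spectrogram = numeric(21),
                                           onsets = numeric(21),
                                           lip = numeric(21)), seed = 1)
  expect_error(generate_dataset(2, 4, 20, tr_bad), "lag support")
  # time axes and durations are consistent across features and responses
  ds <- generate_dataset(2, 4, 12, tr)
  expect_identical(n_samples(ds$features$single), 1200L)
  expect_identical(ncol(ds$responses$single[[1]]$data), 1200L)
})

test_that("behavior generator: null effect, monotone link, scales, errors", {
  set.seed(5)
  big <- data.frame(subject = rep(1:300, each = 2),
                    condition = rep(c("single", "multi"), 300),
                    tracking = rnorm(600))
  beh0 <- generate_behavior(big, behavior_effect = 0,
                            subject_intercept_sd = 0.3, noise_df = 5, seed = 2)
  expect_lt(abs(cor(beh0$tracking, beh0$comprehension)), 0.1)

  # zero noise, zero intercept spread, positive effect: deterministic
  # monotone link, Spearman correlation exactly 1 (uniform tracking keeps all
  # z-scores inside the clipping range)
  bigu <- big; bigu$tracking <- runif(600)
  beh1 <- generate_behavior(bigu, behavior_effect = 1,
                            subject_intercept_sd = 0, noise_df = 5, seed = 3)
  expect_equal(cor(beh1$tracking, beh1$comprehension, method = "spearman"), 1,
               tolerance = 1e-12)

  expect_true(all(beh0$comprehension >= 0 & beh0$comprehension <= 100))
  expect_true(all(beh0$difficulty >= 1 & beh0$difficulty <= 5))
  expect_true(all(beh0$engagement >= 1 & beh0$engagement <= 5))
  # difficulty decreases with tracking under a positive effect
  beh2 <- generate_behavior(big, behavior_effect = 0.8,
                            subject_intercept_sd = 0, noise_df = 30, seed = 4)
  expect_lt(cor(beh2$tracking, beh2$difficulty), 0)

  expect_error(generate_behavior(big, 0.5, 0.3, noise_df = 0, seed = 1), "noise_df")
  expect_error(generate_behavior(big, 0.9, 0.9, noise_df = 5, seed = 1), "variance budget")
  expect_error(generate_behavior(big[1:2, ], 0.5, 0.3, 5, 1), "2 subjects")
})
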