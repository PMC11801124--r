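test_that("design matrix: window counts, impulse response, zero features", {
  fs <- toy_features(n = 900, n_bands = 2)
  # non-overlapping tiling reading: 14 windows of 50 ms over [-100, 600]
  d_tile <- build_design(fs, -100, 600, 50, spacing_ms = 50)
  expect_identical(d_tile$n_windows, 14L)
  expect_identical(ncol(d_tile$X), 2L * 14L)
  # default: one window per sample step
  d <- build_design(fs, -100, 600, 50)
  expect_identical(d$n_windows, 66L)
  expect_identical(length(d$lags_ms), 70L)
  expect_identical(range(d$lags_ms), c(-100, 590))

  # all-zero feature gives all-zero columns
  z <- feature_set(list(lip = matrix(0, 1, 900)))
  expect_identical(max(abs(build_design(z)$X)), 0)

  # unit impulse: each column reproduces its shifted Hamming window
  imp <- matrix(0, 1, 400); imp[1, 200] <- 1
  di <- build_design(feature_set(list(lip = imp)), -100, 600, 50, spacing_ms = 50)
  ham <- as.numeric(signal::hamming(5))
  for (k in c(1L, 5L, 14L)) {
    col <- di$X[, k]
    lag0 <- di$info$lag_start_ms[k] / 10
    expect_equal(col[200 + lag0 + 0:4], ham, tolerance = 1e-12)
    expect_identical(sum(col != 0), 5L)
  }

  expect_error(build_design(fs, -100, 600, 45), "divide")
  expect_error(build_design(fs, -100, 600, 35), "multiple")
  expect_error(build_design(fs, 100, -100, 50), "tmin")
})

test_that("cross-validation folds are contiguous and deterministic", {
  f <- cv_folds(103, 4)
  expect_identical(f, cv_folds(103, 4))
  expect_identical(length(f), 103L)
  expect_true(all(diff(f) >= 0))            # contiguous blocks in time order
  expect_identical(sort(unique(f)), 1:4)
  expect_lte(diff(range(table(f))), 1)      # near-equal sizes
})

test_that("compiled boosting matches the naive R reference implementation", {
  set.seed(42)
  n <- 120; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  beta_true <- c(0.6, -0.4, 0, 0.3, 0, 0)
  y <- as.numeric(X %*% beta_true + 0.3 * rnorm(n))
  tr <- 1:80; va <- 81:120
  ref <- r_boost_reference(X[tr, ], y[tr], X[va, ], y[va],
                           delta = 0.02, patience = 8)
  cpp <- boost_channel_cpp(crossprod(X[tr, ]), crossprod(X[tr, ], y[tr])[, 1],
                           X[va, ], y[va], 0.02, 8L, 10000L)
  expect_equal(as.numeric(cpp$beta), ref$beta, tolerance = 1e-10)
  # training error never increases at any accepted step
  expect_true(all(diff(ref$train_errors) <= 1e-12))
})

test_that("boosting recovers kernels, ignores zero features, and is affine-invariant", {
  lag_ms <- seq(0, 400, 10)
  tr <- synthetic_truth(
    kernels = list(spectrogram = exp(-(lag_ms - 70)^2 / (2 * 25^2)),
                   onsets = numeric(41), lip = numeric(41)),
    condition_gains = list(single = c(spectrogram = 1, onsets = 1, lip = 1)),
    noise_sd = 0, seed = 23)
  ds <- generate_dataset(1, 1, 40, tr)
  spec <- ds$features$single$features$spectrogram
  lipz <- matrix(0, 1, ncol(spec))
  d <- build_design(feature_set(list(spectrogram = spec, lip = lipz)))
  fit <- boosting_fit(d, ds$responses$single[[1]])

  # an identically zero feature can never be selected: kernel exactly zero
  expect_identical(max(abs(fit$kernels["lip", 1, ])), 0)
  expect_gt(fit$accuracies[1], 0.9)
  k_true <- approx(lag_ms, tr$kernels$spectrogram, xout = fit$lags_ms, rule = 2)$y
  k_true[fit$lags_ms < 0 | fit$lags_ms > 400] <- 0
  expect_gt(cor(fit$kernels["spectrogram", 1, ], k_true), 0.9)

  # accuracies are invariant under common affine rescaling of the response
  resp2 <- ds$responses$single[[1]]
  resp2$data <- 5 + 3 * resp2$data
  fit2 <- boosting_fit(d, resp2)
  expect_equal(fit2$accuracies, fit$accuracies, tolerance = 1e-6)

  expect_error(boosting_fit(d, ds$responses$single[[1]]$data[, 1:300, drop = FALSE]),
               "sample counts")
  short <- feature_set(list(spectrogram = spec[, 1:500, drop = FALSE]))
  expect_error(boosting_fit(build_design(short),
                            ds$responses$single[[1]]$data[, 1:500, drop = FALSE]),
               "underdetermined")
})

test_that("prediction accuracy: identities, closed-form oracle, degenerate input", {
  set.seed(3)
  y <- rnorm(50)
  expect_identical(prediction_accuracy(y, y), 1)
  expect_identical(prediction_accuracy(y, -y), -1)
  a <- rep(c(1, -1), 25); b <- rep(c(1, 1, -1, -1), length.out = 50)
  expect_lt(abs(prediction_accuracy(a, b)), 1e-12)  # orthogonal, zero-mean

  # fixed 5-sample pair against the covariance formula
  p <- c(1.2, -0.5, 0.3, 2.2, -1.0); q <- c(0.7, 0.1, -0.4, 1.9, 0.2)
  oracle <- sum((p - mean(p)) * (q - mean(q))) /
    sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
  expect_equal(prediction_accuracy(p, q), oracle, tolerance = 1e-14)

  expect_error(prediction_accuracy(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(prediction_accuracy(1:2, 1:2), "3 samples")
  expect_error(prediction_accuracy(1:4, 1:5), "length")
})

test_that("TRF post-processing: smoothing identities, vector norm, time smoothing", {
  # build a small model by hand
  lags <- seq(-100, 590, 10)
  K <- array(0, dim = c(1, 3, length(lags)), dimnames = list("lip", NULL, NULL))
  K[1, 1, ] <- sin(lags / 50); K[1, 2, ] <- cos(lags / 80); K[1, 3, ] <- 0.5
  model <- structure(list(kernels = K, lags_ms = lags, basis_ms = 50,
                          accuracies = c(0.2, 0.3, 0.1), features = "lip",
                          coords = NULL, orientation_groups = NULL),
                     class = "trf_model")

  # isolated channels (farther than 4 SD apart): smoothing is the identity
  far <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  m1 <- postprocess_trf(model, coords = far, smoothing_sd_mm = 5)
  expect_equal(m1$kernels, K, tolerance = 1e-12)

  # two coincident channels: smoothed value is their mean
  co <- rbind(c(0, 0, 0), c(0, 0, 0), c(100, 100, 100))
  m2 <- postprocess_trf(model, coords = co, smoothing_sd_mm = 5)
  mean12 <- (K[1, 1, ] + K[1, 2, ]) / 2
  expect_equal(m2$kernels[1, 1, ], mean12, tolerance = 1e-12)
  expect_equal(m2$kernels[1, 2, ], mean12, tolerance = 1e-12)

  # orientation triplet with lag values (3, 4, 0) has norm 5
  K3 <- array(0, dim = c(1, 3, 2), dimnames = list("lip", NULL, NULL))
  K3[1, , 1] <- c(3, 4, 0); K3[1, , 2] <- c(1, 2, 2)
  model3 <- structure(list(kernels = K3, lags_ms = c(0, 10), basis_ms = 50,
                           accuracies = c(0.1, 0.1, 0.1), features = "lip",
                           coords = far, orientation_groups = c(1L, 1L, 1L)),
                      class = "trf_model")
  m3 <- postprocess_trf(model3, smoothing_sd_mm = 0, orientation_norm = TRUE)
  expect_equal(as.numeric(m3$kernels[1, 1, ]), c(5, 3), tolerance = 1e-12)

  expect_error(postprocess_trf(model, coords = far, smoothing_sd_mm = 0,
                               orientation_norm = TRUE), "orientation groups")
  expect_error(postprocess_trf(model, coords = NULL), "coordinates")
})

test_that("peak detection: single bump, ramp, and double bump latencies", {
  lags <- seq(-100, 590, 10)
  bump <- exp(-(lags - 160)^2 / (2 * 30^2))
  pk <- detect_peaks(bump, lags)
  expect_identical(nrow(pk), 1L)
  expect_lte(abs(pk$latency_ms - 160), 10)

  ramp <- seq_along(lags) * 0.1
  expect_identical(nrow(detect_peaks(ramp, lags)), 0L)

  two <- exp(-(lags - 70)^2 / (2 * 20^2)) + 0.8 * exp(-(lags - 180)^2 / (2 * 25^2))
  pk2 <- detect_peaks(two, lags)
  expect_identical(nrow(pk2), 2L)
  expect_lte(abs(pk2$latency_ms[1] - 70), 10)
  expect_lte(abs(pk2$latency_ms[2] - 180), 10)

  # peaks outside [-50, 550] are suppressed (edge regression artifacts)
  edge <- exp(-(lags + 90)^2 / (2 * 10^2))
  expect_identical(nrow(detect_peaks(edge, lags)), 0L)
})
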