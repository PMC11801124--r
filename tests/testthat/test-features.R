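test_that("FIR design rule reproduces the printed filter orders", {
  expect_identical(design_fir_order("lowpass", 2.5, 1000)$order, 1320L)
  expect_identical(design_fir_order("highpass", 2.0, 100)$order, 166L)
  # odd raw order is rounded up to even: ceil(3.3*100/2.1) = 158 (already even),
  # ceil(3.3*100/4) = 83 -> 84
  expect_identical(design_fir_order("lowpass", 4, 100)$order, 84L)
  expect_identical(design_fir_order("lowpass", 3.3, 100)$order, 100L)

  k <- design_fir_order("lowpass", 4, 100, cutoff_hz = 10)$kernel
  expect_length(k, 85L)
  expect_equal(k, rev(k))           # linear phase: symmetric windowed sinc
  expect_equal(sum(k), 1, tolerance = 1e-3)  # unit DC gain for a lowpass

  expect_error(design_fir_order("lowpass", 60, 100), "transition")
  expect_error(design_fir_order("lowpass", 4, 100, cutoff_hz = 70), "cutoff")
})

test_that("gammatone spectrogram: shape, band selectivity, silence, homogeneity", {
  fs_in <- 10000
  t <- seq(0, 10 - 1 / fs_in, by = 1 / fs_in)
  tone <- sin(2 * pi * 500 * t)
  gb <- gammatone_bands(tone, fs_in)
  spec <- gb$features$spectrogram
  expect_identical(dim(spec), c(8L, 1000L))
  expect_true(all(is.finite(spec)))

  # the band whose frequency range contains 500 Hz carries the most energy;
  # oracle: locate the band from the edges, independently of the filter code
  edges <- attr(gb, "band_edges")
  band_500 <- findInterval(500, edges)
  expect_identical(which.max(rowMeans(spec)), band_500)

  # scaling audio by c scales bands by c^0.6 (compressive homogeneity)
  gb2 <- gammatone_bands(2 * tone, fs_in)
  expect_equal(gb2$features$spectrogram, 2^0.6 * spec, tolerance = 1e-3)

  silent <- gammatone_bands(numeric(fs_in * 2), fs_in)
  expect_identical(max(abs(silent$features$spectrogram)), 0)

  expect_error(gammatone_bands(cbind(tone, tone), fs_in), "mono")
  expect_error(gammatone_bands(c(tone[1:20000], NA), fs_in), "NA")
})

test_that("acoustic onsets: steady state is silent, edges are localized and compressive", {
  n <- 300
  const <- feature_set(list(spectrogram = matrix(1, 8, n)))
  on_c <- acoustic_onsets(const)$features$onsets
  expect_lt(max(on_c), 1e-9)

  sp <- matrix(0, 8, n); sp[3, 150:n] <- 1
  on_s <- acoustic_onsets(feature_set(list(spectrogram = sp)))$features$onsets
  expect_true(all(on_s >= 0))
  peak_at <- which.max(on_s[3, ])
  expect_lte(abs(peak_at - 150) * 10, 50)      # transient within 50 ms of the step
  expect_lt(max(on_s[-3, ]), 1e-9)             # other bands untouched

  sp10 <- sp; sp10[3, 150:n] <- 10
  on_s10 <- acoustic_onsets(feature_set(list(spectrogram = sp10)))$features$onsets
  expect_lt(max(on_s10[3, ]) / max(on_s[3, ]), 10)  # saturating compression

  # brute-force oracle: direct evaluation of delay layer + saturation + DoG
  set.seed(4)
  m <- matrix(abs(rnorm(8 * 60)), 8, 60)
  got <- acoustic_onsets(feature_set(list(spectrogram = m)))$features$onsets
  delays_ms <- seq(3, 5, length.out = 10)
  ctr <- mean(delays_ms); sdm <- 2
  w <- (ctr - delays_ms) / sdm^2 * exp(-(delays_ms - ctr)^2 / (2 * sdm^2))
  w <- w - mean(w)
  sat <- function(v) 30 * v / (1 + 30 * v)
  expected <- matrix(0, 8, 60)
  for (b in 1:8) for (t0 in 1:60) {
    acc <- 0
    for (k in 1:10) {
      tau <- delays_ms[k] / 10
      f <- floor(tau); a <- tau - f
      i1 <- max(1, t0 - f); i2 <- max(1, t0 - f - 1)
      acc <- acc + w[k] * sat((1 - a) * m[b, i1] + a * m[b, i2])
    }
    expected[b, t0] <- max(acc, 0)
  }
  expect_equal(got, expected, tolerance = 1e-12)

  expect_error(acoustic_onsets(feature_set(list(spectrogram = matrix(1, 4, 50)))), "8-band")
})

test_that("lip aperture: areas, FFT interpolation exactness, bad input rejection", {
  # closed polygon on the unit circle: shoelace equals the inscribed-polygon
  # area exactly, which approaches pi
  k <- 100
  th <- seq(0, 2 * pi, length.out = k + 1)[1:k]
  circ <- as.vector(rbind(cos(th), sin(th)))
  frames <- matrix(rep(circ, 8), nrow = 8, byrow = TRUE)
  la <- lip_aperture(frames, 25)
  expect_equal(la$features$lip[1, 1], k / 2 * sin(2 * pi / k), tolerance = 1e-9)
  expect_equal(la$features$lip[1, 1], pi, tolerance = 3e-3)

  # axes input: ellipse area pi*a*b/4; a = b = 2 gives exactly pi
  ax <- matrix(2, nrow = 5, ncol = 2)
  la2 <- lip_aperture(ax, 25)
  expect_equal(unname(la2$features$lip[1, ]), rep(pi, 20), tolerance = 1e-9)

  # constant input stays constant under 25 -> 100 Hz upsampling (DC preserved)
  expect_equal(max(abs(la2$features$lip - pi)), 0, tolerance = 1e-9)

  # band-limited sinusoid is interpolated exactly (analytic oracle)
  x25 <- sin(2 * pi * 2 * seq(0, 2 - 1 / 25, by = 1 / 25))
  x100 <- sin(2 * pi * 2 * seq(0, 2 - 1 / 100, by = 1 / 100))
  expect_lt(max(abs(fft_interp(x25, 200) - x100)), 1e-6)

  # FFT interpolation preserves mean and total power of band-limited inputs
  set.seed(8)
  for (rep in 1:5) {
    z <- as.numeric(fft_interp(rnorm(25), 50))  # band-limited by construction
    zi <- fft_interp(z, 200)
    expect_equal(mean(zi), mean(z), tolerance = 1e-6)
    expect_equal(mean(zi^2), mean(z^2), tolerance = 1e-6)
  }

  bowtie <- matrix(rep(c(0, 0, 1, 1, 1, 0, 0, 1), 3), nrow = 3, byrow = TRUE)
  expect_error(lip_aperture(bowtie, 25), "self-intersecting")
  expect_error(lip_aperture(ax, 0), "fps")
  expect_error(lip_aperture(ax[1, , drop = FALSE], 25), "2 frames")
})
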