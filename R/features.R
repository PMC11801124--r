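#' Hamming-window FIR design rule
#'
#' Computes the filter order for a Hamming-windowed sinc FIR filter from the
#' desired transition bandwidth, using the classic design rule
#' `order = ceil(3.3 * fs / transition_width)`, rounded up to the nearest even
#' integer so the filter can be applied as a one-pass zero-phase (linear-phase,
#' delay-compensated) filter. Optionally also returns the windowed-sinc kernel.
#'
#' @param filter_type `"lowpass"` or `"highpass"`.
#' @param transition_width_hz transition bandwidth in Hz; must lie strictly
#'   between 0 and the Nyquist frequency.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz optional cutoff frequency in Hz; when given, the
#'   windowed-sinc kernel (length `order + 1`) is returned as well.
#' @return a list with elements `order` (even integer) and `kernel` (numeric
#'   vector, or `NULL` when no cutoff was supplied).
#' @examples
#' design_fir_order("lowpass", 2.5, 1000)$order   # 1320
#' design_fir_order("highpass", 2.0, 100)$order   # 166
#' @export
design_fir_order <- function(filter_type = c("lowpass", "highpass"),
                             transition_width_hz, fs, cutoff_hz = NULL) {
  filter_type <- match.arg(filter_type)
  if (!is.numeric(transition_width_hz) || length(transition_width_hz) != 1L ||
      transition_width_hz <= 0 || transition_width_hz >= fs / 2)
    stop("`transition_width_hz` must lie in (0, fs/2)")
  order <- as.integer(ceiling(3.3 * fs / transition_width_hz))
  if (order %% 2L == 1L) order <- order + 1L
  kernel <- NULL
  if (!is.null(cutoff_hz)) {
    if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
      stop("`cutoff_hz` must lie in (0, fs/2)")
    kernel <- signal::fir1(order, cutoff_hz / (fs / 2),
                           type = switch(filter_type, lowpass = "low", highpass = "high"),
                           window = signal::hamming(order + 1L))
    kernel <- as.numeric(kernel)
  }
  list(order = order, kernel = kernel)
}

# Glasberg & Moore equivalent rectangular bandwidth (Hz) at center frequency f.
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# ERB-number scale and its inverse, used to space gammatone center frequencies.
hz_to_erbnum <- function(f) 21.4 * log10(1 + 0.00437 * f)
erbnum_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# Fourth-order gammatone FIR kernel at center frequency cf, normalized to
# unit gain at cf.
gammatone_kernel <- function(cf, fs, dur_s = 0.1) {
  t <- seq(0, dur_s, by = 1 / fs)
  b <- 1.019 * erb_bandwidth(cf)
  h <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  gain <- Mod(sum(h * exp(-2i * pi * cf * t)))
  h / gain
}

fft_convolve <- function(x_fft, h, nfft, n_out) {
  h_fft <- fft(c(h, numeric(nfft - length(h))))
  y <- Re(fft(x_fft * h_fft, inverse = TRUE)) / nfft
  y[seq_len(n_out)]
}

#' Gammatone-filterbank spectrogram in eight logarithmic bands
#'
#' Decomposes a mono waveform with a 256-channel gammatone filterbank between
#' 20 and 5,000 Hz (center frequencies equally spaced on the ERB-number scale),
#' computes per-channel RMS envelopes in 0.01 s windows (yielding the 100 Hz
#' feature rate), averages channels into eight logarithmically spaced frequency
#' bands over 100-5,000 Hz (channels below 100 Hz are omitted), and compresses
#' each band with exponent 0.6.
#'
#' @param audio numeric vector, mono waveform; must be finite.
#' @param fs_in input sampling rate in Hz (>= 10 kHz and divisible by 100).
#' @param n_channels number of gammatone channels before band averaging.
#' @param f_lo,f_hi filterbank frequency cutoffs in Hz.
#' @param n_bands number of output bands.
#' @param band_lo lowest retained band edge in Hz (channels below are dropped).
#' @param compression amplitude compression exponent.
#' @return a [feature_set()] holding an `n_bands` x samples `spectrogram`
#'   matrix at 100 Hz, with attributes `band_edges` (Hz) and `center_freqs`
#'   (Hz, retained channels).
#' @export
gammatone_bands <- function(audio, fs_in, n_channels = 256L, f_lo = 20,
                            f_hi = 5000, n_bands = 8L, band_lo = 100,
                            compression = 0.6) {
  if (!is.null(dim(audio)) && min(dim(audio)) > 1L)
    stop("`audio` must be mono (a single channel)")
  audio <- as.numeric(audio)
  if (anyNA(audio) || !all(is.finite(audio))) stop("`audio` contains NA/non-finite values")
  if (fs_in < 10000) stop("`fs_in` must be at least 10 kHz")
  if (fs_in %% AV_FS != 0) stop("`fs_in` must be divisible by 100 Hz")
  if (length(audio) < fs_in) stop("`audio` must be at least 1 s long")

  cfs <- erbnum_to_hz(seq(hz_to_erbnum(f_lo), hz_to_erbnum(f_hi),
                          length.out = n_channels))
  keep <- cfs >= band_lo
  cfs_kept <- cfs[keep]

  win <- fs_in / AV_FS
  n_frames <- floor(length(audio) / win)
  n_use <- n_frames * win
  nfft <- stats::nextn(n_use + ceiling(0.1 * fs_in), 2)
  x_fft <- fft(c(audio[seq_len(n_use)], numeric(nfft - n_use)))

  env <- matrix(0, nrow = length(cfs_kept), ncol = n_frames)
  for (i in seq_along(cfs_kept)) {
    y <- fft_convolve(x_fft, gammatone_kernel(cfs_kept[i], fs_in), nfft, n_use)
    env[i, ] <- sqrt(colMeans(matrix(y^2, nrow = win)))
  }

  edges <- exp(seq(log(band_lo), log(f_hi), length.out = n_bands + 1L))
  band_of <- pmin(findInterval(cfs_kept, edges, rightmost.closed = TRUE), n_bands)
  spec <- matrix(0, nrow = n_bands, ncol = n_frames)
  for (b in seq_len(n_bands)) {
    idx <- which(band_of == b)
    if (!length(idx)) stop("empty frequency band; increase `n_channels`")
    spec[b, ] <- colMeans(env[idx, , drop = FALSE])^compression
  }
  out <- feature_set(list(spectrogram = spec))
  attr(out, "band_edges") <- edges
  attr(out, "center_freqs") <- cfs_kept
  out
}

# Fractional-delay copy of x (delay in samples, >= 0), linear interpolation,
# edge value replicated so steady state produces no spurious transient.
frac_delay <- function(x, d) {
  f <- floor(d); a <- d - f
  xf <- if (f > 0) c(rep(x[1L], f), x[seq_len(length(x) - f)]) else x
  xf1 <- c(xf[1L], xf[seq_len(length(x) - 1L)])
  (1 - a) * xf + a * xf1
}

#' Auditory edge detection (acoustic onsets)
#'
#' Applies a neurally inspired onset detector to each band of a gammatone
#' spectrogram: a delay layer (10 delays from 3 to 5 ms), a saturating
#' compressive nonlinearity with scaling factor 30 applied to each delayed
#' copy, and a receptive field given by the derivative of a Gaussian window
#' (SD = 2 ms) across the delay axis, followed by half-wave rectification.
#' Sustained (steady-state) input yields zero output; rising band energy
#' yields a positive transient.
#'
#' @param x a [feature_set()] containing a non-negative 8-band `spectrogram`
#'   at 100 Hz.
#' @param delays_ms delay-layer taps in ms.
#' @param saturation scaling factor of the compressive nonlinearity
#'   `L(v) = s*v / (1 + s*v)`.
#' @param rf_sd_ms SD (ms) of the Gaussian whose derivative forms the
#'   receptive field over the delay axis.
#' @return a [feature_set()] with a non-negative `onsets` matrix matching the
#'   spectrogram's shape.
#' @export
acoustic_onsets <- function(x, delays_ms = seq(3, 5, length.out = 10),
                            saturation = 30, rf_sd_ms = 2) {
  if (!inherits(x, "feature_set") || is.null(x$features$spectrogram))
    stop("`x` must be a feature_set containing a spectrogram")
  spec <- x$features$spectrogram
  if (nrow(spec) != 8L) stop("expected an 8-band spectrogram")
  if (x$fs != AV_FS) stop("expected a 100 Hz spectrogram")
  if (any(spec < 0)) stop("spectrogram must be non-negative")

  samp_ms <- 1000 / x$fs
  tau <- delays_ms / samp_ms                 # delays in samples
  ctr <- mean(delays_ms)
  w <- (ctr - delays_ms) / rf_sd_ms^2 * exp(-(delays_ms - ctr)^2 / (2 * rf_sd_ms^2))
  w <- w - mean(w)                           # derivative-of-Gaussian: zero net weight

  onsets <- matrix(0, nrow = nrow(spec), ncol = ncol(spec))
  for (b in seq_len(nrow(spec))) {
    acc <- numeric(ncol(spec))
    for (k in seq_along(tau)) {
      d <- frac_delay(spec[b, ], tau[k])
      acc <- acc + w[k] * (saturation * d / (1 + saturation * d))
    }
    onsets[b, ] <- pmax(acc, 0)
  }
  feature_set(list(onsets = onsets))
}

# Shoelace area of a closed polygon given as c(x1, y1, x2, y2, ...).
polygon_area <- function(xy) {
  x <- xy[seq(1, length(xy), by = 2)]
  y <- xy[seq(2, length(xy), by = 2)]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(xy) {
  x <- xy[seq(1, length(xy), by = 2)]
  y <- xy[seq(2, length(xy), by = 2)]
  n <- length(x)
  pts <- cbind(x, y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(pts[i, ], pts[if (i == n) 1L else i + 1L, ],
                             pts[j, ], pts[if (j == n) 1L else j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' FFT-based interpolation (band-limited upsampling)
#'
#' Upsamples a uniformly sampled series by zero-padding its discrete Fourier
#' spectrum. Exact for band-limited periodic signals; preserves the mean (DC
#' component) of any input.
#'
#' @param x numeric vector.
#' @param n_out desired output length (>= `length(x)`).
#' @return numeric vector of length `n_out`.
#' @export
fft_interp <- function(x, n_out) {
  n <- length(x)
  if (n_out < n) stop("fft_interp only upsamples (n_out >= length(x))")
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(n_out)
  if (n %% 2L == 0L) {
    h <- n %/% 2L
    Y[seq_len(h)] <- X[seq_len(h)]
    Y[h + 1L] <- X[h + 1L] / 2                 # split the Nyquist bin
    Y[n_out - h + 1L] <- X[h + 1L] / 2
    if (h > 1L) Y[(n_out - h + 2L):n_out] <- X[(h + 2L):n]
  } else {
    h <- (n + 1L) %/% 2L
    Y[seq_len(h)] <- X[seq_len(h)]
    Y[(n_out - (n - h) + 1L):n_out] <- X[(h + 1L):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Lip aperture time series from contours or axes
#'
#' Computes the area enclosed by the lip contour for every video frame --
#' higher values mean a wider mouth opening -- and upsamples the series to
#' 100 Hz by FFT-based interpolation. Input frames are either full contours
#' (columns `x1, y1, x2, y2, ...`, a closed polygon; area via the shoelace
#' formula) or horizontal/vertical axis lengths (two columns `a, b`; area of
#' the inscribed ellipse, `pi * a * b / 4`).
#'
#' @param frames numeric matrix or data frame, one row per video frame.
#' @param fps video frame rate in Hz (e.g. 25).
#' @return a [feature_set()] with a 1 x samples `lip` matrix at 100 Hz.
#' @export
lip_aperture <- function(frames, fps) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) stop("`fps` must be positive")
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (nrow(frames) < 2L) stop("need at least 2 frames")
  if (anyNA(frames)) stop("`frames` contains missing values")
  nc <- ncol(frames)
  if (nc == 2L) {
    area <- pi * frames[, 1L] * frames[, 2L] / 4
  } else if (nc >= 6L && nc %% 2L == 0L) {
    for (i in seq_len(nrow(frames)))
      if (polygon_self_intersects(frames[i, ]))
        stop("self-intersecting lip contour in frame ", i)
    area <- apply(frames, 1L, polygon_area)
  } else {
    stop("`frames` must have 2 columns (axes) or an even number >= 6 (contour)")
  }
  n_out <- nrow(frames) * AV_FS / fps
  if (abs(n_out - round(n_out)) > 1e-9)
    stop("frame count does not map to a whole number of 100 Hz samples")
  feature_set(list(lip = matrix(fft_interp(area, round(n_out)), nrow = 1L)))
}
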