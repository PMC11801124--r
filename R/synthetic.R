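#' Ground truth for a synthetic audiovisual tracking dataset
#'
#' Bundles every parameter of the data-generating process: per-feature TRF
#' kernels, per-condition gains, the 1/f noise model, the target
#' envelope--lip correlation, and the behavioral effect structure. The
#' defaults emulate a two-condition listening experiment (clear single-speaker
#' speech vs. a harder multispeaker "cocktail party" condition): acoustic
#' kernels carry early bumps (70/180-190 ms), the lip kernel later ones
#' (160/290 ms), acoustic gains drop and the lip gain rises in the harder
#' condition.
#'
#' @param kernels named list of numeric vectors (`spectrogram`, `onsets`,
#'   `lip`), each a TRF sampled on `kernel_lags_ms`. `NULL` uses the defaults.
#' @param kernel_lags_ms lag axis of the kernels in ms (multiples of 10,
#'   within -100..600).
#' @param condition_gains named list (one entry per condition) of positive
#'   gains; each entry is a scalar applied to all kernels or a named vector
#'   with one gain per feature.
#' @param noise_sd scale of the additive 1/f response noise (a.u.).
#' @param noise_exponent spectral slope of the 1/f noise.
#' @param av_correlation target lag-zero Pearson correlation between the
#'   broadband envelope and the lip aperture.
#' @param behavior_effect standardized slope linking tracking to behavior
#'   (|value| <= 1; it is the slope after z-scoring both sides).
#' @param subject_intercept_sd SD of the per-subject random intercepts on the
#'   standardized behavioral scale.
#' @param noise_df degrees of freedom of the Student-t behavioral noise.
#' @param lip_lead_ms how far the lip aperture leads the acoustic envelope
#'   (visual speech precedes audio).
#' @param syllable_rate_hz mean syllable rate of the pulse-train envelope
#'   surrogate.
#' @param seed integer RNG seed; regenerating with the same truth gives
#'   bit-identical datasets.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(kernels = NULL,
                            kernel_lags_ms = seq(0, 400, by = 10),
                            condition_gains = list(
                              single = c(spectrogram = 1, onsets = 1, lip = 0.4),
                              multi = c(spectrogram = 0.7, onsets = 0.7, lip = 1.2)),
                            noise_sd = 3,
                            noise_exponent = 1,
                            av_correlation = 0.4,
                            behavior_effect = 0.5,
                            subject_intercept_sd = 0.3,
                            noise_df = 5,
                            lip_lead_ms = 120,
                            syllable_rate_hz = 4.1,
                            seed = 42L) {
  if (is.null(kernels)) {
    bump <- function(lat, width, amp)
      amp * exp(-(kernel_lags_ms - lat)^2 / (2 * width^2))
    kernels <- list(
      spectrogram = bump(70, 25, 1.0) + bump(180, 45, 0.7),
      onsets      = bump(70, 25, 1.2) + bump(190, 45, 0.8),
      lip         = bump(160, 35, 0.8) + bump(290, 55, 0.6))
  }
  kernels <- lapply(kernels, as.numeric)
  if (!all(vapply(kernels, length, 1L) == length(kernel_lags_ms)))
    stop("each kernel must be sampled on `kernel_lags_ms`")
  if (!all(vapply(kernels, function(k) all(is.finite(k)), TRUE)))
    stop("kernels must be finite")
  if (any(abs(kernel_lags_ms %% 10) > 1e-9))
    stop("`kernel_lags_ms` must be multiples of 10 ms (100 Hz lag grid)")
  gains <- unlist(condition_gains)
  if (any(gains <= 0)) stop("condition gains must be positive")
  if (abs(av_correlation) > 1) stop("`av_correlation` must lie in [-1, 1]")
  if (abs(behavior_effect) > 1)
    stop("|behavior_effect| must be <= 1 (it is a standardized slope)")
  if (noise_df <= 0) stop("`noise_df` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(kernels = kernels, kernel_lags_ms = kernel_lags_ms,
                 condition_gains = condition_gains, noise_sd = noise_sd,
                 noise_exponent = noise_exponent,
                 av_correlation = av_correlation,
                 behavior_effect = behavior_effect,
                 subject_intercept_sd = subject_intercept_sd,
                 noise_df = noise_df, lip_lead_ms = lip_lead_ms,
                 syllable_rate_hz = syllable_rate_hz,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed", x$seed, "\n")
  cat("  kernels:", paste(names(x$kernels), collapse = ", "),
      "on lags", min(x$kernel_lags_ms), "..", max(x$kernel_lags_ms), "ms\n")
  cat("  conditions:", paste(names(x$condition_gains), collapse = ", "),
      "| noise_sd", x$noise_sd, "| av_correlation", x$av_correlation, "\n")
  invisible(x)
}

# 1/f^exponent noise of length n, unit SD, synthesized in the frequency domain.
pink_noise <- function(n, exponent = 1) {
  nf <- n %/% 2L
  freqs <- seq_len(nf)
  amp <- freqs^(-exponent / 2)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(n)
  spec[2:(nf + 1L)] <- amp * exp(1i * phases)
  if (n %% 2L == 0L) {
    spec[nf + 1L] <- Re(spec[nf + 1L])  # Nyquist bin must be real
    if (nf > 1L) spec[n:(nf + 2L)] <- Conj(spec[2:nf])
  } else {
    spec[n:(nf + 2L)] <- Conj(spec[2:(nf + 1L)])
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

shift_series <- function(x, by) {
  # positive `by` advances the series (x[t] <- x[t + by]), edge replicated
  n <- length(x)
  if (by >= 0) c(x[(by + 1L):n], rep(x[n], by)) else c(rep(x[1L], -by), x[seq_len(n + by)])
}

smooth_hamming <- function(x, len) {
  w <- as.numeric(signal::hamming(len)); w <- w / sum(w)
  pad <- length(w)
  y <- stats::filter(c(rep(x[1L], pad), x, rep(x[length(x)], pad)), w, sides = 2)
  as.numeric(y[pad + seq_along(x)])
}

# Syllable stream surrogate: onsets with Gamma-distributed inter-onset
# intervals (shape 4) at the given mean rate, sustained syllable durations
# (mean 130 ms, capped below the next onset), lognormal amplitudes, and a
# shared slow "phrasing" amplitude modulation.
syllable_stream <- function(n, rate_hz, fs = AV_FS) {
  dur_s <- n / fs
  n_pulse <- ceiling(dur_s * rate_hz * 2) + 10L
  iv <- rgamma(n_pulse, shape = 4, scale = 1 / (4 * rate_hz))
  times <- cumsum(iv)
  keep <- times < dur_s
  times <- times[keep]
  k <- length(times)
  dur <- pmin(rgamma(k, shape = 6, scale = 0.13 / 6), iv[seq_len(k)] * 0.9)
  amps <- rlnorm(k, 0, 0.3)
  phrase <- exp(0.8 * as.numeric(scale(smooth_hamming(rnorm(n), round(1.0 * fs)))))
  list(onset = floor(times * fs) + 1L, len = pmax(1L, round(dur * fs)),
       amps = amps, phrase = phrase, n = n)
}

# Acoustic envelope of a syllable stream: sustained syllable boxcars smoothed
# with a 50 ms Hamming window, under the phrasing modulation.
stream_envelope <- function(stream, fs = AV_FS) {
  env0 <- numeric(stream$n)
  for (i in seq_along(stream$onset)) {
    a <- stream$onset[i]
    b <- min(stream$n, a + stream$len[i] - 1L)
    env0[a:b] <- env0[a:b] + stream$amps[i]
  }
  smooth_hamming(env0, round(0.05 * fs)) * stream$phrase
}

# Lip-aperture core of the same stream: the mouth opens `lead_ms` before each
# acoustic onset and stays open through the syllable; smoothed 150 ms.
stream_lip_core <- function(stream, lead_ms, fs = AV_FS) {
  lead <- round(lead_ms / 1000 * fs)
  lip0 <- numeric(stream$n)
  for (i in seq_along(stream$onset)) {
    a <- max(1L, stream$onset[i] - lead)
    b <- min(stream$n, stream$onset[i] + stream$len[i] - 1L)
    lip0[a:b] <- lip0[a:b] + stream$amps[i]
  }
  smooth_hamming(lip0 * stream$phrase, round(0.15 * fs))
}

# Mixes the stream-driven lip core with an independent smooth process so the
# lag-zero envelope-lip correlation hits the target exactly (in sample).
make_lip <- function(env, lip_core, target_r, fs = AV_FS) {
  l1 <- as.numeric(scale(lip_core))
  l2 <- as.numeric(scale(smooth_hamming(rnorm(length(env)), round(0.15 * fs))))
  mix_r <- function(w) stats::cor(env, w * l1 + (1 - w) * l2)
  if (mix_r(1) < target_r)
    stop("`av_correlation` = ", target_r, " unreachable: the lip-aperture ",
         "process correlates only ", round(mix_r(1), 3), " with the envelope; ",
         "reduce the target or `lip_lead_ms`")
  lo <- if (mix_r(0) <= target_r) 0 else -1
  w <- stats::uniroot(function(w) mix_r(w) - target_r, c(lo, 1), tol = 1e-10)$root
  mix <- w * l1 + (1 - w) * l2
  2 + as.numeric(scale(mix))   # positive aperture scale; correlation unchanged
}

# Convolution of series x with kernel k sampled at integer sample lags:
# y(t) = sum_l k[l] * x(t - lag[l]); out-of-range samples are zero.
conv_lagged <- function(x, k, lag_samples) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_along(k)) {
    if (k[i] == 0) next
    l <- lag_samples[i]
    if (l >= 0) {
      if (l < n) y[(l + 1L):n] <- y[(l + 1L):n] + k[i] * x[seq_len(n - l)]
    } else {
      m <- -l
      if (m < n) y[seq_len(n - m)] <- y[seq_len(n - m)] + k[i] * x[(m + 1L):n]
    }
  }
  y
}

resolve_gain <- function(condition_gains, condition, feature) {
  g <- condition_gains[[condition]]
  if (length(g) == 1L && is.null(names(g))) return(as.numeric(g))
  if (!feature %in% names(g))
    stop("no gain for feature '", feature, "' in condition '", condition, "'")
  as.numeric(g[[feature]])
}

# Fixed channel sensitivity profiles (channels x features), cycling through
# acoustic-dominant, lip-dominant, mixed and weakly responsive channels so
# that accuracy maps carry fROI structure.
channel_profiles <- function(n_channels) {
  base <- rbind(acoustic = c(1, 1, 0.05),
                lip      = c(0.05, 0.05, 1),
                mixed    = c(0.5, 0.5, 0.5),
                weak     = c(0.05, 0.05, 0.05))
  colnames(base) <- c("spectrogram", "onsets", "lip")
  prof <- base[rep(seq_len(4L), length.out = n_channels), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

grid_coords <- function(n_channels, spacing_mm = 7) {
  k <- ceiling(n_channels^(1 / 3))
  g <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1)))
  g[seq_len(n_channels), , drop = FALSE] * spacing_mm
}

#' Generate a synthetic audiovisual tracking dataset
#'
#' Simulates, per condition, a stimulus (8-band spectrogram surrogate built
#' from a smoothed pulse train at the syllable rate, auditory-edge onsets
#' derived from it, and a lip aperture that leads the envelope and matches the
#' target audiovisual correlation) and, per subject and channel, a neural
#' response formed by convolving the band-averaged features with the truth
#' kernels (scaled by condition, channel and subject gains) plus 1/f noise.
#' Behavioral scores are generated from a per-subject tracking proxy via
#' [generate_behavior()].
#'
#' @param n_subjects number of simulated subjects.
#' @param n_channels number of response channels (>= 1); coordinates are laid
#'   out on a 3-D grid with 7 mm spacing.
#' @param duration_s stimulus duration per condition in seconds (>= 10).
#' @param truth a [synthetic_truth()] object.
#' @return an object of class `synthetic_dataset`: a list with `features`
#'   (per-condition [feature_set()]), `responses` (per condition, a list of
#'   per-subject [neural_response()] objects), `behavior` (a behavior table),
#'   `truth`, `channel_gains`, `subject_gains` and `coords`.
#' @export
generate_dataset <- function(n_subjects, n_channels, duration_s, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (duration_s < 10) stop("`duration_s` must be at least 10 s")
  if (n_channels < 1) stop("`n_channels` must be >= 1")
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  lags <- truth$kernel_lags_ms
  if (min(lags) < -100 || max(lags) > 600)
    stop("kernel lag support must lie within [-100, 600] ms")

  set.seed(truth$seed)
  fs <- AV_FS
  n <- round(duration_s * fs)
  conditions <- names(truth$condition_gains)
  lag_samples <- round(lags / (1000 / fs))

  features <- list()
  for (cond in conditions) {
    stream <- syllable_stream(n, truth$syllable_rate_hz, fs)
    env <- stream_envelope(stream, fs)
    w_b <- seq(1, 0.5, length.out = 8L)
    spec <- matrix(0, nrow = 8L, ncol = n)
    for (b in 1:8) {
      mod <- pmax(1 + 0.3 * smooth_hamming(rnorm(n), round(0.1 * fs)), 0)
      spec[b, ] <- w_b[b] * env * mod
    }
    fset_spec <- feature_set(list(spectrogram = spec))
    onsets <- acoustic_onsets(fset_spec)$features$onsets
    lip_core <- stream_lip_core(stream, truth$lip_lead_ms, fs)
    lip <- make_lip(colMeans(spec), lip_core, truth$av_correlation, fs)
    features[[cond]] <- feature_set(list(spectrogram = spec, onsets = onsets,
                                         lip = matrix(lip, nrow = 1L)))
  }

  chan_gain <- channel_profiles(n_channels)
  subj_gain <- rlnorm(n_subjects, 0, 0.35)
  coords <- grid_coords(n_channels)

  responses <- list()
  for (cond in conditions) {
    fset <- features[[cond]]
    band_means <- lapply(fset$features, function(m) as.numeric(scale(colMeans(m))))
    conv_cache <- lapply(names(truth$kernels), function(f) {
      y <- conv_lagged(band_means[[f]], truth$kernels[[f]], lag_samples)
      if (sd(y) > 0) y / sd(y) else y   # unit SD so gains set the SNR exactly
    })
    names(conv_cache) <- names(truth$kernels)
    responses[[cond]] <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      resp <- matrix(0, nrow = n_channels, ncol = n)
      for (ch in seq_len(n_channels)) {
        sig <- numeric(n)
        for (f in names(truth$kernels)) {
          g <- resolve_gain(truth$condition_gains, cond, f) *
            chan_gain[ch, f] * subj_gain[s]
          sig <- sig + g * conv_cache[[f]]
        }
        if (truth$noise_sd > 0)
          sig <- sig + truth$noise_sd * pink_noise(n, truth$noise_exponent)
        resp[ch, ] <- sig
      }
      responses[[cond]][[s]] <- neural_response(resp, coords, fs)
    }
  }

  acoustic_strength <- vapply(conditions, function(cond)
    mean(c(resolve_gain(truth$condition_gains, cond, "spectrogram"),
           resolve_gain(truth$condition_gains, cond, "onsets"))), 1)
  tracking <- data.frame(
    subject = rep(seq_len(n_subjects), times = length(conditions)),
    condition = rep(conditions, each = n_subjects),
    tracking = as.numeric(outer(subj_gain, acoustic_strength)))
  behavior <- if (n_subjects >= 2L)
    generate_behavior(tracking, truth$behavior_effect,
                      truth$subject_intercept_sd, truth$noise_df,
                      seed = truth$seed + 1L)
  else NULL   # behavioral model needs repeated measures across subjects

  structure(list(features = features, responses = responses,
                 behavior = behavior, truth = truth,
                 channel_gains = chan_gain, subject_gains = subj_gain,
                 coords = coords, conditions = conditions),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n <- n_samples(x$features[[1L]])
  cat("<synthetic_dataset> ", length(x$subject_gains), " subject(s), ",
      nrow(x$channel_gains), " channel(s), ", n / x$features[[1L]]$fs,
      " s per condition\n  conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Noiseless truth response for a synthetic dataset
#'
#' Recomputes the deterministic part of a channel's response (the sum over
#' features of the band-averaged feature convolved with the truth kernel and
#' all gains) -- with `noise_sd = 0` the generated response equals this
#' exactly.
#'
#' @param dataset a [generate_dataset()] result.
#' @param condition condition name.
#' @param subject subject index.
#' @return channels x samples matrix.
#' @export
truth_response <- function(dataset, condition, subject) {
  truth <- dataset$truth
  fset <- dataset$features[[condition]]
  lag_samples <- round(truth$kernel_lags_ms / (1000 / fset$fs))
  band_means <- lapply(fset$features, function(m) as.numeric(scale(colMeans(m))))
  n <- n_samples(fset)
  n_channels <- nrow(dataset$channel_gains)
  conv_cache <- lapply(names(truth$kernels), function(f) {
    y <- conv_lagged(band_means[[f]], truth$kernels[[f]], lag_samples)
    if (sd(y) > 0) y / sd(y) else y
  })
  names(conv_cache) <- names(truth$kernels)
  resp <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    sig <- numeric(n)
    for (f in names(truth$kernels))
      sig <- sig + resolve_gain(truth$condition_gains, condition, f) *
        dataset$channel_gains[ch, f] * dataset$subject_gains[subject] * conv_cache[[f]]
    resp[ch, ] <- sig
  }
  resp
}

#' Generate behavioral scores from tracking metrics
#'
#' Simulates comprehension (\%), subjective difficulty (1-5) and engagement
#' (1-5) from a per-subject/condition tracking metric via a standardized
#' linear model with per-subject random intercepts and Student-t noise:
#' `score_latent = intercept[subject] + effect * z(tracking) + t_noise`. The
#' residual and intercept variances are budgeted so the latent score has unit
#' variance, making `behavior_effect` the standardized slope that a
#' multilevel regression on z-scored variables should recover. Comprehension
#' and engagement increase with tracking; difficulty decreases (the sign is
#' flipped), matching the direction of effects in audiovisual listening
#' experiments. Scores are mapped to their native scales and clipped.
#'
#' @param tracking data frame with columns `subject`, `condition`,
#'   `tracking` (>= 2 subjects).
#' @param behavior_effect standardized slope (|value| <= 1).
#' @param subject_intercept_sd SD of subject random intercepts; requires
#'   `behavior_effect^2 + subject_intercept_sd^2 <= 1`.
#' @param noise_df Student-t degrees of freedom (> 0).
#' @param seed integer RNG seed.
#' @return a data frame (class `behavior_table`) with columns `subject`,
#'   `condition`, `tracking`, `comprehension`, `difficulty`, `engagement`.
#' @export
generate_behavior <- function(tracking, behavior_effect, subject_intercept_sd,
                              noise_df, seed) {
  if (!is.data.frame(tracking) ||
      !all(c("subject", "condition", "tracking") %in% names(tracking)))
    stop("`tracking` must have columns subject, condition, tracking")
  if (length(unique(tracking$subject)) < 2L) stop("need at least 2 subjects")
  if (noise_df <= 0) stop("`noise_df` must be positive")
  b <- behavior_effect; su <- subject_intercept_sd
  if (b^2 + su^2 > 1)
    stop("variance budget exceeded: behavior_effect^2 + subject_intercept_sd^2 must be <= 1")

  set.seed(as.integer(seed))
  n <- nrow(tracking)
  subj <- match(tracking$subject, unique(tracking$subject))
  tr <- tracking$tracking
  z <- if (sd(tr) > 0) as.numeric(scale(tr)) else numeric(n)
  resid_sd <- sqrt(max(0, 1 - b^2 - su^2))
  t_scale <- if (noise_df > 2) resid_sd / sqrt(noise_df / (noise_df - 2)) else resid_sd

  latent <- function(sign) {
    u <- rnorm(length(unique(subj)), 0, su)
    u[subj] + sign * b * z + t_scale * rt(n, noise_df)
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- data.frame(
    subject = tracking$subject, condition = tracking$condition, tracking = tr,
    comprehension = clip(70 + 15 * latent(+1), 0, 100),
    difficulty = clip(3 + 0.8 * latent(-1), 1, 5),
    engagement = clip(3.8 + 0.6 * latent(+1), 1, 5))
  class(out) <- c("behavior_table", "data.frame")
  out
}
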