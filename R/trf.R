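#' Lagged design matrix on a Hamming-window basis
#'
#' Expands each feature band into one design column per basis window: the band
#' convolved with a Hamming window of length `basis_ms`, delayed to that
#' window's position. Windows tile the integration window `[tmin_ms, tmax_ms]`
#' without overlap at `basis_ms` spacing, so a TRF estimated on this basis is
#' a sum of shifted Hamming windows. Samples beyond the record are
#' zero-padded.
#'
#' @param features a [feature_set()].
#' @param tmin_ms,tmax_ms integration window in ms (negative = response leads
#'   the stimulus).
#' @param basis_ms basis window length in ms; must divide
#'   `tmax_ms - tmin_ms` and be a multiple of the 10 ms sample period.
#' @param spacing_ms spacing between basis-window onsets in ms. The default
#'   (`NULL`) places one window per sample step, so the basis acts as a 50 ms
#'   Hamming smoothing of the impulse-response estimate and smooth kernels
#'   are representable without ripple. `spacing_ms = basis_ms` tiles the
#'   integration window without overlap.
#' @return an object of class `trf_design`: list with the design matrix `X`
#'   (samples x columns), per-column metadata `info` (feature, band, window,
#'   lag_start_ms), the kernel lag axis `lags_ms`, and the basis window.
#' @export
build_design <- function(features, tmin_ms = -100, tmax_ms = 600, basis_ms = 50,
                         spacing_ms = NULL) {
  stopifnot(inherits(features, "feature_set"))
  samp_ms <- 1000 / features$fs
  if (is.null(spacing_ms)) spacing_ms <- samp_ms
  if (tmin_ms >= tmax_ms) stop("`tmin_ms` must be < `tmax_ms`")
  if ((tmax_ms - tmin_ms) %% basis_ms != 0)
    stop("`basis_ms` must divide the integration window")
  if (basis_ms %% samp_ms != 0)
    stop("`basis_ms` must be a multiple of the sample period (", samp_ms, " ms)")
  if (spacing_ms %% samp_ms != 0 || spacing_ms <= 0 || spacing_ms > basis_ms)
    stop("`spacing_ms` must be a positive multiple of the sample period, <= `basis_ms`")
  L <- as.integer(basis_ms / samp_ms)
  sp <- as.integer(spacing_ms / samp_ms)
  n_win <- as.integer((tmax_ms - tmin_ms - basis_ms) / spacing_ms) + 1L
  n <- n_samples(features)
  ham <- as.numeric(signal::hamming(L))
  lag0 <- as.integer(tmin_ms / samp_ms)

  cols <- list()
  info <- list()
  for (f in names(features$features)) {
    m <- features$features[[f]]
    for (b in seq_len(nrow(m))) {
      x <- m[b, ]
      base <- as.numeric(stats::filter(c(numeric(L - 1L), x), ham,
                                       sides = 1))[L:(n + L - 1L)]
      for (k in seq_len(n_win) - 1L) {
        s <- lag0 + k * sp
        col <- numeric(n)
        if (s >= 0) {
          if (s < n) col[(s + 1L):n] <- base[seq_len(n - s)]
        } else {
          if (-s < n) col[seq_len(n + s)] <- base[(-s + 1L):n]
        }
        cols[[length(cols) + 1L]] <- col
        info[[length(info) + 1L]] <- data.frame(
          feature = f, band = b, window = k + 1L,
          lag_start_ms = tmin_ms + k * spacing_ms)
      }
    }
  }
  structure(list(
    X = do.call(cbind, cols),
    info = do.call(rbind, info),
    lags_ms = seq(tmin_ms, tmax_ms - samp_ms, by = samp_ms),
    basis = ham, basis_ms = basis_ms, spacing_ms = spacing_ms,
    spacing_samples = sp,
    tmin_ms = tmin_ms, tmax_ms = tmax_ms,
    fs = features$fs, n_windows = n_win,
    features = names(features$features),
    feature_bands = vapply(features$features, nrow, 1L)),
    class = "trf_design")
}

#' @export
print.trf_design <- function(x, ...) {
  cat("<trf_design> ", nrow(x$X), " samples x ", ncol(x$X), " columns (",
      x$n_windows, " x ", x$basis_ms, " ms windows per band), lags ",
      x$tmin_ms, "..", x$tmax_ms, " ms\n", sep = "")
  invisible(x)
}

# Map basis coefficients back to per-(feature, band) kernels on the lag axis.
reconstruct_kernels <- function(design, beta) {
  L <- length(design$basis)
  n_lags <- length(design$lags_ms)
  out <- list()
  for (f in design$features) {
    nb <- design$feature_bands[[f]]
    K <- matrix(0, nrow = nb, ncol = n_lags)
    for (b in seq_len(nb)) {
      sel <- which(design$info$feature == f & design$info$band == b)
      for (i in seq_along(sel)) {
        k0 <- (design$info$window[sel[i]] - 1L) * design$spacing_samples
        K[b, k0 + seq_len(L)] <- K[b, k0 + seq_len(L)] + beta[sel[i]] * design$basis
      }
    }
    out[[f]] <- K
  }
  out
}

#' Contiguous cross-validation folds
#'
#' Deterministically assigns samples to `n_folds` contiguous time blocks of
#' (near-)equal length, avoiding temporal leakage in autocorrelated data.
#'
#' @param n_samples number of samples.
#' @param n_folds number of folds.
#' @return integer vector of fold ids (1..n_folds).
#' @export
cv_folds <- function(n_samples, n_folds) {
  sizes <- diff(round(seq(0, n_samples, length.out = n_folds + 1L)))
  rep(seq_len(n_folds), times = sizes)
}

#' Estimate multivariate TRFs by greedy boosting
#'
#' Fits, per response channel, a sparse TRF on the Hamming-window basis by
#' coordinate-wise boosting: starting from a zero kernel, the single
#' (feature, basis window, sign) increment of size `step` that most reduces
#' the training L2 error is applied repeatedly; estimation stops early when
#' the validation L2 error has not improved for `patience` consecutive steps,
#' and the coefficients at the best validation error are kept. Fourfold
#' nested cross-validation (two training folds, one validation fold, one test
#' fold; contiguous time blocks) is used so each partition serves as test set
#' once. Design columns and response channels are z-scored before fitting.
#' The per-channel prediction accuracy is the Fisher-z average over folds of
#' the test-set Pearson correlation between predicted and observed response;
#' kernels are averaged over folds.
#'
#' @param design a [build_design()] result.
#' @param response a [neural_response()] or channels x samples matrix.
#' @param n_folds number of cross-validation folds (default 4).
#' @param step coefficient increment, in units of the (z-scored) response SD.
#' @param patience validation checks without improvement before stopping.
#' @param max_steps hard cap on boosting steps per channel and fold.
#' @return an object of class `trf_model`: band-averaged `kernels` (array
#'   feature x channel x lag), per-(feature, band) `band_kernels`,
#'   per-channel `accuracies`, per-fold `fold_accuracies`, the lag axis and
#'   fold layout.
#' @export
boosting_fit <- function(design, response, n_folds = 4L, step = 0.005,
                         patience = 10L, max_steps = 50000L) {
  stopifnot(inherits(design, "trf_design"))
  coords <- NULL; groups <- NULL
  if (inherits(response, "neural_response")) {
    coords <- response$coords; groups <- response$orientation_groups
    Y <- response$data
  } else {
    Y <- if (is.null(dim(response))) matrix(response, nrow = 1L) else as.matrix(response)
  }
  n <- ncol(Y)
  if (nrow(design$X) != n) stop("design and response sample counts differ")
  p <- ncol(design$X)
  if (n < 10L * design$n_windows)
    stop("underdetermined fit: need at least 10 samples per basis window (",
         10L * design$n_windows, " for this design)")
  if (n_folds < 3L) stop("nested cross-validation needs at least 3 folds")

  # z-score design columns (zero-variance columns stay zero) and channels
  Xz <- scale(design$X)
  bad <- !is.finite(attr(Xz, "scaled:scale")) | attr(Xz, "scaled:scale") == 0
  col_sd <- attr(Xz, "scaled:scale")
  if (any(bad)) { Xz[, bad] <- 0; col_sd[bad] <- 1 }
  Yz <- t(scale(t(Y)))
  if (any(!is.finite(Yz))) stop("response channel with zero variance")

  fold_id <- cv_folds(n, n_folds)
  n_chan <- nrow(Y)
  fold_r <- matrix(NA_real_, n_chan, n_folds)
  beta_sum <- matrix(0, p, n_chan)

  for (f in seq_len(n_folds)) {
    v <- f %% n_folds + 1L
    idx_te <- which(fold_id == f)
    idx_val <- which(fold_id == v)
    idx_tr <- which(!(fold_id %in% c(f, v)))
    Xtr <- Xz[idx_tr, , drop = FALSE]
    G <- crossprod(Xtr)
    Xv <- Xz[idx_val, , drop = FALSE]
    Xte <- Xz[idx_te, , drop = FALSE]
    for (ch in seq_len(n_chan)) {
      y <- Yz[ch, ]
      fit <- boost_channel_cpp(G, crossprod(Xtr, y[idx_tr])[, 1L],
                               Xv, y[idx_val], step, patience, max_steps)
      beta <- fit$beta
      beta_sum[, ch] <- beta_sum[, ch] + beta
      pred <- as.numeric(Xte %*% beta)
      fold_r[ch, f] <- if (sd(pred) > 0) stats::cor(pred, y[idx_te]) else 0
    }
  }

  acc <- apply(fold_r, 1L, function(r) fisher_average(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))
  beta_mean <- beta_sum / n_folds / col_sd   # back to per-unit-feature scale
  band_kernels <- lapply(seq_len(n_chan), function(ch)
    reconstruct_kernels(design, beta_mean[, ch]))
  n_lags <- length(design$lags_ms)
  kernels <- array(0, dim = c(length(design$features), n_chan, n_lags),
                   dimnames = list(design$features, NULL, NULL))
  for (ch in seq_len(n_chan))
    for (f in design$features)
      kernels[f, ch, ] <- colMeans(band_kernels[[ch]][[f]], na.rm = TRUE)

  structure(list(kernels = kernels, band_kernels = band_kernels,
                 lags_ms = design$lags_ms, basis_ms = design$basis_ms,
                 accuracies = as.numeric(acc), fold_accuracies = fold_r,
                 folds = fold_id, features = design$features,
                 coords = coords, orientation_groups = groups,
                 step = step, patience = patience),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat("<trf_model> ", dim(x$kernels)[2L], " channel(s), features: ",
      paste(x$features, collapse = ", "), "\n  lags ", min(x$lags_ms), "..",
      max(x$lags_ms), " ms | mean accuracy r = ",
      format(mean(x$accuracies), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Cross-validated prediction accuracy
#'
#' Pearson correlation between a predicted and an observed response; the
#' standard neural-tracking metric.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3), finite.
#' @return Pearson r.
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 samples")
  if (!all(is.finite(predicted)) || !all(is.finite(observed)))
    stop("inputs must be finite")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop("prediction accuracy undefined: zero variance")
  stats::cor(predicted, observed)
}

#' Spatial smoothing and orientation collapse of TRFs
#'
#' Smooths kernels across channels with Gaussian weights on the Euclidean
#' channel distance (accounting for interindividual anatomical variability),
#' optionally collapses free-orientation dipole triplets to one kernel per
#' source via the lag-wise Euclidean vector norm, and optionally smooths over
#' time with a Hamming window (for display). Accuracies are never smoothed;
#' when triplets are collapsed, per-source accuracy is the Fisher-z average
#' of the three orientations.
#'
#' @param model a [boosting_fit()] result.
#' @param coords channels x 3 coordinate matrix (mm); defaults to the
#'   coordinates carried by the model.
#' @param smoothing_sd_mm SD of the Gaussian spatial kernel (mm); weights are
#'   truncated beyond 4 SD. Use 0 to skip.
#' @param orientation_norm collapse orientation triplets to source-level
#'   kernel magnitudes?
#' @param temporal_window_ms optional Hamming smoothing window length in ms.
#' @return the modified `trf_model`.
#' @export
postprocess_trf <- function(model, coords = model$coords, smoothing_sd_mm = 5,
                            orientation_norm = FALSE, temporal_window_ms = NULL) {
  stopifnot(inherits(model, "trf_model"))
  if (is.null(coords)) stop("channel coordinates required")
  K <- model$kernels
  n_chan <- dim(K)[2L]
  if (nrow(coords) != n_chan) stop("`coords` must have one row per channel")

  if (smoothing_sd_mm > 0) {
    d <- as.matrix(stats::dist(coords))
    W <- exp(-d^2 / (2 * smoothing_sd_mm^2))
    W[d > 4 * smoothing_sd_mm] <- 0
    W <- W / rowSums(W)
    for (f in seq_len(dim(K)[1L]))
      K[f, , ] <- W %*% matrix(K[f, , ], nrow = n_chan)
  }

  acc <- model$accuracies
  groups <- model$orientation_groups
  if (orientation_norm) {
    if (is.null(groups))
      stop("orientation groups required for the vector-norm collapse")
    gids <- unique(groups)
    Kn <- array(0, dim = c(dim(K)[1L], length(gids), dim(K)[3L]),
                dimnames = list(dimnames(K)[[1L]], NULL, NULL))
    acc_n <- numeric(length(gids))
    coords_n <- matrix(0, length(gids), 3L)
    for (gi in seq_along(gids)) {
      idx <- which(groups == gids[gi])
      for (f in seq_len(dim(K)[1L]))
        Kn[f, gi, ] <- sqrt(colSums(K[f, idx, , drop = TRUE]^2))
      acc_n[gi] <- fisher_average(pmin(pmax(acc[idx], -1 + 1e-12), 1 - 1e-12))
      coords_n[gi, ] <- colMeans(coords[idx, , drop = FALSE])
    }
    K <- Kn; acc <- acc_n; coords <- coords_n; groups <- NULL
  }

  if (!is.null(temporal_window_ms)) {
    samp_ms <- 1000 / AV_FS
    Lt <- max(1L, round(temporal_window_ms / samp_ms))
    w <- as.numeric(signal::hamming(Lt)); w <- w / sum(w)
    for (f in seq_len(dim(K)[1L]))
      for (ch in seq_len(dim(K)[2L]))
        K[f, ch, ] <- smooth_hamming(K[f, ch, ], Lt)
  }

  model$kernels <- K
  model$accuracies <- acc
  model$coords <- coords
  model$orientation_groups <- groups
  model
}

#' Detect TRF magnitude peaks
#'
#' Local maxima of a TRF magnitude series, restricted to -50..550 ms by
#' default to suppress the regression artifacts that typically occur at the
#' edges of the integration window.
#'
#' @param trf numeric vector (TRF magnitude per lag).
#' @param lags_ms lag axis in ms, same length as `trf`.
#' @param window_ms two-element analysis window in ms.
#' @return data frame with `latency_ms` and `magnitude`, sorted by latency;
#'   zero rows when no interior local maximum exists.
#' @export
detect_peaks <- function(trf, lags_ms, window_ms = c(-50, 550)) {
  if (length(trf) != length(lags_ms)) stop("`trf` and `lags_ms` lengths differ")
  keep <- lags_ms >= window_ms[1L] & lags_ms <= window_ms[2L]
  x <- trf[keep]; lg <- lags_ms[keep]
  n <- length(x)
  if (n < 3L) return(data.frame(latency_ms = numeric(0), magnitude = numeric(0)))
  i <- 2:(n - 1L)
  pk <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  data.frame(latency_ms = lg[pk], magnitude = x[pk])
}
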