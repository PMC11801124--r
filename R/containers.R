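#' Stimulus feature set
#'
#' Container for named stimulus features sharing a single time axis. Each
#' feature is a numeric matrix (bands x samples). The canonical features of
#' the audiovisual tracking pipeline are `spectrogram` (8 bands), `onsets`
#' (8 bands) and `lip` (1 band), all sampled at 100 Hz.
#'
#' @param features named list of numeric matrices (bands x samples); vectors
#'   are promoted to 1-row matrices.
#' @param fs sampling rate in Hz (the pipeline uses 100 Hz throughout).
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(features, fs = AV_FS) {
  if (!is.list(features) || is.null(names(features)) || any(names(features) == ""))
    stop("`features` must be a named list of matrices")
  allowed <- c("spectrogram", "onsets", "lip")
  bad <- setdiff(names(features), allowed)
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         " (expected spectrogram, onsets, lip)")
  features <- lapply(features, function(x) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    storage.mode(x) <- "double"
    x
  })
  ns <- vapply(features, ncol, 1L)
  if (length(unique(ns)) != 1L)
    stop("all features must share the same number of samples")
  if (!all(vapply(features, function(x) all(is.finite(x)), TRUE)))
    stop("features must be finite")
  structure(list(features = features, fs = fs), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", n_samples(x), " samples @ ", x$fs, " Hz (",
      format(n_samples(x) / x$fs, digits = 4), " s)\n", sep = "")
  for (nm in names(x$features))
    cat("  ", nm, ": ", nrow(x$features[[nm]]), " band(s)\n", sep = "")
  invisible(x)
}

#' Number of samples in a feature set
#' @param x a `feature_set`.
#' @return integer sample count.
#' @export
n_samples <- function(x) ncol(x$features[[1L]])

#' Multichannel neural response
#'
#' Container for a continuous multichannel neural recording (sensor- or
#' source-space) at 100 Hz, with channel coordinates in mm and an optional
#' grouping of channels into free-orientation dipole triplets per source.
#'
#' @param data numeric matrix, channels x samples.
#' @param coords numeric matrix, channels x 3, positions in mm.
#' @param fs sampling rate in Hz.
#' @param orientation_groups optional integer vector (length = channels)
#'   assigning each channel to a source; each source must own exactly 3
#'   channels (the three orthogonal dipole orientations).
#' @return an object of class `neural_response`.
#' @export
neural_response <- function(data, coords, fs = AV_FS, orientation_groups = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("response data must be finite")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(data) || ncol(coords) != 3L)
    stop("`coords` must be a channels x 3 matrix of mm positions")
  if (!is.null(orientation_groups)) {
    orientation_groups <- as.integer(orientation_groups)
    if (length(orientation_groups) != nrow(data))
      stop("`orientation_groups` must have one entry per channel")
    if (any(table(orientation_groups) != 3L))
      stop("orientation groups must partition channels into disjoint triplets")
  }
  structure(list(data = data, coords = coords, fs = fs,
                 orientation_groups = orientation_groups),
            class = "neural_response")
}

#' @export
print.neural_response <- function(x, ...) {
  cat("<neural_response> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$fs, " Hz\n", sep = "")
  if (!is.null(x$orientation_groups))
    cat("  ", length(unique(x$orientation_groups)), " orientation triplet(s)\n", sep = "")
  invisible(x)
}
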