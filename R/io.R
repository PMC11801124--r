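#' Read and write pipeline objects as delimited text
#'
#' All on-disk formats are plain text so that intermediate results are
#' portable and diffable: feature sets and responses as CSV matrices
#' (samples in rows), behavior tables as CSV, and ground-truth/config
#' snapshots as YAML.
#'
#' @param x object to write.
#' @param dir target directory (created if missing).
#' @param prefix filename prefix.
#' @return `write_*` return the written paths invisibly; `read_*` return the
#'   reconstructed object.
#' @name avtrack_io
NULL

#' @rdname avtrack_io
#' @export
write_feature_set <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "feature_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(x$features)) {
    m <- t(x$features[[nm]])
    colnames(m) <- paste0("band_", seq_len(ncol(m)))
    p <- file.path(dir, paste0(prefix, nm, ".csv"))
    write.csv(m, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname avtrack_io
#' @export
read_feature_set <- function(dir, prefix = "") {
  feats <- list()
  for (nm in c("spectrogram", "onsets", "lip")) {
    p <- file.path(dir, paste0(prefix, nm, ".csv"))
    if (file.exists(p)) {
      m <- t(as.matrix(read.csv(p)))
      dimnames(m) <- NULL
      feats[[nm]] <- m
    }
  }
  if (!length(feats)) stop("no feature files found in ", dir)
  feature_set(feats)
}

#' @rdname avtrack_io
#' @export
write_neural_response <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "neural_response"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- t(x$data)
  colnames(m) <- paste0("ch_", seq_len(ncol(m)))
  p1 <- file.path(dir, paste0(prefix, "response.csv"))
  write.csv(m, p1, row.names = FALSE)
  co <- x$coords
  colnames(co) <- c("x_mm", "y_mm", "z_mm")
  p2 <- file.path(dir, paste0(prefix, "coords.csv"))
  write.csv(co, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname avtrack_io
#' @export
read_neural_response <- function(dir, prefix = "") {
  m <- t(as.matrix(read.csv(file.path(dir, paste0(prefix, "response.csv")))))
  co <- as.matrix(read.csv(file.path(dir, paste0(prefix, "coords.csv"))))
  dimnames(m) <- NULL
  dimnames(co) <- NULL
  neural_response(m, co)
}

#' @rdname avtrack_io
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in x$conditions) {
    write_feature_set(x$features[[cond]], file.path(dir, cond))
    for (s in seq_along(x$responses[[cond]]))
      write_neural_response(x$responses[[cond]][[s]], file.path(dir, cond),
                            prefix = sprintf("sub%02d_", s))
  }
  write.csv(as.data.frame(x$behavior), file.path(dir, "behavior.csv"),
            row.names = FALSE)
  truth <- x$truth
  yaml::write_yaml(list(
    kernel_lags_ms = truth$kernel_lags_ms,
    kernels = lapply(truth$kernels, as.numeric),
    condition_gains = lapply(truth$condition_gains, as.list),
    noise_sd = truth$noise_sd, noise_exponent = truth$noise_exponent,
    av_correlation = truth$av_correlation,
    behavior_effect = truth$behavior_effect,
    subject_intercept_sd = truth$subject_intercept_sd,
    noise_df = truth$noise_df, lip_lead_ms = truth$lip_lead_ms,
    syllable_rate_hz = truth$syllable_rate_hz, seed = truth$seed),
    file.path(dir, "truth.yaml"), precision = 12L)
  invisible(dir)
}

#' @rdname avtrack_io
#' @param path CSV file with columns `frame` (optional) plus either
#'   `axis_h, axis_v` or `x1, y1, x2, y2, ...`.
#' @export
read_lip_frames <- function(path) {
  d <- read.csv(path)
  if ("frame" %in% names(d)) d$frame <- NULL
  as.matrix(d)
}
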