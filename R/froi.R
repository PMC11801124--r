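#' Define a functional region of interest from an accuracy map
#'
#' Selects the channels whose prediction accuracy reaches the given
#' percentile of the whole-map accuracies (linear-interpolation percentile;
#' ties at the threshold are included via `>=`). Optionally unions the
#' selection with an existing fROI, e.g. to build a combined audiovisual fROI
#' from the acoustic and lip fROIs.
#'
#' @param accuracy_map numeric vector of per-channel prediction accuracies.
#' @param percentile percentile threshold in (0, 100); default 90.
#' @param union_with optional `froi` to union with.
#' @param model,condition names of the defining model and condition, recorded
#'   for provenance.
#' @return an object of class `froi`: channel indices, the percentile and the
#'   defining model/condition.
#' @export
define_froi <- function(accuracy_map, percentile = 90, union_with = NULL,
                        model = NA_character_, condition = NA_character_) {
  if (!all(is.finite(accuracy_map))) stop("`accuracy_map` must be finite")
  if (percentile <= 0 || percentile >= 100) stop("`percentile` must lie in (0, 100)")
  thr <- as.numeric(quantile(accuracy_map, percentile / 100, type = 7))
  idx <- which(accuracy_map >= thr)
  if (!is.null(union_with)) {
    stopifnot(inherits(union_with, "froi"))
    idx <- sort(union(idx, union_with$channels))
  }
  if (!length(idx)) stop("empty fROI selection")
  structure(list(channels = idx, percentile = percentile,
                 defining_model = model, defining_condition = condition),
            class = "froi")
}

#' @export
print.froi <- function(x, ...) {
  cat("<froi> ", length(x$channels), " channel(s) at the ", x$percentile,
      "th percentile", sep = "")
  if (!is.na(x$defining_model))
    cat(" (", x$defining_model, " model, ", x$defining_condition, " condition)", sep = "")
  cat("\n")
  invisible(x)
}

#' Fisher-z average of correlation coefficients
#'
#' Averages Pearson correlations on the variance-stabilized atanh scale and
#' back-transforms: `tanh(mean(atanh(r)))`.
#'
#' @param values numeric vector of correlations, all strictly inside (-1, 1).
#' @return averaged correlation.
#' @export
fisher_average <- function(values) {
  if (!all(is.finite(values))) stop("correlations must be finite")
  if (any(abs(values) >= 1)) stop("|r| = 1 has infinite Fisher z; cannot average")
  tanh(mean(atanh(values)))
}

#' Unique contribution of lip movements (percentage change)
#'
#' Expresses how much a combined acoustic + lip model improves on the
#' acoustic-only baseline within the same fROI:
#' `100 * (r_combined - r_acoustic) / r_acoustic`. Because the percentage
#' change explodes for near-zero baselines, values with
#' `0 < r_acoustic < floor` are flagged unstable, and non-positive baselines
#' yield `NA` with a warning (undefined percentage change).
#'
#' @param r_acoustic,r_combined fROI-averaged prediction accuracies (same
#'   subjects/conditions, element-wise).
#' @param floor baseline stability floor (default 0.01).
#' @return numeric vector of percentage changes with attribute `unstable`
#'   (logical; `TRUE` where the baseline is below the floor).
#' @export
unique_contribution <- function(r_acoustic, r_combined, floor = 0.01) {
  if (length(r_acoustic) != length(r_combined)) stop("length mismatch")
  out <- rep(NA_real_, length(r_acoustic))
  ok <- r_acoustic > 0
  if (any(!ok))
    warning(sum(!ok), " value(s) with non-positive acoustic baseline excluded (undefined % change)")
  out[ok] <- 100 * (r_combined[ok] - r_acoustic[ok]) / r_acoustic[ok]
  attr(out, "unstable") <- ok & r_acoustic < floor
  out
}

#' Bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))` with sample skewness
#' `g1` and sample excess kurtosis `g2` (bias-corrected, SAS-type
#' definitions). Values above 0.555 (the value attained by a uniform
#' distribution) indicate bimodality; a normal sample gives about 1/3.
#'
#' @param values numeric sample, n >= 4, non-zero variance.
#' @return the bimodality coefficient.
#' @export
bimodality_coefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 values")
  if (sd(values) == 0) stop("zero variance sample")
  g1 <- e1071::skewness(values, type = 2)
  g2 <- e1071::kurtosis(values, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}
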