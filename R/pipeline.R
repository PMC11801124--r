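#' Pipeline configuration
#'
#' Collects every tunable of the audiovisual tracking pipeline with its
#' default, so a run is fully described by one object (snapshotted alongside
#' the outputs).
#'
#' @param n_subjects,n_channels,duration_s synthetic dataset dimensions.
#' @param truth a [synthetic_truth()]; its seed is overridden by the fan-out
#'   of `seed`.
#' @param tmin_ms,tmax_ms,basis_ms TRF integration window and basis.
#' @param n_folds,step,patience boosting settings.
#' @param froi_percentile accuracy percentile defining fROIs.
#' @param froi_condition condition used to extract fROIs (the harder
#'   condition, which engages all features).
#' @param contribution_floor baseline stability floor for the percentage
#'   change.
#' @param smoothing_sd_mm spatial smoothing SD for TRF post-processing.
#' @param tfce_n_perm,tfce_E,tfce_H,tfce_step TFCE settings.
#' @param bayes_draws,bayes_warmup,bayes_chains MCMC settings.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8L, n_channels = 6L, duration_s = 60,
                            truth = synthetic_truth(),
                            tmin_ms = -100, tmax_ms = 600, basis_ms = 50,
                            n_folds = 4L, step = 0.005, patience = 10L,
                            froi_percentile = 90,
                            froi_condition = "multi",
                            contribution_floor = 0.01,
                            smoothing_sd_mm = 5,
                            tfce_n_perm = 1000L, tfce_E = 0.5, tfce_H = 2,
                            tfce_step = 0.1,
                            bayes_draws = 1000L, bayes_warmup = 1000L,
                            bayes_chains = 4L,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  truth <- snap$truth
  snap$truth <- list(
    kernel_lags_ms = truth$kernel_lags_ms,
    kernels = lapply(truth$kernels, as.numeric),
    condition_gains = lapply(truth$condition_gains, as.list),
    noise_sd = truth$noise_sd, noise_exponent = truth$noise_exponent,
    av_correlation = truth$av_correlation,
    behavior_effect = truth$behavior_effect,
    subject_intercept_sd = truth$subject_intercept_sd,
    noise_df = truth$noise_df, lip_lead_ms = truth$lip_lead_ms,
    syllable_rate_hz = truth$syllable_rate_hz, seed = truth$seed)
  snap
}

subset_features <- function(fset, names) {
  feature_set(fset$features[names], fs = fset$fs)
}

#' Run the audiovisual tracking pipeline end to end
#'
#' Orchestrates the full analysis on a synthetic (or supplied) dataset:
#' per condition and subject, three forward models are estimated by boosting
#' (acoustic = spectrogram + onsets; lip; combined acoustic + lip); fROIs are
#' defined from the group-level accuracy maps of the harder condition
#' (acoustic fROI, lip fROI, and their union as the audiovisual fROI);
#' fROI-averaged accuracies (Fisher-z) and the unique contribution of lip
#' movements are computed per subject and condition; conditions are compared
#' with [paired_test()]; the contribution distribution is assessed with
#' [bimodality_coefficient()]; and behavior is regressed on tracking with
#' [fit_multilevel()].
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all result tables
#'   (CSV), a YAML config snapshot, and a plain-text report are written.
#' @param dataset optional pre-built [generate_dataset()] result; by default
#'   a dataset is generated from `config`.
#' @return an object of class `avtrack_results`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)

  if (is.null(dataset)) {
    truth <- config$truth
    truth$seed <- seed + 101L
    dataset <- generate_dataset(config$n_subjects, config$n_channels,
                                config$duration_s, truth)
  }
  conds <- dataset$conditions
  if (!config$froi_condition %in% conds)
    stop("fROI stage: condition '", config$froi_condition, "' not in dataset")
  n_subj <- length(dataset$subject_gains)
  model_feats <- list(acoustic = c("spectrogram", "onsets"),
                      lip = "lip",
                      combined = c("spectrogram", "onsets", "lip"))

  # --- stage 1: forward models -------------------------------------------
  acc <- list()    # acc[[model]][[cond]]: channels x subjects
  for (m in names(model_feats)) {
    acc[[m]] <- list()
    for (cond in conds) {
      design <- build_design(subset_features(dataset$features[[cond]],
                                             model_feats[[m]]),
                             config$tmin_ms, config$tmax_ms, config$basis_ms)
      amat <- vapply(seq_len(n_subj), function(s) {
        fit <- boosting_fit(design, dataset$responses[[cond]][[s]],
                            n_folds = config$n_folds, step = config$step,
                            patience = config$patience)
        fit$accuracies
      }, numeric(config$n_channels))
      acc[[m]][[cond]] <- amat
    }
  }

  # --- stage 2: fROIs -----------------------------------------------------
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  group_map <- function(m, cond)
    apply(acc[[m]][[cond]], 1L, function(r) fisher_average(clamp(r)))
  froi_acoustic <- define_froi(group_map("acoustic", config$froi_condition),
                               config$froi_percentile, model = "acoustic",
                               condition = config$froi_condition)
  froi_lip <- define_froi(group_map("lip", config$froi_condition),
                          config$froi_percentile, model = "lip",
                          condition = config$froi_condition)
  froi_av <- define_froi(group_map("lip", config$froi_condition),
                         config$froi_percentile, union_with = froi_acoustic,
                         model = "acoustic+lip",
                         condition = config$froi_condition)

  # --- stage 3: fROI-averaged tracking and unique contribution ------------
  froi_mean <- function(m, cond, froi) vapply(seq_len(n_subj), function(s)
    fisher_average(clamp(acc[[m]][[cond]][froi$channels, s])), 1)
  tracking <- do.call(rbind, lapply(conds, function(cond) data.frame(
    subject = seq_len(n_subj), condition = cond,
    r_acoustic_froi = froi_mean("acoustic", cond, froi_acoustic),
    r_lip_froi = froi_mean("lip", cond, froi_lip),
    r_acoustic_av = froi_mean("acoustic", cond, froi_av),
    r_combined_av = froi_mean("combined", cond, froi_av))))
  contrib <- unique_contribution(tracking$r_acoustic_av,
                                 tracking$r_combined_av,
                                 floor = config$contribution_floor)
  tracking$contribution_pct <- as.numeric(contrib)
  tracking$contribution_unstable <- attr(contrib, "unstable")

  # --- stage 4: condition statistics --------------------------------------
  stats_out <- list()
  if (length(conds) == 2L && n_subj >= 5L) {  # paired tests need >= 5 pairs
    pick <- function(col, cond) tracking[tracking$condition == cond, col]
    hard <- config$froi_condition
    easy <- setdiff(conds, hard)[1L]
    ok <- complete.cases(cbind(pick("contribution_pct", hard),
                               pick("contribution_pct", easy)))
    stats_out$contribution_condition <- paired_test(
      pick("contribution_pct", hard)[ok], pick("contribution_pct", easy)[ok])
    stats_out$acoustic_condition <- paired_test(
      pick("r_acoustic_froi", hard), pick("r_acoustic_froi", easy))
    hc <- pick("contribution_pct", hard)
    stats_out$contribution_bimodality <-
      if (sum(is.finite(hc)) >= 4L && sd(hc[is.finite(hc)]) > 0)
        bimodality_coefficient(hc) else NA_real_
  }

  # --- stage 5: brain-behavior models -------------------------------------
  beh <- merge(as.data.frame(dataset$behavior), tracking,
               by = c("subject", "condition"))
  beh <- beh[order(beh$condition, beh$subject), ]
  bayes_out <- list()
  for (outc in c("comprehension", "difficulty", "engagement")) {
    bayes_out[[paste0(outc, "_acoustic")]] <- fit_multilevel(
      beh[[outc]], beh$r_acoustic_froi, beh$subject,
      n_draws = config$bayes_draws, n_warmup = config$bayes_warmup,
      n_chains = config$bayes_chains, seed = seed + 303L)
  }

  results <- structure(list(
    config = config, dataset = dataset, accuracies = acc,
    frois = list(acoustic = froi_acoustic, lip = froi_lip,
                 audiovisual = froi_av),
    tracking = tracking, behavior = beh, stats = stats_out,
    bayes = bayes_out), class = "avtrack_results")

  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_snapshot(results$config),
                   file.path(out_dir, "config.yaml"), precision = 12L)
  write.csv(results$tracking, file.path(out_dir, "tracking.csv"),
            row.names = FALSE)
  write.csv(results$behavior, file.path(out_dir, "behavior.csv"),
            row.names = FALSE)
  for (m in names(results$accuracies))
    for (cond in names(results$accuracies[[m]])) {
      a <- results$accuracies[[m]][[cond]]
      colnames(a) <- paste0("sub_", seq_len(ncol(a)))
      write.csv(a, file.path(out_dir, paste0("accuracy_", m, "_", cond, ".csv")),
                row.names = FALSE)
    }
  rpt <- file.path(out_dir, "report.txt")
  con <- file(rpt, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("audiovisual neural speech tracking: pipeline report")
  wl("conditions: ", paste(results$dataset$conditions, collapse = ", "))
  for (nm in names(results$frois))
    wl(nm, " fROI: ", length(results$frois[[nm]]$channels), " channel(s)")
  if (!is.null(results$stats$contribution_condition)) {
    st <- results$stats$contribution_condition
    wl(sprintf("unique lip contribution, condition contrast: %s, statistic = %.4f, p = %.5f, %s = %.3f",
               st$method, st$statistic, st$p.value, st$effect_type, st$effect_size))
    wl(sprintf("contribution bimodality coefficient: %.4f",
               results$stats$contribution_bimodality))
  }
  for (nm in names(results$bayes)) {
    bf <- results$bayes[[nm]]
    wl(sprintf("%s: b = %.3f, 89%% CI [%.3f, %.3f], PP(b>0) = %.2f%%, significant = %s, reliable = %s",
               nm, bf$b_mean, bf$ci_89[1L], bf$ci_89[2L], bf$pp_gt0,
               bf$significant, bf$reliable))
  }
  invisible(out_dir)
}

#' @export
print.avtrack_results <- function(x, ...) {
  cat("<avtrack_results> ", length(x$dataset$subject_gains), " subject(s), ",
      "conditions: ", paste(x$dataset$conditions, collapse = ", "), "\n", sep = "")
  if (!is.null(x$stats$contribution_condition)) {
    st <- x$stats$contribution_condition
    cat(sprintf("  lip contribution contrast: p = %.4g, %s = %.3f\n",
                st$p.value, st$effect_type, st$effect_size))
  }
  invisible(x)
}
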