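# avtrack

Audiovisual neural speech tracking with boosted temporal response functions.

## What this package is for

When someone listens to continuous speech while watching the speaker, their
neural activity "tracks" both the acoustics and the speaker's lip movements.
A central question for audiovisual speech research — and for applications
such as objective assessments of audiovisual speech perception — is how much
the lip movements contribute to neural tracking *over and above* the
acoustics (the two are correlated, since the mouth opens when sound comes
out), how much that unique visual contribution varies across listeners, and
whether it predicts behavior when visual speech is taken away (for example
by a face mask).

`avtrack` implements that analysis end to end for researchers working with
continuous multichannel recordings (MEG/EEG, sensor- or source-space):

1. **Stimulus features** — `gammatone_bands()` (8-band gammatone
   spectrogram, 100 Hz), `acoustic_onsets()` (auditory edge detection per
   band), `lip_aperture()` (lip-contour area, FFT-interpolated from video
   rate), plus the Hamming FIR design rule `design_fir_order()`.
2. **Forward models** — `build_design()` and `boosting_fit()` estimate
   multivariate temporal response functions (TRFs),

   ŷ(t) = Σᵢ Σ_τ hᵢ(τ) xᵢ(t−τ),  τ ∈ [−100, 600] ms,

   by greedy L2 boosting on a 50 ms Hamming-window basis with fourfold
   nested cross-validation and validation-based early stopping. Tracking is
   the cross-validated Pearson r between ŷ and y. `postprocess_trf()`
   smooths kernels spatially (Gaussian, SD 5 mm) and collapses
   free-orientation dipole triplets; `detect_peaks()` extracts TRF peak
   latencies.
3. **Unique contribution** — `define_froi()` (percentile-threshold
   functional ROIs), `fisher_average()`, and `unique_contribution()`
   compute 100·(r_combined − r_acoustic)/r_acoustic in a combined
   audiovisual fROI; `bimodality_coefficient()` assesses whether listeners
   split into lip-reliant and non-reliant groups (BC > 0.555 indicates
   bimodality).
4. **Inference** — `tfce_permutation_test()` (threshold-free cluster
   enhancement with sign-flip permutations for paired designs) and
   `paired_test()` (Shapiro-gated paired t / Wilcoxon with rank-biserial
   effect size); `fit_multilevel()` fits Bayesian Student-t regressions
   `behavior ~ 1 + tracking + (1 | subject)` with 89% credible intervals
   and the joint CI + posterior-probability significance rule.
5. **Synthetic data** — `generate_dataset()` / `generate_behavior()`
   simulate the full data structure (syllable-stream envelope, correlated
   lip aperture that leads the audio, condition-dependent TRF kernels, 1/f
   noise, behavioral scores with subject random intercepts and Student-t
   noise) with complete ground truth, so every stage is testable.
   `run_pipeline()` orchestrates everything.

## Worked example

```r
library(avtrack)

res <- run_pipeline(pipeline_config(n_subjects = 8, n_channels = 6,
                                    duration_s = 60, seed = 5))
print(res)
#> <avtrack_results> 8 subject(s), conditions: single, multi
#>   lip contribution contrast: p = 0.1126, cohens_d = 0.641

aggregate(cbind(r_acoustic_av, r_combined_av, contribution_pct)
          ~ condition, data = res$tracking, mean)
#>   condition r_acoustic_av r_combined_av contribution_pct
#> 1     multi         0.202         0.283           74.766
#> 2    single         0.151         0.172           14.789

print(res$bayes$comprehension_acoustic)
#> <bayes_fit> outcome ~ 1 + predictor + (1 | subject), Student-t errors
#>   b = 0.632, 89% CI [0.212, 1.073], PP(b>0) = 99.22%  *
```

Reading the numbers: the acoustic-only model predicts held-out responses in
the audiovisual fROI at r ≈ 0.15–0.20, a realistic neural-tracking range;
adding the lip feature raises accuracy much more in the harder multispeaker
condition (+75% vs +15% mean unique contribution), matching the ground
truth used by the simulation (lip kernel gain 1.2 vs 0.4), although with
only 8 simulated subjects the paired condition contrast is suggestive
rather than significant (d = 0.64, p = 0.11). The Bayesian model recovers
a positive standardized slope between acoustic tracking and comprehension
(b = 0.63, CI excluding 0, PP > 94.5% → significant under the joint rule);
the simulated truth is b = 0.5.

A thin command-line wrapper over the same functions is installed at
`inst/cli/avtrack.R` (subcommands `simulate`, `features`, `behavior`,
`run`).

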