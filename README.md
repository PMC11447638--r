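# neurodyn

Resting-state EEG temporal dynamics across unequal societies: a tested,
ROI-level analysis pipeline in R.

## The problem

Cross-country EEG studies ask whether structural income inequality — the
Gini coefficient, the percentage area between a country's Lorenz curve and
the 45° line of perfect equality,

```
G = 100 * (1 - sum_i (x_i - x_{i-1}) * (y_i + y_{i-1}))
```

— predicts individual brain dynamics over and above age, sex, education and
cognition. Answering that requires a harmonised multi-centre pipeline:
standardise heterogeneous recordings (0.5–40 Hz 8th-order zero-phase
Butterworth, 512 Hz, first 5 min, per-channel z-scoring), quantify signal
quality (OQD: percentage of 1-s epochs passing four artifact criteria), and
derive four families of outcomes per region of interest:

* **Complexity** — Higuchi fractal dimension, permutation entropy, Wiener
  entropy (spectral flatness) and spectral structure variability, plus a
  folded "uniform complexity scale" (z-scores above +1.2 are sign-flipped so
  both overly regular and noise-like signals map low);
* **Aperiodic spectrum** — Lorentzian parameterisation
  `A(F) = b - log10(k + F^chi)` of the Welch PSD (offset, knee, exponent;
  slope = −chi);
* **Band power** — mean nPSD and relative power density in canonical bands
  and subject-specific bands anchored at the individual alpha frequency
  (IAF) and theta/alpha transition (TF);
* **Connectivity** — Gaussian-copula mutual information, fully partialised
  conditional MI, and O-information, with weighted graph metrics (global
  efficiency, transitivity, density, small-worldness).

An inference layer reduces the ROI space by sign-flipping permutation tests
with Benjamini–Hochberg FDR, fits hierarchical regressions (R², Cohen's
f² = R²/(1−R²), model F/p), and trains median-binarised gradient-boosted
classifiers (10 × stratified 80/20 splits; AUC, accuracy, precision, recall,
F1, normalised gain importances).

Raw multi-centre recordings cannot ship with a package, so `neurodyn`
includes a first-class synthetic cohort generator whose recordings have
exactly known aperiodic parameters, oscillatory peak ratios and coupling
structure — every stage of the pipeline is tested against that ground truth.
See the methods vignette (`vignettes/eeg-inequality-pipeline.Rmd`) for the
models, parameter choices and their rationale.

## Worked example

```r
library(neurodyn)

# one synthetic 10-ROI recording: 1/f background (b = 0.5, k = 3,
# chi = 1.5) with alpha and beta peaks
sp  <- signal_spec(fs = 512, duration = 60, exponent = 1.5, knee = 3,
                   peaks = data.frame(f0 = c(10, 20), amp = c(0.4, 0.08),
                                      bw = c(1.2, 2.5)))
rec <- simulate_recording(sp, n_rois = 10, seed = 1)
rec
#> <recording> 10 channel(s) x 30720 samples @ 512 Hz (60.0 s), centre synthetic

assess_quality(rec)
#> <quality_report> OQD 100.0% (excellent), 60 epochs

feats <- extract_features(rec, per_roi = FALSE, target_fs = 512,
                          max_duration = 60, seed = 1)
round(unlist(feats[c("we_all", "pe_all", "fd_all", "ssv_all",
                     "slope_all", "alpha_rel_all", "geff_cmi")]), 4)
#>        we_all        pe_all        fd_all       ssv_all     slope_all
#>        0.4972        0.5848        1.0845        0.4222       -3.2524
#> alpha_rel_all      geff_cmi
#>       25.2808        0.4306
```

The complexity values sit mid-scale (a 1/f signal with oscillations is
neither a line nor white noise), a quarter of the relative power lies in the
alpha bands, and CMI global efficiency reflects the generator's modular
coupling. Single-recording aperiodic estimates are noisy (the fitted slope
here overshoots the generating −1.5); slopes are meant to be analysed at
cohort level, where the estimator tracks the generating exponent.

```r
# a small five-country cohort with the default planted inequality effects
tab <- run_cohort_pipeline(default_countries(5), effect_spec(), seed = 7,
                           fs = 256, duration = 30, per_roi = FALSE)
hierarchical_regression(tab, "we_all", "gini")
#> <regression_report> we_all ~ gini: R2 0.8902, f2 8.1075, F 389.16, p 1.14e-24, n 50
#>   feature   estimate   t_value      p_value
#> 1    gini -0.1780769 -19.72718 1.141902e-24
```

Higher Gini lowers Wiener entropy, as planted: the standardised coefficient
is negative and the model explains 89% of the variance in this small, clean
cohort.

A command-line front end chaining the stages
(`simulate | quality | features | infer`) ships at `inst/cli/neurodyn`.

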