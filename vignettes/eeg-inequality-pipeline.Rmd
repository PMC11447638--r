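---
title: "Resting-state EEG dynamics across unequal societies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG dynamics across unequal societies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

## What the package does

`neurodyn` implements a harmonised analysis of resting-state EEG temporal
dynamics at the region-of-interest (ROI) level, together with an inference
layer that relates country-level structural income inequality — the Gini
coefficient — to EEG outcomes across a multi-country cohort. Because raw
multi-centre recordings cannot ship with a package, a first-class synthetic
cohort generator produces ROI-level recordings with fully known ground truth,
so every stage (signal standardisation, quality indexing, complexity,
spectral and connectivity metrics, regression and classification) is
verifiable end to end.

## Signal model and generator

Each synthetic ROI signal is drawn from a target one-sided power spectral
density

$$S(F) \;=\; 10^{\,b - \log_{10}(k + F^{\chi})} \;+\;
  \sum_p a_p \, e^{-(F-f_p)^2 / 2w_p^2},$$

an aperiodic Lorentzian background (offset $b$ in log10-power units, knee
$k \ge 0$, exponent $\chi > 0$; the log–log slope is $-\chi$) plus Gaussian
oscillatory peaks — at least an alpha peak at the subject's individual alpha
frequency (IAF) and a beta peak at 20 Hz. White-noise Fourier amplitudes are
shaped to $\sqrt{S(F)}$, which makes the generating parameters exactly
recoverable in expectation. Oscillatory power adds *linearly* to the
background (powers of independent processes add), which matters for the
fitting algorithm below.

Two generator choices deserve emphasis:

* **Peak heights are ratios, not absolute amplitudes.** Peak amplitude is
  parameterised as a multiple of the aperiodic background at the peak
  frequency ($a_p = r_p\,S_{ap}(f_p)$, defaults $r_\alpha = 4.5$,
  $r_\beta = 2.5$). Per-channel z-scoring — a mandated harmonisation stage —
  fixes total signal power, so an effect planted on an absolute amplitude is
  cancelled by the rescaling, while a ratio effect survives. This is also the
  specparam notion of peak height above the background.
* **Connectivity is built from pair-specific latents.** Each ROI mixes a
  private component, one global factor (weight 0.15 — the baseline
  inter-channel correlation a quality criterion relies on), chain-edge
  latents linking neighbouring ROIs within each of two modules (weight 0.12,
  the segregated "backbone"), and one cross-module edge latent per ROI pair
  $(i, i+5)$ (weight $c_x$, default 0.06). Shared factors are eliminated by
  full partialisation, so only the pair latents can move conditional mutual
  information; and because global efficiency is computed on max-normalised
  weights, it is monotone in $c_x$ only while cross-links stay weaker than
  the backbone — hence $c_x$ is kept in $[0.01, 0.11]$.

### Cohort structure and planted effects

`simulate_cohort()` draws subjects per country (default: ten countries with
Gini 25–55%, ages $\mathcal N(55, 15)$ clipped to 20–90, education
$\mathcal N(12, 4)$ years, MMSE $\mathcal N(27.5, 2)$, balanced sex), maps
covariates through an `effect_spec()` to the generating parameters, and
records the truth in `true_*` columns. The default effects plant the
qualitative inequality pattern the inference layer is meant to detect:
with higher standardised Gini, a larger aperiodic exponent (hence lower
slope $-\chi$ and lower signal complexity), lower offset, weaker alpha and
beta peak ratios (lower band power), and stronger cross-module coupling
(higher CMI global efficiency).

The effect magnitudes were fixed by a one-shot sensitivity calibration: each
pipeline outcome was regressed on the two generator channels (exponent;
log alpha ratio) in a development cohort, and magnitudes chosen so that every
planted direction dominates its designated outcome. The binding constraints
are that the alpha-ratio effect must stay below roughly the exponent effect
(otherwise the ratio channel flips the fitted slope and the ordinal metrics)
and above about a third of it in magnitude (otherwise the exponent channel
flips the alpha-power sign, because with fixed total power a steeper
background *raises* the relative share of the alpha band). The defaults
(`exponent_gini = 0.45`, `alpha_gini = beta_gini = -0.15`,
`coupling_gini = 0.025`) give exponents in 0.9–2.1 and alpha ratios in
1.6–13 across the Gini range — physiologically plausible — and regression
effect sizes of the same order as typically reported for these outcomes
(R² of a few percent for slope and network metrics, tens of percent for
band power).

Artifact epochs (default 5% of 1-s epochs) are injected with one of four
failure modes chosen at random per epoch: large-amplitude bursts (×8),
flatlines, high-frequency tones (~32 Hz), and decorrelated channel noise —
exactly the four failure classes the quality index tests. The generator does
not emulate line noise, electrode drift, volume conduction, or non-Gaussian
background dynamics; passing tests therefore demonstrate internal
consistency of the estimators under the stated model, not robustness to
every property of real recordings.

## Standardisation and harmonisation

Recordings are resampled to 512 Hz (polyphase, with anti-alias filtering),
band-passed 0.5–40 Hz with an 8-pole Butterworth applied forward–backward
(an "8th-order zero-phase" net response), truncated to the first 300 s, and
per-channel z-scored. Resampling always precedes filtering: the
transfer-function form of a band-pass whose low edge sits at 0.5 Hz is
numerically unstable at sampling rates of 1024 Hz and above (the two-pass
filter diverges), while at 512 Hz it is well conditioned. Channels with zero
variance are flagged and excluded from scaling. Z-scoring is a per-channel
transform, so recruitment-centre grouping affects bookkeeping only.

Note the attenuation limits of this design: the 8-pole zero-phase band-pass
leaves ~13% of a 50 Hz tone's amplitude (its theoretical two-pass magnitude
at 50 Hz is 0.128). Stop-band rejection to below 1% would require roughly a
40th-order response; tests therefore assert agreement with the filter's own
theoretical magnitude, not an arbitrary rejection target.

## Quality index

The per-recording quality index is the percentage of 1-s epochs passing four
criteria, evaluated on z-scored data: (i) no constant channels and no
missing/infinite voltages; (ii) no sample with $|z| > 5$ and no degenerate
peak-to-peak range ($< 10^{-6}$ z-units); (iii) 25–40 Hz power at most 50% of
0.5–40 Hz power on every channel; (iv) at most 25% of channels whose maximum
absolute correlation with every other channel is below 0.2. The numeric
thresholds are package defaults (config-overridable); the category
boundaries are fixed: excellent for OQD ≥ 90, good for [80, 90), poor for
[60, 80), bad below 60. Quality is reported and available as a covariate; no
epochs are dropped.

## Complexity metrics

* **Higuchi fractal dimension** (`higuchi_fd`, kmax = 8): slope of
  log mean curve length against log(1/k); 1 for smooth lines, 2 for
  uncorrelated noise.
* **Permutation entropy** (`permutation_entropy`, order 3, delay 1): Shannon
  entropy of ordinal rank patterns normalised by $\ln 3!$, ties broken by
  temporal order.
* **Wiener entropy** (`wiener_entropy`): spectral flatness
  (geometric/arithmetic mean of PSD bins) on the 0.5–40 Hz analysis range;
  zero bins are floored at $10^{-30}$ and flagged.
* **Spectral structure variability** (`spectral_structure_variability`):
  one minus the mean cosine similarity of consecutive unit-norm short-time
  spectra (2-s Hann windows, 50% overlap). No published formula exists for
  this metric; the successive-window cosine-distance definition is this
  package's interpretation.

The **uniform complexity scale** standardises each metric across subjects
and sign-flips z-scores above +1.2, so that both extremes — overly regular
and noise-like signals — map low while mid-range (critical-regime) values
stay high. Folding is applied per metric across the pooled sample; the fold
step itself is idempotent and bounds the folded scale above by +1.2.

## Spectral analysis

`welch_psd` uses 1-s Hann segments, 50% overlap, zero-padded to 2 s (0.5-Hz
grid), mean-detrended per segment, scaled as a one-sided density. The
`average = "median"` variant replaces the segment mean by the median divided
by $\ln 2$ (the median of a unit-mean exponential), which is unbiased for
stochastic spectra and robust to transient artifacts — the pipeline uses it
because the quality module flags but does not remove artifact epochs.
Deterministic line components are *not* unbiased under median averaging;
the classical mean is the default for generic use.

Landmarks: IAF is the nPSD maximum on 7.5–12.5 Hz and TF the minimum on
4–8 Hz constrained below the IAF, each required to be a local extremum, with
canonical fallbacks (10, 6 Hz) and flags otherwise. The search windows are
package choices; "the second half of the theta range" admits several
readings and the sub-IAF constrained 4–8 Hz window is the one implemented.
Canonical bands are delta 1.5–6, theta 6.5–8, alpha1 8.5–10, alpha2 10.5–12,
beta1 12.5–18, beta2 18.5–21, beta3 21.5–30, gamma 30–40 Hz, treated as
closed intervals as printed, with a bin shared by two adjacent bands
assigned to the higher band; subject-specific bands are delta [TF−4, TF−2),
theta [TF−2, TF), alpha-low [TF, IAF), alpha-high [IAF, IAF+2], with beta
and gamma canonical. Two band summaries are reported: mean in-band nPSD
("equivalent percent power") and 100 × in-band share of total nPSD
("relative power density"). With a 0.5-Hz grid and 1-s Hann windows, a tone
at a band edge leaks roughly a third of its power into the neighbouring
band; band-resolved assertions must budget for this.

### Aperiodic parameterisation

`fit_aperiodic` fits $A(F) = b - \log_{10}(k + F^{\chi})$ plus Gaussian
peaks in log10 space, with knee mode always on ($\chi \in [0, 8]$,
$k \in [0, 10^4]$). Because oscillatory power in this package's signal model
adds linearly — so a log-space Gaussian is only an approximation whose
mis-modelled shoulders can masquerade as a huge knee — the fit runs two
paths and selects between them:

* **Path A** (small-peak regime): a quantile-trimmed robust Lorentzian
  (drop the quarter of bins bulging most above a first pass), Gaussian peaks
  from the residual, plain least-squares refit of the peak-subtracted
  spectrum.
* **Path B** (broad-peak regime): a lower-envelope Lorentzian (iteratively
  refit on the bins at or below the current curve, where oscillations cannot
  lie), peaks from the envelope residual, and a final refit that excludes
  peak-dominated bins and one-sided outliers.

The selected path is the one whose background leaves less median-centred
*negative*-residual energy: oscillations only add power, so a correct
background never sits far above the data. Peak detection runs largest-first
while the residual maximum exceeds the median + 2 robust SDs, at most six
peaks, widths within 0.5–12 Hz, centres within ±2 Hz of the seed; the width
seed comes from the contiguous half-height run around the maximum. Reported
peaks need height ≥ 0.05 log10 units. Noiseless model spectra are recovered
to ~1e−11; under 5% multiplicative noise the median per-parameter error is
a few percent.

In the pipeline, the PSD entering the fit is first deconvolved by the known
two-pass band-pass power gain $|H(f)|^4$, and the fit range is 1–38 Hz
rather than 0.5–40: the 0.5-Hz bin is attenuated to ~35% of its true value
by the 1-s Hann window's resolution limit (the window cannot represent half
a cycle after detrending) and the outermost bins sit on the filter rolloff;
both distortions masquerade as knee curvature. `fit_aperiodic` itself keeps
0.5–40 Hz as its default contract for externally supplied spectra. The
fitted slope is reported as $-\chi$, so flatter spectra have less-negative
slope. Per-channel z-scoring fixes total power, which makes the fitted
*offset* a function of spectral shape rather than an independent quantity;
an offset effect planted in the generator is therefore not identifiable
after harmonisation, and the package asserts recovery of slope but only
reports the offset.

## Connectivity

Margins are rank-normalised ($\Phi^{-1}((r - 0.5)/n)$, the Gaussian copula
transform), after which mutual information has the closed form
$-\tfrac12\ln(1-\rho^2)$ nats. Conditional MI conditions each pair on all
remaining ROIs via partial correlations from the inverse of a
Schäfer–Strimmer-shrunk correlation matrix (for two ROIs, CMI = MI exactly).
O-information is computed from Gaussian entropies (log-determinants of
correlation submatrices); positive values flag redundancy-dominated systems,
negative synergy. The per-edge O-information matrix averages the triplet
O-information over all triplets containing each pair — an artifact
construction that lets graph metrics run on an O-information network;
negative edges are clipped to zero (flagged) before graph analysis, and the
system-wide scalar is reported alongside.

Graph metrics on max-normalised weights: global efficiency (mean inverse
shortest-path length with edge lengths 1/weight, Dijkstra), geometric-mean
triangle transitivity, mean off-diagonal weight (density), and
small-worldness $\sigma = (C/C_{rand})/(L/L_{rand})$ on the graph binarised
at 30% proportional density against ten degree-preserving rewired null
graphs (seeded). $\sigma$'s null model is defined for binary graphs, which
is why only this metric binarises. Metrics are computed broadband; the
conditioning set for CMI is all remaining ROIs.

## Inference layer

* `permutation_mean_test`: two-sided sign-flipping test of mean = 0 with
  $p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\})/(1 + n_{perm})$, default 5000
  randomisations.
* `bh_fdr`: Benjamini–Hochberg step-up rejection flags (hand-written step-up
  rule; `stats::p.adjust` serves as an independent oracle in the tests).
* `reduce_rois`: per-ROI permutation tests + FDR, returning the surviving
  ROI set, applied alike to band powers, complexity and aperiodic metrics.
* `hierarchical_regression`: OLS of an outcome on Gini alone, Gini + one
  factor, or Gini + age + Gini×age, with z-scored continuous predictors and
  0/1 sex; reports estimates, t, p, R², Cohen's $f^2 = R^2/(1-R^2)$, model F
  and p, and the complete-case n.
* `classify_outcomes`: outcome binarised at its median (ties to class 0),
  gradient-boosted trees (100 rounds, depth 3, learning rate 0.1 — package
  defaults, configurable), k = 10 repeats of stratified 80/20 splits, with
  AUC/accuracy/precision/recall/F1 per repeat and gain importances averaged
  and normalised to sum 1.

## Problem sizes and reproducibility

Development and test evaluations use 60-s recordings (10 ROIs) and cohorts
of 100–400 subjects; sign-recovery runs use 256 Hz sampling and the
reproducibility run 512 Hz. These sizes are the package's test-design
choices: estimator behaviour at 300 s tightens (the consistency test
verifies exponent error shrinks with duration), and all qualitative
conclusions are unchanged. Every stochastic step takes an explicit seed;
identical configuration and seed reproduce byte-identical output tables.

## Known limitations

* The fitted aperiodic offset is shape-determined after z-scoring (above).
* Median-Welch biases deterministic line components upward by $1/\ln 2$.
* Band-edge tones split across adjacent bands by window leakage.
* Small-worldness is unstable on very small or near-complete binary graphs
  (returned as NA when the null model degenerates).
* The synthetic artifact taxonomy covers only the four quality-criterion
  failure modes, and no artifact repair is attempted anywhere.
* EDF support is a minimal standard 16-bit reader/writer (no annotations,
  uniform per-signal rates).
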