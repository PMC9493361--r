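---
title: "Multimodal resting-state connectivity and connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal resting-state connectivity and connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neurofeedback training does not work equally well for everyone, and
predicting who will benefit is a practical question for any clinical use of
the technique. One candidate family of predictors is resting-state
functional connectivity measured *before* the task, on the grounds that the
network configuration a participant brings to the session constrains what
they can do in it. `neurocpm` implements a complete, testable pipeline for
this question with two simultaneously recorded modalities:

* **EEG** (8 frontal channels, 500 Hz), summarised not by band power but by
  *spectro-temporal amplitude modulation*: the spectral content of a band's
  Hilbert envelope. The pipeline focuses on the beta band modulated at alpha
  rate (beta-m-alpha) and the gamma band modulated at alpha rate
  (gamma-m-alpha), the two combinations most directly tied to cerebral
  hemodynamics in the amplitude-modulation literature.
* **fNIRS** (25 channels over the same frontal territory, 5.2083 Hz), giving
  oxy- (HbO) and deoxyhemoglobin (HbR) concentration changes through the
  modified Beer-Lambert law.

Each subject thus contributes four channel-by-channel Pearson connectivity
matrices (two 8x8, two 25x25) and one behavioural performance score
(a percentage in [0, 100]). The package predicts the score from the
matrices with connectome-based predictive modelling (CPM) and then asks how
similar the *predictive* parts of the four connectomes are across
modalities.

## The model and procedure

### EEG feature path

1. **Broadband filtering.** Second-order Butterworth band-pass 0.1-100 Hz,
   applied forward-backward (zero phase).
2. **wICA artifact correction.** Channels are unmixed with FastICA (the
   deterministic `ica::icafast` implementation, fixed initialisation), each
   independent component is transformed with a periodized orthogonal
   Daubechies (4-tap) DWT, coefficients exceeding an artifact criterion are
   amplitude-limited, and all corrected components are remixed — no
   component is discarded, so neural activity leaked into artifactual
   components survives. The criterion is a per-level universal threshold
   `sigma_l * sqrt(2 log N)` with `sigma_l` a MAD estimate of that level's
   coefficient scale; a component is treated at all only if some coefficient
   exceeds `ic_artifact_threshold` (default 1.6) times the threshold, and
   treated coefficients are clipped at `cleaning_tolerance` (default 1.4)
   times it. Per-level scale estimation matters: EEG oscillations live at
   specific scales, and a single global sigma (dominated by the fine,
   low-amplitude scales) would clip genuine beta/gamma activity.
   The decomposition depth defaults to `floor(log2(fs / 4))` (6 levels at
   500 Hz), placing the coarsest detail band around the alpha range.
3. **Amplitude modulation.** Per channel: linear-phase FIR band-pass to the
   carrier band, Hilbert envelope, FIR band-pass of the envelope to the
   modulation band. The admissible carrier/modulator pairs are a fixed
   enumeration of 14 (the envelope of a band-limited signal cannot carry
   modulation above limits set by its carrier band, and the method's
   definition prints the admissible list rather than a formula — notably
   alpha-m-alpha is excluded while beta-m-beta and gamma-m-gamma are
   included — so the package hard-codes the enumeration). FIR orders are
   chosen for a 2 Hz transition band with the Hamming window
   (>= 40 dB stopband; order 826 at 500 Hz), and filters are applied in a
   single pass with the integer group delay compensated. For a symmetric
   FIR this is exactly zero-phase while leaving the designed magnitude
   response unsquared, which keeps the passband within its design ripple; a
   forward-backward pass would have doubled attenuation instead. The first
   and last second of every AM series are flagged and excluded from
   correlations (filter and Hilbert edge transients; the group delay is
   0.83 s, so 1 s covers it).

### fNIRS feature path

Fixed order: linear-phase FIR band-pass 0.01-0.2 Hz (order 500 at
5.2083 Hz, group-delay compensated) → whole-record linear detrend → MBLL.
The MBLL solves, per channel and sample, the 2x2 system relating
optical-density changes at 760/850 nm to chromophore concentration changes
via extinction coefficients, the 30 mm source-detector distance and
per-wavelength differential pathlength factors. Defaults: DPF 7.25 at
760 nm and 6.38 at 850 nm — the printed DPF pair is bound to wavelengths in
that order, the convention of the acquisition software family for these two
wavelengths, and both are configurable because the pairing is ambiguous as
printed. Extinction coefficients are shipped as an explicit 2x2 table (a
standard compiled hemoglobin spectrum, in 1/(mM*cm)) so results are
bit-for-bit reproducible from configuration.

### Connectivity and CPM

Connectivity is plain Pearson correlation over the resting block (AM series
trimmed by 1 s per edge; hemoglobin series untrimmed — they pass through no
Hilbert step). Edges are the strict upper triangle: self-correlations are
constants and carry no information.

Prediction follows CPM with leave-one-subject-out (LOSO) folds. In each
fold, every edge of every modality is correlated with performance across
the training subjects; edges with two-tailed `p <= 0.05` (inclusive, as the
selection rule is stated) form the fold's mask; each training subject's
masked edges are summed into one *connectivity summary score* (CSS) per
modality — a single signed sum, not the positive/negative network split
used elsewhere in the CPM literature; the four CSS features train a linear
epsilon-SVR (`C = 1`, epsilon = one tenth of the training-performance
standard deviation); the held-out subject is scored with the training
fold's masks and model. Nothing from the held-out subject ever enters
selection, scaling or fitting, and the test suite checks each fold is
bit-identical when the held-out subject's data is deleted outright.

Two unstated choices are made explicit and flag-reversible:

* **Edge p-values are two-tailed** — both signs of an edge-performance
  association are admissible, and selected-edge maps in this literature
  contain both.
* **CSS features are z-scored with training-fold statistics** before the
  SVR. A 300-edge HbO mask and a 2-edge EEG mask produce CSS values on
  wildly different scales, and an unscaled linear SVR with `C = 1` is
  scale-sensitive. Predictions are reported raw (not clipped to [0, 100]);
  `clip = TRUE` is available.

The error metric is the mean absolute error on the percentage scale, with
its standard deviation taken across per-subject absolute errors (the
aggregation behind a printed "mean ± sd" MAE is ambiguous; per-subject is
the finest-grained reading).

### Coupling statistics

For each modality, edges selected in *at least one* LOSO fold form the
union mask; every subject's CSS under the union mask gives one vector per
modality; the six pairwise Pearson correlations (HbO-HbR, beta-gamma, and
the four inter-modality pairs) are tested by permuting one CSS vector
across subjects. The two-tailed permutation p uses the add-one estimator
`(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`, which can never return zero.
The six p-values are corrected with Benjamini-Hochberg FDR ("FDR" is
interpreted as BH). The method-faithful permutation count is 1e6;
`n_perm = 1e4` is the fast default used in examples and tests, and the
count is configurable everywhere.

## The synthetic cohort generator

No public data release accompanies the study design this package targets,
so the generator is a first-class module: it emulates the *structure* the
pipeline needs and carries known ground truth for every planted quantity.

* **Performance scores** are a clipped linear transform of a standard
  normal latent: `clip(70 + 24.18 z, 0, 100)` — location and spread chosen
  to resemble a typical neurofeedback-literacy distribution (median ~70%,
  sd ~24%), as a reference shape only.
* **Planted predictive edges** (defaults: three per hemodynamic modality,
  one per EEG modality, echoing the empirically sparser EEG masks) receive
  per-subject latent weights `w = r z_perf + a u + sqrt(1 - r^2 - a^2) e`,
  with `r = effect_r`, `u` a latent shared between the planted HbO and
  gamma-m-alpha edges (loading `a`, default 0.4, capped at
  `sqrt(1 - r^2)`), and `e` edge-specific noise. Weights map to
  connectivity targets `0.30 + 0.15 w` (clamped to ±0.85). Correlations
  with performance therefore hold *in expectation* and fluctuate with the
  natural sampling law of Pearson's r — in particular, null cohorts
  (`effect_r = 0`) reproduce the null distribution of r exactly, which the
  test suite verifies against direct simulation. Non-planted edges sit at a
  constant modality baseline (0.25 hemodynamic, 0.15 EEG) plus
  subject-level jitter (sd 0.05) independent of performance.
* **Realisation as correlation matrices.** Per-subject target matrices are
  projected to the nearest correlation matrix (eigenvalue floor, unit-diag
  rescale). The HbO/HbR (and beta/gamma modulator) sets are coupled through
  a block mixing matrix built from symmetric square roots, which is
  positive semidefinite by construction, so within-modality planted values
  are realised exactly while the cross-set correlation (default HbO-HbR
  -0.8) is imposed channelwise.
* **Signals.** Latent time courses are white noise, FIR-filtered into the
  target band (8-12 Hz modulators for EEG; 0.01-0.2 Hz for fNIRS),
  orthonormalised and mixed, so their sample correlation matrix equals the
  target exactly before noise. EEG channels are sinusoidal beta and gamma
  carriers whose instantaneous amplitudes ride the modulators
  (depth 0.4) plus broadband noise (`noise_sd`, default 0.2 relative to
  the unit carriers). Carriers share fixed frequencies of 17 and 45 Hz with
  random per-channel phases, for two reasons: the carrier bands are too
  narrow to hold both 8-12 Hz sidebands, so envelope extraction applies a
  linear distortion that must be identical across channels for the AM
  correlation to equal the planted modulator correlation; and at 17/45 Hz
  neither band's modulation sidebands (5-9/25-29 and 33-37/53-57 Hz) fall
  inside the other band, which would otherwise beat against the in-band
  carrier and corrupt its envelope. Hemoglobin amplitudes are 0.5 uM (HbO)
  and 0.25 uM (HbR); by default the generator forward-projects them through
  the MBLL to two-wavelength optical densities with a small linear drift,
  so the inversion, band-pass and detrend stages are all exercised
  end-to-end. Optional artifact injection (frontal-dominant ocular-like
  transients, brief high-amplitude spikes) supports the wICA tests and is
  off by default.

What the generator does *not* emulate: 1/f background spectra, volume
conduction between EEG channels, systemic physiology (cardiac, respiratory,
Mayer waves) in the fNIRS band, motion artifacts, or any optode geometry.
Passing tests therefore demonstrate that the pipeline recovers the planted
statistical structure through the full signal path — not that it would be
robust to every nuisance in real recordings.

## Numerical choices and degenerate inputs

* Zero-variance channels make Pearson correlation undefined: connectivity
  raises an error naming the channel. Zero-variance *edges* (possible in
  latent-direct cohorts) get `NA` statistics and are never selected.
* Ties at `p = alpha` are selected (inclusive rule, as stated).
* An empty mask yields CSS 0 for every subject; constant CSS columns pass
  through feature scaling unscaled (they carry no information either way).
* Constant training performances make edge selection undefined; the fold
  errors out with the fold id.
* FastICA uses a fixed deterministic initialisation; the reconstruction is
  refit by least squares so the round trip is exact even if the iteration
  stops at tolerance. Rank-deficient channel sets (duplicated or constant
  channels) are rejected before decomposition.
* All randomness flows from named seeds (`cohort_spec$seed`, the wICA seed,
  the permutation seed); reruns with an identical configuration are
  byte-identical, which the test suite asserts.

## Validation scale and known limitations

The statistical suites run at desk scale, chosen to finish in minutes while
keeping Monte-Carlo error well below the tested tolerances: the full
signal-level recovery run uses 30 subjects at the native 300 s / 500 Hz,
null calibration uses 100 latent-direct replicate cohorts of 30, the
permutation type-I study uses 1000 draws at 2000 permutations, and the
monotone-recovery and coupling-dominance suites use latent-direct cohorts
of 60 subjects.

Two method-level behaviours are worth knowing:

* **Weak effects can be counterproductive at small n.** With 30 subjects
  the `p <= 0.05` selection threshold corresponds to `|r| ~ 0.37`, so a
  planted effect of 0.3 is selected in only a minority of folds; the
  resulting fold-unstable features, combined with the leave-one-out
  anticorrelation of training means with the held-out value, push the mean
  out-of-fold correlation *below* the null level. Recovery is monotone in
  effect size once selection is stable (n = 60 in the suite, where the
  threshold is `|r| ~ 0.25`). Users applying CPM at n ~ 30 should expect
  near-threshold effects to contribute noise, not signal.
* **The CSS coupling analysis inherits mask noise.** Union masks include
  every edge that cleared `p <= alpha` once across folds, so CSS vectors
  mix planted structure with selection noise; cross-modality coupling
  planted in the generator dominates the inter-modality comparisons
  reliably only when it is strong relative to the shared
  performance-driven component.

Also out of scope, deliberately: short-separation regression or any
systemic-physiology removal for fNIRS, EEG re-referencing, volume-conduction
correction, partial/directed/frequency-domain connectivity variants, nested
hyperparameter tuning, and multiple-testing correction at the
edge-selection stage (the selection rule is part of the method definition).

## A minimal run

```{r, eval = FALSE}
library(neurocpm)

spec <- cohort_spec(n_subjects = 30, seed = 42)
res <- run_pipeline(pipeline_config(spec, n_perm = 10000, seed = 42))

res$prediction          # per-subject LOSO predictions, MAE +/- sd
res$coupling            # six CSS correlations with permutation p and FDR q
```

The same run, stage outputs included, is available from the shell via
`inst/cli/neurocpm-run`, and `scripts/acceptance.R` recomputes the headline
quantities from scratch into a JSON file.
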