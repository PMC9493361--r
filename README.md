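# neurocpm

Multimodal resting-state connectivity and connectome-based prediction of
behavioural performance, for simultaneously recorded EEG and fNIRS.

## What it is for

Whether a participant will gain control in a neurofeedback session is hard
to know in advance, and pre-task resting-state functional connectivity is a
candidate predictor. `neurocpm` implements the full analysis path for the
two-modality version of that question, for researchers working with joint
EEG-fNIRS recordings:

* **EEG amplitude-modulation connectivity.** Raw EEG is band-passed
  (0.1-100 Hz, second-order Butterworth), cleaned with wavelet-enhanced ICA
  (wICA: each independent component is wavelet-thresholded, none is
  discarded), and summarised per channel by the alpha-band (8-12 Hz)
  modulation of the beta and gamma Hilbert envelopes — the beta-*m*-alpha
  and gamma-*m*-alpha series. Only 14 carrier/modulator band combinations
  are admissible (the envelope of a band-limited signal cannot carry
  arbitrarily fast modulation); the package ships the enumeration.
* **fNIRS hemoglobin connectivity.** Two-wavelength optical densities are
  band-passed (0.01-0.2 Hz, linear-phase FIR), detrended over the whole
  record, and converted to oxy-/deoxyhemoglobin concentration changes with
  the modified Beer-Lambert law
  (ΔOD(λ) = (ε_HbO(λ) ΔHbO + ε_HbR(λ) ΔHbR) · d · DPF(λ), solved per
  sample; DPF defaults 7.25/6.38 at 760/850 nm, d = 30 mm).
* **Connectome-based predictive modelling (CPM).** Per modality, Pearson
  connectivity matrices (8×8 EEG, 25×25 fNIRS) enter a leave-one-subject-out
  loop: edges correlated with performance in the training subjects at
  p ≤ 0.05 form a mask; each subject's masked edges are summed into one
  connectivity summary score (CSS) per modality; a linear SVR (C = 1,
  ε = sd(train)/10) maps the four CSS features to performance; the held-out
  subject is predicted. The report carries per-subject absolute errors and
  the MAE ± sd.
* **Cross-modality coupling.** CSS vectors built from edges selected in at
  least one fold are compared across the six modality pairs with
  permutation tests (two-tailed, add-one estimator) and Benjamini-Hochberg
  FDR over the six comparisons.
* **A synthetic cohort generator** with planted ground truth — performance
  scores, edge-performance correlations of chosen strength, an HbO-HbR
  anticorrelation, and a shared latent coupling the HbO and gamma-m-alpha
  connectomes — renders full EEG/fNIRS signal sets so the entire pipeline
  is testable end-to-end without any data download.

## Worked example

Simulate a 30-subject cohort (5 min of rest per subject, planted
edge-performance correlation 0.8) and run the full pipeline — features,
connectivity, LOSO prediction, coupling:

```r
library(neurocpm)

spec <- cohort_spec(n_subjects = 30, seed = 42)
res <- run_pipeline(pipeline_config(spec, n_perm = 10000, seed = 42))

res$prediction
#> <prediction_report> 30 subjects, MAE 10.95 +/- 8.23 %

res$coupling
#> <coupling_report>
#>     modality_a    modality_b     r      p       q n_perm
#> 1          hbo           hbr 0.460 0.0111 0.01332  10000
#> 2 beta_m_alpha gamma_m_alpha 0.495 0.0051 0.00765  10000
#> 3          hbo  beta_m_alpha 0.694 0.0001 0.00030  10000
#> 4          hbo gamma_m_alpha 0.831 0.0001 0.00030  10000
#> 5          hbr  beta_m_alpha 0.200 0.2859 0.28587  10000
#> 6          hbr gamma_m_alpha 0.592 0.0005 0.00100  10000

head(res$prediction$predictions, 3)
#>   subject  observed predicted abs_error
#> 1     S01 100.00000  90.13288  9.867122
#> 2     S02  56.34560  65.22812  8.882518
#> 3     S03  78.78044  90.65162 11.871180
```

Reading the output: the LOSO predictions land within ~11 % of the observed
performance on average — well under the cohort's performance spread
(sd ≈ 27 %), so the planted connectivity-performance relation survives the
whole signal path (synthesis → filtering → wICA → envelopes → connectivity
→ fold-wise selection → SVR). In the coupling table, the hbo-gamma pair
carries the strongest inter-modality correlation (r = 0.83, q < 0.001):
exactly the pair the generator couples through a shared latent. Each row's
`p` comes from 10,000 permutations of one CSS vector across subjects; `q`
is the BH-adjusted value across the six comparisons.

Individual stages are exported (`bandpass_broadband()`, `wica_clean()`,
`amplitude_modulation()`, `fnirs_bandpass()`, `detrend_series()`, `mbll()`,
`pearson_connectivity()`, `loso_predict()`, `coupling_analysis()`, ...) and
documented; `inst/cli/neurocpm-run` wraps simulation and the end-to-end run
for shell use. The methods vignette
(`vignettes/multimodal-connectivity-cpm.Rmd`) describes the model,
parameter choices, and what the synthetic cohorts do and do not emulate.

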