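---
title: "Digital EEG phenotyping and tDCS response stratification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital EEG phenotyping and tDCS response stratification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpheno)
```

## Overview

`eegpheno` stratifies subjects into spectral phenotypes from eyes-closed
resting-state EEG recorded before neuromodulation, and then asks whether
membership in a phenotype predicts the behavioral benefit (or harm) of
active versus sham tDCS. The pipeline has five stages — synthetic cohort
generation, feature extraction, soft clustering, responder labeling, and
robustness validation — each exposed as plain functions and orchestrated by
`run_pipeline()`.

This vignette documents the model assumptions, the parameters that matter,
the numerical conventions, and what the synthetic benchmark does and does
not establish about real data.

## Feature extraction

A session is one 120 s, 32-channel (10-20 montage), 500 Hz recording in
microvolts. The chain is:

1. **Band-pass 2–45 Hz**, linear-phase FIR. We design an order-1000
   (1001-coefficient) Hamming-windowed filter so the group delay is exactly
   500 samples; the filter is applied once per channel by FFT convolution
   and the delay removed by an integer shift. An even-order design was
   chosen over a 1000-coefficient (odd-order) one because only the former
   has an integer delay, making single-pass zero-phase compensation exact.
2. **Demean/detrend** per channel: the least-squares line is subtracted.
3. **Frontal exclusion**: AF4, Fp2, Fp1, AF3 are removed outright; in real
   recordings these carry heavy ocular artifact, and the pipeline performs
   no ICA-style correction by design.
4. **Artifact rejection** at 100 µV, at *epoch* granularity: an epoch is
   discarded if any retained channel exceeds the threshold anywhere inside
   it. Features are epoch-based, so partial epochs would bias the spectra;
   sample-level masking is deliberately not offered. The threshold is
   applied after filtering and before re-referencing by default
   (`reject_after_reref` flips the order; the convention is exposed because
   either order is defensible).
5. **Cz re-referencing**: Cz is subtracted from every channel and then
   dropped, leaving 27 channels.
6. **Epoching**: 4 s windows, 50% overlap — a 120 s recording yields 59
   epochs (`floor((120 - 4)/2) + 1`).
7. **Relative band power** per epoch and channel: a Hann-windowed
   periodogram (a one-segment Welch estimate — the simplest estimator
   consistent with per-epoch spectra) integrated over δ (2–4), θ (4–8),
   α (8–13), β (13–30), γ (30–45 Hz). Band edges are half-open `[low, high)`
   so shared edges are never double-counted, and the denominator is the
   total over 2–45 Hz, so each channel's five fractions sum to exactly 1.
8. **Median over epochs**, elementwise, then per-channel renormalization —
   the elementwise median does not exactly preserve the sum-to-one
   constraint, and we prefer to keep the declared RBP semantics exact.

The flattened vector has a fixed order — channels in montage order minus
exclusions, bands δ→γ within channel — giving 27 × 5 = 135 features, each in
[0, 1]. Because RBP is a ratio, the vector is invariant to any positive
rescaling of the recording (as long as rescaling does not move samples
across the artifact threshold).

## Clustering and memberships

Both algorithms operate on the raw 135-dimensional fractions. No z-scoring
is applied: RBP features are already dimensionless, commensurate across
channels, and bounded; standardization would inflate low-variance gamma
features.

**Fuzzy c-means** uses the standard alternating updates with fuzzifier
m = 1.7 (soft enough to differ from k-means while keeping crisp structure
crisp), tolerance 1e-6 on the maximum center displacement, at most 300
iterations, and 5 deterministic restarts keeping the lowest final objective
— single random initializations occasionally land in poor local optima on
4-cluster data. A sample coinciding with a center takes membership 1 there
(the standard singularity rule). The objective is non-increasing across
iterations and the final memberships satisfy their fixed-point equation to
1e-6; both properties are tested.

**Spectral clustering** builds a full RBF affinity with γ = 1/135 (the
inverse feature dimension, the common library default) plus a uniform floor
of 1e-12 that guarantees a connected graph, embeds on the top k eigenvectors
of the symmetrically normalized affinity with row normalization, and runs
k-means with 10 restarts under an explicit seed. Since spectral clustering
yields no memberships of its own, prototypes are computed as cluster means
and soft memberships as normalized inverse Euclidean distance to them,
u<sub>ic</sub> = (1/d<sub>ic</sub>) / Σ<sub>c'</sub> (1/d<sub>ic'</sub>).
"A probability function of the distance" admits many forms; we chose
normalized inverse distance because it is the m→2 fuzzy-c-means membership,
has the exact-prototype limit (membership 1 at zero distance), and needs no
scale parameter. A softmax(−d²/τ) alternative is available behind
`method = "softmax"` for sensitivity analyses.

Session memberships are averaged per subject (they remain row-stochastic)
and hard assignment is arg max with ties broken toward the lower index — a
documented, deterministic convention.

`validity_scan()` tabulates Silhouette (singleton clusters contribute 0),
Davies–Bouldin, Calinski–Harabasz, inertia, and a BIC under a
spherical-Gaussian per-cluster model with shared variance and penalty
(k·d + k − 1)·log N. BIC for hard clusterings has no canonical form; this
one is intended only for relative comparison across k. The scan also emits a
kneedle-style elbow suggestion (largest distance of the inertia curve to its
end-to-end chord) but never fixes k automatically: in high-dimensional
feature spaces these indices are known to be unreliable, so the final k is a
configuration input (default 4).

## Responder labeling

The behavioral outcome is the per-subject active − sham difference per task
(Flanker, N-Back, CPT), metric (accuracy as a fraction; RT in ms) and
concurrency condition, computed only for subjects with both arms present.
Analysis proceeds per experimental condition (stimulation group ×
concurrency):

* outliers beyond mean ± 2.5 SD of the endpoint's deltas are removed in a
  single pass (no re-iteration; with zero SD everything is kept);
* the partial Spearman correlation between each cluster's averaged
  membership and the deltas is computed by rank-transforming both variables,
  residualizing on an intercept plus age (years), sex (0/1), IQ and the raw
  handedness laterality score, and correlating the residuals; the p-value is
  two-sided from a t distribution on n − 2 − 4 degrees of freedom
  (two-sided because the direction of a cluster's response is not known in
  advance);
* Benjamini–Hochberg correction is applied within the family of all
  cluster × endpoint tests of that condition (4 clusters × 6 endpoints = 24
  tests per condition here; the family composition is a configuration
  matter and the realized sizes are reported in the run log);
* every cluster × endpoint with a significant adjusted correlation is
  re-tested: the cluster members' deltas versus all other subjects', with a
  two-sided rank-sum test — exact enumeration when the combined sample is at
  most 12 and untied (where exactness matters most and costs nothing),
  normal approximation with tie correction otherwise — BH-corrected within
  the condition;
* the verdict (*positive* when accuracy correlates positively or RT
  negatively with membership; *negative* for the reverse) is kept only when
  both adjusted tests pass, otherwise the cluster is a *non-responder* for
  that endpoint.

## Robustness validation

`clustering_holdout()` refits on a random 80% (20 folds by default — the
number of repeats is a free choice), assigns held-out samples to the nearest
prototype, and reports agreement with the full-data fit after best label
matching (exhaustive over label permutations, k ≤ 8). Agreement is the
quantitative stand-in for a visual overlap check, with a configurable pass
threshold (default 0.9) for automated use.

`correlation_holdout()` redraws M subject-level subsamples (all sessions of
a subject move together — the analysis unit is the subject) at 80/60/40% of
the data, stratified by stimulation group so small groups are never emptied,
and reruns the correlation and rank-sum tests on each. It summarizes means
and SDs of the coefficients and p-values, plus the mean absolute vertical
residual of the subsample points to the full-data least-squares line of
delta versus membership ("distance to the original fit line" is not uniquely
defined; this degree-1 fit mirrors how such fits are usually drawn). At
fraction 1 the report provably collapses to the full-data run with zero
spread.

`baseline_structure_check()` runs a Kruskal–Wallis test of pre-treatment
baseline behavior across clusters per endpoint (clusters under 2 subjects
are excluded; fewer than 2 usable clusters skips the endpoint with a
message). On cohorts without a planted baseline confound the null should be
retained — phenotype structure must not be an artifact of baseline ability.

## The synthetic cohort generator

No public data exist for this design, so the generator *is* the benchmark.
Defaults mirror the emulated study: 56 subjects (ages 10–17, mean 14.09,
SD 2.1; 32:24 female:male; IQ ≥ 80; EHI in [−100, 100]), two stimulation
groups (A: lDLPFC, B: rIFG), 4 sessions each, four phenotypes in equal
proportion.

**EEG synthesis.** Each phenotype is a per-channel band-power topography
plus an alpha peak frequency, an optional beta peak, and a 1/f background
exponent. The four archetypes encode: (1) neurotypical posterior-dominant
alpha; (2) alpha→theta slowing with a low (8.5 Hz) alpha peak; (3) low
alpha with elevated beta/gamma; (4) strong alpha with a 20 Hz beta peak and
a flattened frontal–parietal alpha gradient. Signals are realized in the
frequency domain as random-phase processes: spectral amplitudes follow the
target band powers deterministically (flat within each band, with Gaussian
bumps of 0.5 Hz width at the peaks holding half the band's power), so every
realization carries the intended relative band powers exactly, which is the
only property downstream stages consume. Band noise is realized slightly
inside the band edges (delta from 2.5 Hz, gamma to 44 Hz, 0.25 Hz inset at
interior edges) so the acquisition filter's transition bands and spectral
leakage do not clip the planted powers. The 1/f background carries 5% of
channel power, channels run at 15 µV RMS (comfortably under the 100 µV
rejection threshold), and Cz is synthesized at 0.3 relative gain so that
reference subtraction perturbs the other channels' relative powers by well
under the 0.05 fidelity tolerance the generator is tested against.

**Variability.** Subject-level weight jitter (CV 10%) nests session-level
jitter (CV 5%); the 5% default was chosen so that each subject's four
sessions stay mutually closer than any foreign phenotype centroid, the
qualitative within-subject stability the pipeline presumes. A `separation`
dial scales all archetypes' contrast about their common mean; recovery
degrades monotonically as it shrinks, which is tested.

**Feature-level fast path.** `generate_cohort()` returns session feature
vectors drawn directly from the jittered topographies (plus 0.005
measurement noise), and synthesizes raw EEG lazily per session
(`cohort_recording()`): a full-size raw cohort is ~3.4 GB, so Monte-Carlo
studies use the feature path while the EEG path — validated against the
feature path by the spectral-fidelity tests — feeds the EDF/preprocessing
integration tests.

**Behavior.** Sham values come from subject baselines (logistic-bounded
Gaussian accuracy around 0.8; log-normal RT around 450 ms); active values
add effect × membership × scale (0.05 accuracy fraction, 40 ms RT per unit
effect), signed +accuracy/−RT for the planted positive phenotype (number 2
by default) and reversed for the negative one (number 3). Per-record noise
is 0.03 / 20 ms. A weak age confound (2 ms/year on the active−sham RT
difference) exercises the covariate adjustment without dominating the
planted effect. The planted effect sizes are calibrated only to make the
pipeline's power measurable at the default cohort size — the emulated study
reports no effect sizes, so no claim of matching it is made.

**What passing tests do not show.** The generator produces stationary,
Gaussian-like, artifact-free signals with phenotypes that are genuinely
separated and behavioral effects that are linear in membership. Real
resting EEG is nonstationary, artifact-laden, and its phenotype structure —
if present — is far less crisp; perfect ARI on defaults is a statement about
the pipeline's correctness, not about expected performance on clinical
recordings.

## Numerical conventions and degenerate inputs

* Membership matrices are row-stochastic to 1e-9 at every stage; FCM
  convergence tolerance is 1e-6 on center displacement.
* Zero distances (point on prototype/center) yield indicator memberships.
* Coincident prototypes raise an error rather than returning NaNs.
* A channel with zero total power makes the epoch's RBP undefined: the
  epoch is flagged and excluded; if nothing remains, extraction fails
  loudly ("all epochs rejected").
* Constant rank vectors make the partial correlation undefined (NA result,
  flagged rather than guessed).
* All randomness flows from one integer seed through a stage-tagged hash
  (`seed × stage × entity`), so any stage — or any single subject-session's
  EEG — can be regenerated in isolation; all derived seeds stay within the
  32-bit signed range.

## Problem sizes used in the automated checks

The test suite and the acceptance script run phenotype recovery on 10
cohorts of 40 subjects, responder-label recovery on 50 cohorts of 56
subjects, null-cohort false-label rates on 25 cohorts, hold-out trends at
M = 200 per fraction, and 1000-replicate type-I simulations — sizes chosen
to keep Monte-Carlo error comfortably inside the asserted margins while the
whole suite stays fast on a single CPU. Raw-EEG integration tests use small
cohorts (4–8 subjects) and shorter recordings where only plumbing, not
study conditions, is being exercised.

## Known limitations

* The validity indices are unreliable in 135 dimensions (the scan makes
  them available but the package never auto-selects k).
* No ocular/muscle artifact modeling beyond amplitude thresholding; no
  eyes-open analysis; no tDCS field modeling; no task-evoked EEG.
* The labeling stage is correlational; nothing here supports causal claims
  about stimulation response.
* Exact family composition for the multiple-testing correction is a design
  choice; with unbalanced missing data the realized family sizes differ by
  condition, so they are logged on every run.
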