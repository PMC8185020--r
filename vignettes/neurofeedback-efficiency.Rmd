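---
title: "Simulating and analysing real-time fMRI neurofeedback paradigms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing real-time fMRI neurofeedback paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnf)
library(dplyr)
```

## The problem

Real-time fMRI neurofeedback (NF) lets a participant see, with a delay of a
few seconds, a summary of the BOLD activity in a target brain region — here
the anterior midcingulate cortex (aMCC) — and try to drive it up with mental
strategies. Two block designs are in common use. In the **parallel**
paradigm, the thermometer display is shown *while* the strategy is executed:
a 50-s baseline, then six cycles of a 20-s "think" period alternating with a
30-s "count" control period, closed by a 20-s baseline. In the **serial**
paradigm, strategy execution and feedback viewing are separated into
consecutive 10-s blocks: a 40-s baseline, then eight cycles of think /
feedback-think / count / feedback-count, closed by a 10-s baseline. Both
runs last 370 s and comprise 185 volumes at TR = 2 s, so the two designs are
matched in duration and statistical power but differ in total regulation
time (6 × 20 s = 120 s parallel vs 8 × 10 s = 80 s serial) and in the
cognitive load during regulation.

`rtnf` implements the full computation chain of such an experiment —
the online feedback signal, the offline per-run training-efficiency
estimate, the selection of each subject's most efficient training run
(mETR), the group-level behavioral comparison, and a desk-scale whole-brain
map analysis with functional labeling — together with a synthetic-data
module that generates all of its inputs with known ground truth.

## The feedback signal

At every TR the online system computes, for the target ROI and for a
whole-brain "background" ROI, the percent signal change of the current
volume relative to a paradigm-specific baseline window, and displays their
difference:

$$
FS_t \;=\; 100\,\frac{\mathrm{aMCC}_t - \mathrm{aMCC}_{bas}}{\mathrm{aMCC}_{bas}}
\;-\; 100\,\frac{\mathrm{bg}_t - \mathrm{bg}_{bas}}{\mathrm{bg}_{bas}} .
$$

The background subtraction removes global, unspecific signal changes
(blood-flow or respiration effects): if both ROIs are scaled by the same
per-volume factor, $FS_t = 0$ identically — an algebraic identity the test
suite asserts exactly. The baseline window is the 5 volumes of the most
recent completed feedback-count block (serial) or the last 10 volumes of the
most recent completed count block (parallel).

Two details of the online system are under-determined and were fixed as
package design choices:

* **Which 10 of the 15 count volumes** (30 s / 2 s) form the parallel
  baseline is not specified; we use the last 10, allowing the hemodynamic
  response to settle after the think period.
* **The first cycle** has no completed reference block; we fall back to the
  tail of the initial baseline block with the same window length. Some
  reference is required for a display that starts with the first cycle, and
  the long opening baseline is the natural one.

The display quantizes FS onto a 21-level thermometer. The map is linear
from $-fs_{max}$ to $+fs_{max}$ (default 2 %) onto levels 0–20, with FS = 0
at mid-scale (level 10) and clamping beyond the range; the scale factor is
configurable because the original display mapping is not documented. The
parallel paradigm's 10-s intrinsic display lag is a presentation property,
not part of the FS computation; `run_feedback_loop()` computes FS at the
frame where the data arrive and optionally exposes a shifted
`fs_displayed` trace.

## Training efficiency and the mETR

Offline, each run's raw ROI time courses are fit with a GLM whose
regressors are condition boxcars convolved with a canonical double-gamma
HRF: a single "think" regressor for the parallel paradigm (its implicit
baseline is the count period) and "think" and "count" regressors with the
contrast think > count for the serial paradigm, which makes the two
paradigms' contrast estimates comparable. Contrast estimates are converted
to percent signal change and the training efficiency of a run is

$$
TE \;=\; PSC_{\mathrm{aMCC}} - PSC_{\mathrm{bg}} ,
$$

the offline analogue of the feedback signal. Per subject, the run with the
largest TE among the 18 training runs is the mETR (earliest run on ties —
deterministic and matching training chronology).

The PSC conversion is stated only as "converted to PSC" in the protocols
this package models, so the convention is explicit and documented here:
the contrast estimate is multiplied by the peak height of the contrasted
regressor and divided by the run mean,
$PSC = 100\,(c^\top\hat\beta)\,h / \bar y$. For multi-condition contrasts
$h = \max_j |c_j|\,h_j$ over the contrasted conditions' regressor peaks;
with this choice the single-regressor "think" model and the two-regressor
"think > count" model agree exactly whenever count carries no signal, which
is the interpretation the paradigm comparison relies on. The ROI model
includes only condition regressors and an intercept; temporal derivatives
and motion regressors belong to the whole-brain model, not to this one.

The HRF is the difference of two gamma densities with unit scale and modes
at exactly 6 s (response) and 16 s (undershoot), undershoot ratio 1/6,
truncated at 32 s and normalized to unit peak. With unit-scale gammas the
mode-6 requirement fixes shape 7 and 17; this keeps the sampled kernel's
argmax at 6 s.

## The synthetic-data generator

Every ROI or voxel time course follows

$$
y_t = B\,(1 + d_t + g_t)\Bigl(1 + \textstyle\sum_c \frac{a_c}{100}\,s_c(t)\Bigr) + e_t,
$$

with $B$ the baseline intensity (default 1000 a.u.), $s_c$ the condition-c
boxcar convolved with the HRF and rescaled to unit peak (so $a_c$ is the
peak percent signal change injected for condition $c$), $d_t$ a slow drift
(cosine of period 120 s plus a linear term, peak amplitude 0.5 % of
baseline), $g_t$ a multiplicative global fluctuation (SD 0.2 %) shared by
all ROIs and voxels of a run so that the feedback signal's background
subtraction is exactly testable, and $e_t$ AR(1) noise (coefficient 0.3)
with stationary SD 0.5 % of baseline. The source protocols do not
characterize their data's noise; these are fixture choices — the simplest
serially correlated noise model plus the slow confounds the preprocessing
operators are designed to remove — not estimates of any study's data.
Physiological waveforms (cardiac/respiratory), rigid-body head motion and
EPI artifacts are deliberately not modeled, so passing tests demonstrate
the correctness of the computation chain, not robustness to every property
of real scanner data.

A subject is 18 runs sharing all parameters except the per-run think
amplitude; the ground-truth best run is the argmax of the injected
amplitudes. A two-group study draws each subject's best-run TE from the
group's normal distribution — defaults are the study conditions, parallel
mean 1.27 (SD 0.8) and serial mean 2.3 (SD 1.0) percent — and converts TE
targets to injected amplitudes through the noise-free TE-per-unit-amplitude
calibration slope, computed once per schedule and cached (TE is linear in
the injected amplitude because OLS and the PSC conversion are linear).
Non-best runs receive amplitudes at least 1 TE-percent below the best run
(uniform over a 1-percent band below that), so the designated run is
recoverable under the default noise; the best run's position is uniform
over the 18 runs. Scan-to-scan displacement traces are smoothed noise
around 0.1 mm, optionally coupled to the think boxcar via
`motion_coupling` to emulate task-correlated movers for the exclusion rule.

## Group-level behavioral statistics

`behavior_report()` runs the four published analyses on a per-subject
behavioral table: Shapiro–Wilk normality of the pooled TE values and of the
pooled mETR positions, Welch's unequal-variance t-test on TE, and the
Mann–Whitney rank test on mETR positions (exact for small tie-free samples,
normal approximation with continuity and tie correction otherwise — the
mETR positions contain ties). These delegate to R's canonical
implementations (`shapiro.test`, `t.test`, `wilcox.test`); the tests verify
them against hand-computed and enumerated oracles. The published
per-subject table ships as a plain-text fixture
(`system.file("extdata", "behavior_table.tsv", package = "rtnf")`) and
`reproduce_published_stats()` recomputes all of its summary statistics from it:

```{r published-stats}
rep <- reproduce_published_stats()
rep$summary
rep$tests
```

Two printed values are known not to recompute from the table and are
reported as-is by the package without any attempt to match them: the Welch
degrees of freedom (16.81 from the printed one-decimal TE values vs 16.665
as published — consistent with rounding before printing) and the
Mann–Whitney statistic (61.5/38.5 depending on orientation vs 43.5 as
published, under standard rank-sum conventions).

## Desk-scale whole-brain analysis

The map module mirrors a standard volume pipeline at grid sizes where exact
oracles are affordable (6³–12³ voxels):

* **Preprocessing operators**: separable Gaussian smoothing
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$ per axis in mm, reflecting
  boundaries; the study used FWHM 8 mm) and high-pass filtering by
  discrete-cosine basis projection (cutoff 0.01 Hz), which removes the mean
  and all slower components while preserving fast ones.
* **Motion exclusion**: each subject's scan-to-scan displacement trace is
  correlated with the think-condition regressor, and subjects above the
  group fence $Q_1 + 1.5\,\mathrm{IQR}$ are excluded. That fence is the
  rule as printed; because the conventional outlier fence is
  $Q_3 + 1.5\,\mathrm{IQR}$, the choice is exposed as a flag
  (`fence = "q1"`/`"upper"`). Which task regressor the original correlation
  used is not stated; the think boxcar is assumed.
* **First level**: least-squares-all GLM — one regressor per think
  repetition (six parallel, eight serial), a combined count regressor, a
  combined feedback regressor in the serial paradigm, temporal derivatives
  of the regressors of interest (weight 0 in all contrasts), and the
  standard six or extended 24-parameter motion set. Contrasts are "think"
  (parallel) and "think", "feedback", and the overall "think + feedback"
  (serial); count always enters at weight −1 and positive weights are
  scaled to sum to 1. Count is modeled explicitly in both paradigms so
  that "count at weight −1" is well-defined; the equivalence with the
  implicit-baseline parameterization is asserted on fixtures. Voxelwise t
  statistics are Gaussianized to z by matched upper-tail quantiles
  (computed on the log scale, capped at |z| = 8.29).
* **Group level and inference**: a voxelwise one-sample OLS t-test on
  subject contrast maps, Gaussianized to z; cluster-forming threshold
  z > 3.1 with cluster-level FWE at 0.05 (conjunction: z > 2.3 at 0.01) by
  **sign-flip permutation** of subject maps under the max-cluster-size
  null, enumerating all $2^n$ sign patterns when that is cheaper than the
  requested number of draws. This replaces the original mixed-effects
  model and random-field correction deliberately: at desk scale the
  permutation null is exact, assumption-free and fully testable (the
  4-subject null is verified against exhaustive enumeration), whereas
  replicating FLAME 1 numerics is explicitly out of scope.
* **Conjunction / disjunction**: the conjunction is the voxelwise minimum
  of the two group z maps, cluster-thresholded with both groups' subjects
  flipped independently; the disjunction removes the conjunction's voxels
  from a group map (exclusive mask, applied identically in every
  permutation) and re-thresholds at z > 3.1.
* **Labeling**: functional labeling computes the Pearson correlation, over
  the intersection mask, between the *unthresholded* group z map and each
  template network map (the similarity operates on statistic maps;
  thresholded-map correlation is available as an option since the original
  configuration is not stated). Structural labeling binarizes a
  probabilistic atlas at P = 0.25 and tallies supra-threshold voxels per
  region, and `overlap_map()` produces the tri-color
  parallel-only/serial-only/both partition. The real network templates and
  anatomical atlases are user-supplied at runtime; the package ships
  synthetic stand-ins (`make_template_set()`, `make_probabilistic_atlas()`)
  — smooth, near-decorrelated Gaussian fields and Gaussian-profile
  sub-partitions — which support the oracles but carry no anatomical
  meaning, so the published real-data correlation values are out of reach
  by construction.

## Numerical choices and degenerate inputs

* All OLS fits use QR decompositions; rank deficiency is an error naming
  the collinear columns rather than a silent drop.
* mETR ties break to the earliest run; non-finite TE values are ignored,
  and an all-non-finite vector is an error.
* The thermometer quantizer uses `floor(10 fs / fs_max + 0.5)`, i.e.
  half-up rounding, making the level map monotone with exactly 21
  reachable levels.
* Constant time series are rejected where a statistic is undefined
  (Shapiro–Wilk, both-groups-constant Welch t, zero-variance maps in
  spatial correlation); constant displacement traces yield an undefined
  motion correlation and are flagged for manual review instead of being
  silently excluded or retained.
* Cluster connectivity is face (6-neighbor) adjacency; corrected p-values
  use the add-one rule for random permutations and exact proportions for
  exhaustive enumeration.
* Seeds are explicit everywhere; a fixed (seed, parameters) pair
  reproduces every output bit-identically, and child seeds are derived
  deterministically from the study seed.

## Problem sizes used in the checks

The packaged checks run the behavioral pipeline at the study's size
(10 + 10 subjects × 18 runs × 185 volumes): single studies complete in
well under a second, and the distributional check of the group comparison
uses 1,000 replicate studies. Selection-recovery and null-calibration
checks use 200 replicates. Volume analyses use 6³–11³ grids with 4–12
subjects — sizes chosen so that brute-force per-voxel OLS, exhaustive
sign-flip enumeration and voxel-wise null calibration are exact or
near-exact oracles.

## Known limitations

* The generator's noise model is stationary AR(1) plus smooth confounds;
  real fMRI noise is richer (physiological cycles, motion spikes, spatial
  autocorrelation of noise), so quantitative agreement with any real
  dataset's SNR is not claimed.
* The group map model is OLS, not mixed-effects: between-subject variance
  heterogeneity is handled by the permutation null, not modeled.
* Spatial normalization, registration, brain extraction and slice timing
  are out of scope; volume fixtures are already "registered" by
  construction.
* The published whole-brain activation maps and their template
  correlations require the study's fMRI data and the real atlases, and are
  therefore not reproduced — only the machinery that would compute them is.

## A complete worked run

```{r study}
study <- run_study(study_config(seed = 2026))
study$report$summary
head(study$behavior)
```

```{r feedback-example}
sched <- build_serial_schedule()
run <- simulate_roi_run(sched, sim_params(), seed = 11)
trace <- run_feedback_loop(run)
summary(trace$fs[trace$display])
```
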