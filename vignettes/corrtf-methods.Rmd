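---
title: "CorrTF connectivity and hierarchical staging: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CorrTF connectivity and hierarchical staging: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrtf)
```

## The model

Resting-state fMRI measures slow (0.01–0.08 Hz) BOLD fluctuations in every
brain region. If region $j$ drives region $i$ through a linear
time-invariant communication path with impulse response $h(t)$, then
$x_i(t) = (x_j * h)(t)$ and, in the frequency domain, $X_i(f) = X_j(f)\,H(f)$.
The correlation transfer function (CorrTF) estimates that path directly as
the per-bin ratio of discrete Fourier transforms,

$$\mathrm{CorrTF}(i, j)[k] \;=\; \frac{X_i[k]}{X_j[k]},$$

so a subject with $R$ ROI mean time series of length $T$ yields a complex
$R \times R \times T$ tensor (116 × 116 × 130 at the default atlas and
protocol). The per-subject feature matrix is formed by taking the ratio
*magnitude* — the gain of the path — Fisher r-to-z transforming it
($\operatorname{arctanh}$), and averaging over the $T$ frequency bins. The
off-diagonal cells, flattened in a fixed row-major order, are the
$R(R-1)$-dimensional feature vector per subject.

Downstream, edges are selected per contrast by a two-sided Welch t-test at
$p < 0.05$ and fed to linear SVMs in two arrangements: a *flat* four-class
machine (one-vs-one voting) and a *hierarchical* tree that peels off the
most separable contrasts first — AD vs the rest, then NC vs pooled MCI,
then EMCI vs LMCI — with every test subject routed to exactly one of
NC / EMCI / LMCI / AD. Performance is estimated by stratified 10-fold
cross-validation, reported both as per-fold metrics (mean ± SD of accuracy,
sensitivity, specificity, PPV, NPV) and as a pooled predicted × ground-truth
confusion matrix.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| TR | 3 | s | sampling interval of the target protocol; sets Nyquist at 0.167 Hz |
| retained volumes | 130 | — | 140 acquired minus 10 discarded for magnetization equilibrium |
| passband | 0.01–0.08 | Hz | the conventional neuronal BOLD band |
| `guard` | 1e-8 | relative | denominator bins below `guard × max` give ratio 0 (flagged) instead of dividing by numerical noise |
| `eps_clip` | 1e-6 | — | ratio magnitudes ≥ 1 are clipped to `1 − eps_clip` before `arctanh`; clip counts are recorded |
| `alpha` | 0.05 | — | raw (uncorrected) selection threshold; an FDR option exists but is off by default, matching the feature family's convention |
| SVM | linear, C = 1 | — | high-dimensional small-n regime; no silent hyperparameter search |
| folds / seed | 10 / 42 | — | stratified; fold assignment is fully determined by the seed |
| threshold | 0.1 | z units | network-analysis strength cutoff, inclusive (≥) |

## Numerical choices

**Complex-to-real reduction.** Fisher's r-to-z is defined for correlations
in $[-1, 1]$; a spectral ratio is complex and unbounded. We take the
magnitude (configurable to the real part), because gain is the quantity
interpreted as connection strength. Magnitudes above 1 are clipped to
$1 - 10^{-6}$, which preserves ordering and guarantees finite features;
$\operatorname{arctanh}(1 - 10^{-6}) \approx 7.25$ is therefore the feature
ceiling. Note a consequence: for *unrelated* unit-variance signals the
ratio magnitude exceeds 1 at about half the bins, so null features sit on a
large positive baseline rather than near 0. The t-test and SVM are
invariant to that shared offset, but the network-analysis threshold of 0.1
is far below the synthetic baseline — on synthetic cohorts essentially all
edges survive thresholding, and the network report is a format/bookkeeping
exercise rather than a sparse graph. On real data with the real-part
reduction the threshold is a meaningful pruning level.

**Order of operations.** The z transform is applied per frequency bin and
*then* averaged (transform before averaging). The alternative — average the
complex ratios, then transform — is expressible by composing the exported
primitives but is not the tested default.

**Denominator guard.** After band-passing, out-of-band DFT bins of the
denominator are numerically zero; dividing by them would manufacture huge
ratios out of rounding error. Bins below `1e-8` of the row's peak magnitude
yield ratio 0 and are flagged per (ROI, bin). A `band_limited` option
restricts averaging to in-band bins instead; the faithful default averages
all $T$ bins.

**Feature z-scoring** (the "zero mean, unit variance" step) is *not* part
of feature extraction: it is performed inside the classifier with
training-fold statistics only, so no test-set moments leak into training.
For the same reason, t-test edge selection is refit inside every training
fold; a `paper_mode` flag reproduces whole-dataset selection for
comparison and is labeled as leaking.

**Band-pass filter.** No signal-processing package is available in the
target environment, and a forward–backward IIR (Butterworth) design has a
concrete defect at this record length: on 130-sample series its edge
transients leave ~7% RMS of a 0.15 Hz tone in the output, violating the
intended stopband behavior. The implemented filter is a zero-phase
DFT-domain mask retaining bins with $|f| \in [0.01, 0.08]$ Hz. It is exactly
zero-phase (critical, since CorrTF measures inter-regional phase), exactly
idempotent, rejects DC to machine precision, passes a 0.04 Hz tone within
1% of unit gain, and attenuates a 0.15 Hz tone to below 2% RMS. No
detrending is performed before or after filtering.

**t-test variant.** Welch (unequal variances), two-sided, directed edges
tested separately. Degenerate edges (zero variance in both groups) get
$p = 1$ and a flag. No multiple-testing correction by default — a known
limitation, documented rather than silently changed.

**Tie-breaking.** Ranked edge lists break p-value ties by row-major edge
index. One-vs-one voting breaks vote ties by the accumulated decision
margin, then by stage order. Both rules are deterministic.

**Undirected reduction.** For network counting, the two directions of an
ROI pair are collapsed by the maximum, so any supra-threshold direction
keeps the edge; the threshold boundary is inclusive.

## The synthetic world

The generator emulates what the feature model assumes: stationary,
band-limited, unit-variance Gaussian ROI signals (white noise masked to the
passband and z-scored), with selected ROI pairs coupled by planted FIR
kernels — the target series is the circular convolution of its source with
the taps plus white observation noise. Circular convolution makes the
DFT-ratio relationship *exact*, giving a clean recovery oracle:
noise-free, the CorrTF magnitude at the target–source cell equals
$|\mathrm{DFT}(h)|$ at every bin. Kernel graphs must be DAGs (chains
compose; feedback is outside the single input–output model).

Two deliberate details:

* **Leakage floor.** Out-of-band bins of base signals keep a relative
  amplitude of $10^{-3}$ (power ~$10^{-6}$ of total, far below the 1%
  spectral-support bound), so every non-DC bin is observable and the ratio
  is defined at all bins.
* **DC bin.** Base signals are exactly zero-mean, so their DC bin is
  exactly zero and the DC ratio is guarded to 0. Demonstration kernels are
  therefore chosen with zero DC gain ($\sum_t h(t) = 0$ where bin-exact
  recovery at *all* bins is asserted); kernels with nonzero DC gain are
  recovered at all non-DC bins.

The four-group demonstration cohort (`demo_sim_config()`) plants three
discriminative edges aligned with the hierarchy — one separating AD from
the rest, one separating NC from the MCI stages, one separating EMCI from
LMCI — plus two edges identical across groups. Gains are 0.3/0.6/0.9 on
taps $g \cdot (0.7, 0.2, 0.1)$ and the observation noise SD is 0.5 against
unit-variance signals. Neither the group effect sizes nor the noise level
are published quantities for any real cohort: they are this package's
choices, fixed a priori at a level a practitioner would call a noisy but
detectable ROI-level effect (per-bin noise-to-signal about one third
in-band, reduced by averaging ~56 in-band bins). Defaults of 40 subjects
per group keep 10-fold stratification valid at desk scale.

What a green synthetic run does and does not establish: it verifies the
estimator algebra (bin-exact transfer recovery), the statistical
calibration of selection (type-I fraction near $\alpha$, high recall at
3-SD effects), and the correctness of the CV/metrics machinery
(conservation laws, determinism, perfect staging of separable cohorts). It
does **not** establish clinical performance: real rs-fMRI has hemodynamic
convolution, motion, physiological noise, site effects and far subtler
group differences — none of which are simulated — and the published
512-subject accuracies are properties of an access-controlled dataset, not
reproducible from synthetic data. The published confusion matrices are
bundled only as *inputs* to verify the metric arithmetic (503/512 = 98.2%
hierarchical, 489/512 = 95.5% flat; EMCI 100/102, LMCI 129/129).

## Open design points resolved here

* **Flat multiclass construction** (unstated in the source convention):
  one-vs-one voting with per-pair edge selection; each pairwise machine
  sees only its own contrast's significant edges.
* **Hierarchy origin**: fixed to the AD-first tree by default;
  `pairwise_binary_cv()` reports all pairwise binary accuracies so the
  ordering can be re-derived from data.
* **Null-edge count in the calibration check**: a full off-diagonal edge
  set has $R(R-1)$ members, so the nominal "200 edges" is realized as the
  nearest full set, $15 \times 14 = 210$; the type-I band is insensitive
  to the difference.
* **NIfTI I/O and the linear SVM** are implemented in-package (minimal
  NIfTI-1 reader/writer; dual coordinate-descent hinge-loss SVM) because
  the target environment ships no R package for either; both are tested
  against independent oracles (nibabel round-trip; the closed-form
  maximum-margin solution).
* **AAL network mapping**: the six-network assignment
  (`aal116_networks()`) is a documented reconstruction from the region
  lists commonly attributed to each network; it ships as an editable TSV
  and is not treated as ground truth.

## Known limitations

* Uncorrected mass-univariate selection inflates the selected-edge count;
  the FDR flag exists but changes the method's identity, so it is off by
  default.
* The magnitude + clip reduction saturates strong gains at
  $\operatorname{arctanh}(1 - 10^{-6})$ and imposes a positive null
  baseline (see above).
* The 0.1 network threshold is meaningful only relative to the strength
  scale of the chosen reduction.
* Preprocessing upstream of ROI extraction (slice timing, realignment,
  normalization, smoothing) is out of scope; inputs are assumed
  preprocessed.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(demo_sim_config(n_per_group = 40, seed = 1))
fs <- cohort_features(cohort)
cv <- crossvalidate(fs, scheme = "hierarchical", k = 10, seed = 42)
cv
```

Every number shown by the example and asserted in the test suite is
computed at run time by this code; the vignette states no empirical result
the tests or the acceptance script do not themselves produce.
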