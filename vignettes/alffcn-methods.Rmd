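---
title: "Mapping brain networks from across-subject ALFF covariance"
author: "alffcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain networks from across-subject ALFF covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alffcn)
```

## The three estimators

Resting-state networks are usually mapped within subject: a seed region's
BOLD time series is correlated with every voxel's series, and the
subject-level correlation maps are taken to a group random-effects test.
`alffcn` implements that estimator (the time-series intrinsic connectivity
network, TS-ICN) alongside two *across-subject covariance* estimators that
need only one number per subject and voxel:

* **ALFF-FCN** — the amplitude of low-frequency fluctuations (ALFF) is a
  per-voxel index of local resting activity. For seed region $s$ with
  subject-wise mean standardized ALFF $a_i^{(s)}$, the functional covariance
  network is the voxel-wise $t$ statistic of $\beta_1$ in
  $y_{iv} = \beta_0 + \beta_1 a_i^{(s)} + \mathbf{c}_i^\top\gamma + \varepsilon_{iv}$,
  with covariates $\mathbf{c}_i$ = mean white-matter ALFF, mean CSF ALFF,
  acquisition centre, sex and age. This is the partial-correlation $t$ of
  (voxel ALFF, seed ALFF | covariates) with $n - 2 - c$ degrees of freedom.
* **TS-ICN** — per subject, voxel and seed series are residualized against a
  nuisance set (motion if supplied, WM and CSF mean signals, optionally the
  global signal, default on), the residual Pearson correlation is Fisher
  $z$-transformed, and the group map is the intercept $t$ of
  $z_{iv} \sim 1 + \text{centre} + \text{sex} + \text{age}$ (df $= n-1-c$).
* **VBM-SCN** — the same across-subject engine applied to gray-matter volume
  maps, seeded by the region's mean GM volume, with total cranial volume,
  whole GM volume, centre, sex and age as covariates.

All three produce per-seed `stat_map`s on a shared `volume_grid`, and are
thresholded by two-sided Bonferroni control at family-wise level
$\alpha = 0.05$: $t_{\text{crit}}$ is the upper $\alpha/(2V)$ Student-$t$
quantile over the $V$ in-mask voxels. Bonferroni was chosen over
random-field theory deliberately: it is exactly testable against a quantile
oracle, assumption-free, and conservative; the cost is reduced sensitivity
on smooth maps.

## ALFF definition and conventions

Each voxel series (repetition time TR, length $N$) is transformed by FFT;
with one-sided coefficients $c_k$ the amplitude at bin $k$ is
$\mathrm{amp}_k = 2|c_k|/N$, so a sinusoid of amplitude $A$ sitting exactly
on a bin has $\mathrm{amp} = A$. ALFF is the mean of $\mathrm{amp}_k$ over
bins with $0.01 \le k/(N\cdot TR) \le 0.08$ Hz (band edges inclusive, DC and
Nyquist always excluded), i.e. the average square-root power in the
low-frequency band. Whether the underlying power spectrum is one- or
two-sided is a pure convention; ours is pinned by oracle tests (a direct
$O(N^2)$ DFT summation) and by a Parseval identity: for a mean-removed,
Nyquist-free series, $\sum_k \mathrm{amp}_k^2 = 2\,\mathrm{var}(x)$.
Standardization divides by the full-brain mean ALFF, making the in-mask
mean exactly 1 and cancelling any global scale.

Preprocessing follows the conventional order: spatial Gaussian smoothing
(FWHM 8 mm by default, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis,
converted to voxels), then linear detrending and ideal frequency-domain
band-pass filtering (out-of-band DFT bins zeroed; exactly invertible and
oracle-testable, where a Butterworth filter would impose arbitrary rolloff
choices the source conventions do not determine). Filtering to the ALFF
band leaves the in-band bins untouched, so for ALFF it is nearly a no-op —
it matters for the TS-ICN series. Smoothing uses mask-aware renormalized
convolution (dividing by the smoothed mask) so brain-edge voxels are not
diluted by out-of-mask zeros; kernels are truncated at $6\sigma$, which
preserves totals of interior-supported fields to better than $10^{-6}$.
`alff_pipeline(fast = TRUE)` exploits the fact that per-frame spatial
smoothing and the per-voxel temporal DFT commute, smoothing only the
in-band complex spectral frames; a test asserts equality with the literal
chain to $10^{-12}$.

## Seeds, conjunctions and the dichotomy

Nine 6-mm spherical seeds in three sets are shipped: DMN (PCC, DMPFC, left
AG), TPN (right DLPFC, left IPL, left FEF) and sensory (left S1, V1, A1) at
their standard MNI coordinates. A voxel joins a sphere when its centre lies
within the radius — the simplest rule consistent with a stated radius; no
partial-volume weighting.

Map-space analytics follow the conjunction logic of seed-map studies:

* **Intra-set (2-of-3)** — a voxel enters the positive (negative) mask when
  significantly positive (negative) in at least 2 of a set's 3 maps; signs
  are counted separately and never mix, which is what makes the resulting
  module maps sign-coherent.
* **Inter-set (8-of-9)** — the sensory set's maps are sign-flipped first
  (flip, then count), then the same rule with $k = 8$ over all nine maps.
  The positive mask is the high-level (DMN + TPN) system, the negative mask
  the low-level sensory system.
* **TS-ICN dichotomy** — per subject, DMN seed maps are negated and
  averaged with TPN maps; the group $t$ of the combined map, FWE-masked,
  gives the task-positive/default-mode partition.

Hierarchical clustering of the nine maps uses the pairwise spatial Pearson
correlation $r$ over the brain mask (not significance-restricted — the
choice is configurable but unrestricted masks avoid biasing distances by
thresholding), transformed to a dissimilarity $d = 1 - r$ (default; the
$\sqrt{2(1-r)}$ and $(1-r)/2$ variants are selectable since the literature
formula is not uniquely determined), and `stats::hclust` with average
linkage (single/complete selectable). The conventional cut at $d = 0.4$
corresponds to $r = 0.6$ under the default transform. Distances, linkage
and cut are configuration, never silently assumed to reproduce any
particular published dendrogram.

`dichotomy_statistics()` reports, over subjects, the Pearson correlation
between the mean standardized ALFF of the two systems (with its two-sided
$p$) and the Welch two-sample $t$ comparing their levels — the pair of
numbers that summarises "anti-correlated fluctuation amplitudes, equal mean
levels".

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` emulate the statistical structure
the estimators assume, at desk scale:

* Grid $24^3$ at 3 mm with a spherical brain mask (radius 34 mm); the nine
  seed coordinates are scaled by 0.35 so every sphere fits the field of
  view; spherical WM and CSF compartments sit away from all seeds. Because
  the geometry is scaled, the desk-scale analyses in the tests and the
  acceptance script scale the smoothing kernel with it
  ($8 \times 0.35 \approx 2.8$ mm — about one voxel); the full-size default
  of `study_config()` remains 8 mm.
* Per subject, system amplitude factors $(h, l)$ are bivariate normal with
  correlation $-0.8$ (the planted two-system anti-correlation); each
  region's BOLD amplitude is $1 + 0.18 f + \text{nuisance} + 0.05\,\epsilon$
  with $f = h$ for DMN/TPN and $f = l$ for sensory regions. Nuisance
  effects (centre 0.02, sex 0.01, age $-0.01$/decade) are deliberately
  small: they must be present (so covariate removal is testable) but must
  not bias the unadjusted dichotomy correlation beyond Monte-Carlo error,
  which is the generator's stated recovery requirement.
* Temporal structure: each region voxel's band-limited signal shares its
  system's latent time course in variance proportion $\rho_{time} = 0.5$;
  latent signals are random-phase sinusoid sums on the in-band DFT bins, so
  a noiseless region's ALFF is analytically $a\sqrt{2/K}$ ($K$ in-band
  bins). The DMN and TPN latents are mixed to correlation $-0.6$,
  driving the within-subject dichotomy. White temporal noise has SD 0.25;
  non-region brain voxels carry subject-invariant amplitude 0.8.
* GM maps load per-system structural factors (loading 0.15, voxel noise
  0.1) under a subject total-volume scale (SD 0.05); motion regressors are
  zeros (motion simulation is out of scope, as are physiological noise and
  scanner drift beyond a linear trend).

What passing tests show — and what they do not: the generator plants
exactly the covariance structure the estimators model, with Gaussian noise
and perfectly registered, artifact-free volumes. Recovery of the planted
dichotomy therefore validates the estimator chain, not robustness to
motion, registration error, physiological confounds or non-Gaussian
amplitude distributions in real cohorts.

Cohorts are reproducible from `(spec, seed)`; per-subject BOLD volumes are
regenerated on demand from stored sub-seeds, so a 300-subject cohort never
holds all series in memory.

## Numerical choices and degenerate inputs

* Voxels with zero residual variance are flagged and capped (group maps) or
  set to $z = 0$ (subject maps) — never propagated as NaN; collinear design
  columns raise errors naming the columns.
* Correlations are clipped to $|r| \le 1 - 10^{-7}$ before $\operatorname{atanh}$.
* Categorical covariates are mean-centred treatment dummies, so intercepts
  remain the covariate-adjusted mean. A consequence worth knowing: adding
  centred covariates never moves a one-sample intercept estimate, only its
  df and standard error.
* Cluster tables use 26-connectivity components, peak $|t|$ voxels
  reported in MNI mm, sorted by extent; empty masks give empty tables.
* Problem sizes used by the shipped checks: oracle comparisons at
  $n = 200$ series / $50 \times 200$ cohorts; null calibration over 200
  cohorts of $n = 30$, $V = 500$; dichotomy recovery at $n = 300$ on the
  $24^3$ grid; determinism on a 12-subject study run twice.

## Known limitations

* FWE control is Bonferroni only; no random-field or permutation option.
* No registration, slice-timing, motion correction or segmentation —
  inputs must already share a common space (grids are validated to agree
  to $10^{-4}$ mm).
* No fALFF or sub-band variants; no graph-theoretic network metrics.
* Anatomical labels for cluster-table rows are out of scope (the `label`
  column identifies components, not brain areas).
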