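---
title: "Methods: motion-aware MST connectomics on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion-aware MST connectomics on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstconnect)
```

`mstconnect` implements a resting-state fMRI analysis chain for
treatment-response studies: head-motion quantification and censoring,
nuisance regression, ALFF, minimum-spanning-tree (MST) network metrics,
and a permutation/FDR inferential layer, validated end-to-end on
synthetic cohorts with known (planted) structure. This vignette explains
the models and the choices behind them.

## The analysis model

Each subject contributes a 6-column rigid-body realignment table
(translations in mm, then rotations in radians), an ROI × time matrix,
three tissue-mean series (GM, WM, CSF), and pre/post clinical scores
(CAPS total). The pipeline proceeds:

1. discard the leading dummy volumes (default 10 of 320, leaving 310);
2. framewise displacement (FD) per volume; spike flags at FD > 0.2 mm
   (strict inequality); subjects retaining < 4 minutes of uncensored
   data are excluded;
3. linear detrending, then least-squares removal of the 36-parameter
   nuisance model plus one indicator regressor per censored volume;
4. the connectome branch band-passes residuals to 0.01–0.08 Hz,
   correlates ROIs (Pearson), extracts the maximum-weight spanning tree,
   and computes global and nodal metrics; the ALFF branch computes
   spectral amplitude on the unfiltered residuals, since ALFF defines
   its own band;
5. group inference by label permutation with Benjamini–Hochberg FDR,
   preceded by 3 × IQR outlier removal and a motion-sensitivity screen.

### Framewise displacement

FD follows Jenkinson's root-mean-square formulation. Consecutive
rigid transforms are composed into the relative motion
$M = T_t T_{t-1}^{-1} - I$ with $3\times3$ part $A$ and translation $b$,
and

$$\mathrm{FD}_t = \sqrt{\tfrac{R^2}{5}\,\mathrm{tr}(A^\top A) + b^\top b},$$

the RMS displacement of points in a head-sized ball (radius
$R = 80$ mm). The rotation order is $R_z R_y R_x$ about the coordinate
origin. Neither the rotation order nor the rotation centre is
universal across realignment tools, so both the head radius and the
centre are arguments (`head_radius`, `origin`), as is the column
dialect (`rotations_first`). One property worth stating precisely:
FD is invariant to a constant offset added to all translations only
when the inter-frame rotation change vanishes — with rotation change
$A$, the relative translation becomes $b - Ac$ under offset $c$,
because rotations act about the origin rather than the (shifted) head
centre. The test suite asserts the invariance in the two exact cases
(translation-only motion; rotation constant across volumes).

### Censoring by spike regression

Censored volumes are *retained*: each flagged volume gets an indicator
regressor, which forces its residual to exactly zero, and the full
residual series (common time axis across subjects) feeds the
correlation step. This matches a spike-regression reading of temporal
censoring, as opposed to deletion ("scrubbing"); a deletion mode
(`delete_censored = TRUE`) exists for sensitivity checks. The mean-FD
covariate is computed over all post-dummy volumes (pre-censoring) by
default, with `fd_pre_censoring = FALSE` to switch — the alternative
convention found in the literature.

### The nuisance design

The 36 base regressors are Friston's 24-parameter motion block (6
parameters, the same 6 lagged one volume, and both sets squared) plus
12 tissue regressors (GM/WM/CSF means, their first differences, and
the squares of both). Lags and differences at the first volume are set
to 0 — the common convention; any constant is absorbed by the
intercept, which is always included. Rank deficiency (e.g., duplicate
or collinear columns) is resolved by pivoted QR, and the design is
rejected as degenerate if its rank reaches the number of volumes.

### Band-pass filter

A zero-phase (forward–backward) Butterworth band-pass of order 4 per
edge, applied after odd-reflection padding of the series to suppress
edge transients (the underlying `filtfilt` does not pad). At
TR = 1.6 s the 0.01–0.08 Hz band sits comfortably below the 0.3125 Hz
Nyquist rate; the steady-state response preserves a 0.05 Hz probe to
within 0.2% and attenuates a 0.2 Hz probe to under 2% of its input
amplitude.

### ALFF

ALFF is the mean of the one-sided amplitude spectrum
($\tfrac{2}{T}\lvert\mathrm{FFT}\rvert$, i.e. the square-rooted power
spectrum up to a fixed scale) over bins with
$f_\text{low} \le f \le f_\text{high}$, DC excluded. The absolute scale
is irrelevant downstream because maps are z-scored across regions
before analysis; z-scoring uses the sample (n−1) standard deviation.
Smoothing of voxel maps is a separable Gaussian with
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, under half-sample
symmetric (reflective) boundaries — this keeps flat maps flat and
preserves the global sum exactly. The small-volume machinery packages
the five study sphere centres (5 mm radius) as the
`"paper_svc_spheres"` preset; the study's whole-brain mask is not
reconstructible and is therefore a user-supplied inclusion mask.

### MST extraction and metrics

Negative correlations are set to 0 (avoiding the interpretive problems
of negative BOLD couplings), then Kruskal's algorithm runs over the
remaining edges in descending weight order with union-find cycle
rejection. The result is the spanning tree of maximum total weight —
the "strongest connections without loops" backbone. Equal weights are
ordered by (smaller first node index, then second index), which makes
trees bit-reproducible; ties have probability zero on real-valued data
but occur in constructed tests. If the positive-weight subgraph is
disconnected the function raises an error rather than silently
including non-positive edges. Average strength reports the mean
*original* weight of the included edges.

Normalisations follow the convention that the extremal topology maps
to 1: leaf fraction divides the degree-1 node count by $N-1$ (star
$\to$ 1); diameter and average eccentricity divide edge counts by
$N-1$ (path diameter $\to$ 1); betweenness centrality divides the
interior-pair count by $\binom{N-1}{2}$ (star centre $\to$ 1, every
leaf $\to$ 0). Betweenness uses interior-node counting (endpoints are
not members of their own paths), the standard definition; on a tree the
unique-path structure lets it be computed exactly from the component
sizes left by removing each node. A cross-implementation caveat: other
network toolboxes may normalise eccentricity differently or count path
endpoints, which shifts absolute values but not group contrasts.

The 8- and 16-region occipital exclusion sets of the study design are
available as presets (`occipital8`, `occipital16`) over the synthetic
parcellation labels; with 246 regions the 8-region exclusion leaves
238 nodes and 28 203 unique edges.

### Inference

All group tests are label-permutation tests with two-sided add-one
p-values, $p = (1 + \#\{|s^*| \ge |s|\})/(B+1)$, so $p > 0$ always and
p-values are uniform on their achievable grid under the null. The
default statistic is the difference of means (difference of medians
and a pooled-variance t are available); vectorised nodal/ROI testing
shares one permutation set across outcomes to preserve their joint
dependence. Quantiles everywhere (median, IQR, the 3 × IQR outlier
fences) use linear interpolation between order statistics — the outlier
set depends on this convention, so it is fixed and tested. Outlier
removal is a single pass, applied to the motion and global metrics
before their group tests (not to the mass-univariate nodal/ALFF tests,
where a per-outcome removal would break the shared-permutation
structure).

The omnibus group × metric test is a reconstruction (the study's exact
statistic is not public): each metric is z-standardised across
subjects, the table is melted to long format, and sequential two-way F
statistics (group, metric, interaction) are referred to permutation
nulls. Group labels are permuted at the subject level for the group
and interaction effects. The metric main effect needs different
handling: its F statistic is invariant to group labels, so
label permutation cannot calibrate it; instead, Freedman–Lane
residuals of the group-only model are permuted across metrics within
each subject. Note that after per-metric standardisation the metric
main effect is structurally null — matching the behaviour this design
produces in practice (omnibus metric p-values near 1).

The motion-sensitivity suite screens for residual confounding: (1)
Kendall tau between mean FD and each edge's strength, FDR-corrected,
reported as a percentage of significant edges; (2) the distribution of
those correlations and its mean; (3) tau per global metric,
uncorrected (mirroring how such screens are usually reported; a
corrected variant is a one-line change); (4) per-node tau for degree
and betweenness, FDR-corrected. If leaf fraction correlates with FD at
the screen's alpha, the pipeline gates it out of the global group
tests — a pre-registered rule wired to the suite's output. Edges or
nodes that are constant across subjects have undefined correlations;
these are *reported* (counted, set NA), never raised as errors, since
a single degenerate edge should not abort a 28 203-edge screen. The
single-pair `kendall_tau()` uses tau-b with an exact p-value for
n ≤ 10 without ties; the vectorised edgewise screen uses the normal
approximation $z = 3\tau\sqrt{n(n-1)}/\sqrt{2(2n+5)}$, adequate for
n = 46 continuous inputs.

Voxel-map inference is a cluster-mass permutation test: covariates of
no interest are residualised out once (Freedman–Lane, reduced model),
a pooled-variance two-sample t is computed per voxel, suprathreshold
voxels (two-sided cluster-defining threshold, default p < 0.001) are
grouped under 26-connectivity into sign-consistent clusters scored by
the sum of |t|, and each observed cluster is referred to the
permutation null of the *maximum* cluster mass (FWE control). This is
a documented divergence from SnPM, whose pseudo-t variance smoothing
is not reproduced.

The minimal detectable effect solves for the smallest Cohen's d whose
two-sided two-sample t-test power reaches the target, using the
noncentral-t distribution with $df = n_1 + n_2 - 2$ and noncentrality
$d\sqrt{n_1 n_2/(n_1+n_2)}$, by bisection to $10^{-4}$. For 24 vs 22
at 80% power and $\alpha = 0.05$ the solution is d = 0.8456 (power at
d = 0.84 is 0.795, just below target — a two-decimal report of this
quantity as 0.84 is a truncation rather than a rounding).

## The synthetic cohort generator

The generator emulates the study conditions so the pipeline can be
exercised and validated at scale: two groups (defaults 24 and 22
subjects), 246 regions, 320 volumes at TR = 1.6 s, baseline CAPS
scores N(70.33, 15.3²) truncated at zero, and a planted response
effect (responder-law mean reduction 0.55 ± 0.12, non-responder
0.12 ± 0.10, so classification at the ≥ 30% reduction rule reproduces
the intended groups with realistic misclassification at the boundary).

**Motion** is an AR(1) process per rigid-body parameter
(persistence 0.95; innovation SD 0.03 mm for translations and
3 × 10⁻⁴ rad for rotations at scale 1), with persistent jumps of at
least five innovation SDs injected at spike volumes (rate 0.02/volume
by default). These magnitudes were chosen once as representative of a
compliant adult cohort (median FD ≈ 0.05–0.08 mm); the study itself
reports no between-group motion effect size, so the default 1.5× scale
ratio between groups (responders lower, matching the reported
direction) is illustrative, not calibrated.

**Connectivity structure** comes from a latent-signal construction: a
unit-variance signal at a root region propagates along a planted
spanning tree, each child being $a \cdot \text{parent} +
\sqrt{1-a^2}\cdot\text{fresh}$ with attenuation
$a$ (`edge_signal_strength`), plus white observation noise of SD
$\sigma$. Two regions at tree distance $d$ then have population
correlation $a^d/(1+\sigma^2)$ — strictly decreasing in $d$ — so the
planted tree is the *unique* maximum-weight spanning tree of the
population correlation matrix. This is the reason the construction was
preferred over drawing from a covariance with specified tree support:
recovery has an unambiguous ground truth. The closed form also gives
the generator's target correlation for planted edges,
`planted_adjacent_correlation()`. Defaults $a = 0.6$, $\sigma = 0.5$
produce adjacent-pair correlations around 0.5 and a realistic spread
of weaker long-range correlations.

`planted_hub_trees()` constructs paired trees that differ only in the
centrality of designated hub nodes (leaves in one tree, chained star
centres in the other), planting a nodal-betweenness group difference
with no difference elsewhere — the ground truth for the
parameter-recovery suites.

Per-subject streams derive deterministically from the master seed via
an integer hash, so identical specifications give byte-identical
cohorts without cross-subject correlation. Rotations are simulated in
radians (the FD convention), and CAPS scores are truncated at zero
(the instrument's floor).

**What the generator does not emulate:** spatial structure within
regions (no voxel geometry in the ROI pathway), physiological noise
(cardiac/respiratory), motion-induced signal artifacts coupled to the
motion trace (motion and BOLD series are generated independently, so
the sensitivity suite's null behaviour is by construction — planted
confounds must be injected explicitly), scanner drift beyond a linear
trend, and the real atlas's anatomy (labels are synthetic; the
occipital presets mark the tail of the label list). Passing tests
therefore demonstrate algorithmic correctness and statistical
calibration, not robustness to every artifact of real data.

## Numerical choices and degenerate inputs

- Zero-variance ROIs abort correlation with the offending label named;
  constant metric columns abort the omnibus with the column named.
- A motion scale of 0 is allowed (an exactly still head, FD ≡ 0);
  negative scales are rejected.
- If censoring saturates the nuisance design (as many spike columns as
  volumes), the subject is marked unanalysable instead of erroring;
  the retention rule excludes such subjects anyway.
- An all-censoring configuration (threshold 0) runs to completion and
  reports zero analyzable subjects.
- Permutation ties at the observed statistic are counted as
  exceedances with a small relative tolerance — without it,
  floating-point accumulation differences between the observed and
  permuted computation paths produce spuriously small p-values on
  near-constant outcomes.
- MST ties break deterministically by node index; adding a constant to
  all weights or applying any strictly increasing transform leaves the
  tree unchanged (rank dependence, tested).

## Problem sizes used in validation

The validation suites run at sizes chosen to exercise the mathematics
decisively: oracle equivalence uses exhaustive enumeration (all 1 296
spanning trees of 6-node graphs; all labelled trees to n = 6 plus
random trees at n = 7, 8 for betweenness); calibration suites use
500 null datasets for the two-group test and 200 for the cluster-FWE
test at 199 permutations each; planted-hub recovery uses 50 replicate
cohorts of 46 subjects over 60-region, 200-volume networks (the
planted-tree recovery property is topological and does not depend on
parcellation size); and the end-to-end demo runs the full study
geometry (46 subjects, 246 regions, 320 volumes) twice to verify
bit-reproducibility.

## Known limitations

- The omnibus statistic and the SnPM variance smoothing are documented
  reconstructions; absolute p-values need not match the original
  software even on identical data.
- Eccentricity/betweenness normalisation conventions differ across
  network toolboxes (see above); comparisons across software should use
  contrasts, not absolute values.
- The edgewise Kendall screen's normal-approximation p-values assume
  no ties; with heavily discretised edge weights the tau-b correction
  in `kendall_tau()` should be preferred per edge.
- The voxel pathway is deliberately minimal (arrays in, cluster table
  out); no image registration, resampling, or NIfTI orientation
  handling is provided.
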