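---
title: "Jackknife reliability and post-hoc power for fMRI group maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jackknife reliability and post-hoc power for fMRI group maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jackmap)
```

## The problem

A second-level (random-effects) fMRI analysis fits, at every voxel, a GLM
across subjects' first-level contrast estimates and thresholds the
resulting t-map. The map answers "is this voxel significant in *this*
group of n subjects?" — it says nothing about whether the activation would
survive a slightly different or slightly smaller group, which is exactly
the question that matters when groups are small (patients, children) or
possibly inhomogeneous. jackmap addresses this with an iterative jackknife
("third-level") analysis: remove every subject, then every combination of
2, 3, ... subjects; re-fit and re-threshold each reduced design with
identical settings; and summarize how the significant set moves.

## The model and the resampling scheme

**Second level.** At each mask voxel, ordinary least squares of the subject
values on an intercept plus mean-centered nuisance covariates;
t = c'b / sqrt(s2 c'(X'X)^-1 c) with df = m − rank(X), where m is the
number of retained subjects. The default contrast tests the intercept
(group mean > 0): one-sided activation inference, the convention for
directional contrasts; a two-sided flag exists. Covariates are re-centered
*within each subset*, so every reduced design is a self-contained
second-level analysis rather than a projection of the full one.

**Jackknife.** Removing r of n subjects admits C(n, r) unique reduced
designs — 39 leave-one-out designs at n = 39, but already ~5.8e5 at r = 4.
The number of designs actually fitted per step is capped (default 100);
below the cap all combinations are enumerated in lexicographic order,
above it the cap is filled by drawing ranks uniformly without replacement
and unranking them through the combinatorial number system, so the design
space is sampled uniformly without ever being materialized. Sampling
without replacement is the right scheme here: a bootstrap's
with-replacement draws would duplicate subjects inside one design.

**Overlap summaries.** Each reduced thresholded map is compared to the
original by the Dice similarity index, DSI = 2|A∩B|/(|A|+|B|) on the
binary significant sets; an empty reduced map scores 0 by convention. All
maps of a step are combined into a group percent overlap map (gPOM): the
per-voxel percentage of reduced designs in which the voxel is significant
(rounded half-up to integers; exact counts are kept alongside). Voxels are
classified *very reliable* (significant in 100% of the designs computed —
an exact-count test, so 99.5% never rounds up into it), *reliable*
(50–99%), or *unreliable* (below 50%). The 50% boundary is counted as
reliable by default (`boundary_reliable = FALSE` gives the strict-majority
reading). With a capped sample, "100%" means all designs actually
computed — a sampling-based statement, not an exhaustive one.

**Post-hoc power.** Sweeping the group size m from n−1 down to a floor
(default 12, the classical minimum for random-effects groups) and building
a per-size gPOM turns the loss of detection power into a measurement: a
voxel is *safely detected* at m when its detection fraction reaches
`safe_threshold` (default 100%, 80% offered as the common power-analysis
convention) at m *and at every evaluated size above m*. This monotone
closure is our rule — sampled detection can dip non-monotonically, and the
closure makes the minimum well-defined. min_n is the smallest such m;
voxels only the full design detects get min_n = n; voxels not significant
in the full map get none (computing power only for significant voxels
avoids the power-approach paradox). Clusters of the full-map significant
set (26-connectivity by default; 6 and 18 available) inherit min_n from
their member voxels — by default the minimum over members, i.e. the size at
which the cluster first contains a safely detected voxel; `rule = "peak"`
and `rule = "all"` are the obvious alternatives, since any-voxel vs
peak-voxel vs whole-cluster semantics is a genuinely open choice. Ranking
clusters by min_n ranks them by observable effect size, a more comparable
quantity than peak t, whose meaning shifts with the degrees of freedom.

## Multiple-comparison control

Four voxelwise rules: uncorrected (p ≤ α), Bonferroni FWE (p ≤ α/V over
the V mask voxels), Benjamini–Hochberg FDR (step-up over mask voxels), and
a sign-flip max-t permutation FWE (B seeded sign-flip refits; a voxel is
significant when its t reaches the (1−α) quantile of the permutation
maxima). Bonferroni is deliberately chosen over random-field-theory FWE:
RFT requires smoothness estimation that is out of scope here, Bonferroni is
a valid (conservative) FWE control, and the permutation option is the less
conservative alternative — voxel counts will therefore differ from an SPM
analysis of the same data. Significance is closed (p ≤ α) throughout.
Voxels with zero residual variance are flagged and given p = 1 rather than
an infinite t; "zero" is judged relative to the data's energy
(RSS ≤ 1e-24 × ΣY²), since an exact fit leaves RSS at rounding level
(~1e-31), not exactly 0, while even a variance ratio of 1e-13 (noise sd
1e-6 on unit signals) stays far above the cut.

## The synthetic-data generator

`simulate_cohort()` produces the inputs every test runs on: each subject's
volume is a shared template of isotropic Gaussian blobs (truncated at 4
s.d.) plus i.i.d. Gaussian noise; optional deviant subjects have their
finished maps sign-inverted (inversion acts on template + noise, so the
deviant is the exact negation of the map the same seed would otherwise
have produced — the natural reading of inverting a finished parameter
map). Deviants sit last in subject order and are flagged in the manifest
so tests can locate them. Covariates default to independent standard
normals (they are nuisance-only). Identical specs regenerate bit-identical
cohorts.

Defaults — the conditions all seeded scenario tests run under — are a
20×24×20 grid, noise sd 1, and three blobs of sd 1.5 with peak amplitudes
2.4, 1.7 and 1.2 noise units. Peak effect sizes well above 1 look large by
behavioural standards but are ordinary for smoothed fMRI contrast images
at strong foci; they were fixed so that *all three* foci are reliably
significant in full-group Bonferroni-corrected maps at n ≈ 19–39 — a
power ranking is only defined for foci present in the full map — and so
the hierarchy spans the scanned size range. Noise is spatially white by
default so closed-form t expectations hold exactly per voxel; an optional
Gaussian smoothing of the noise field adds spatial autocorrelation for
realism but is off by default. What the generator does *not* emulate:
BOLD time-series structure, first-level fitting, motion or distortion
artifacts, non-stationary smoothness, and realistic anatomy. Passing
scenario tests therefore demonstrate the machinery's behaviour under a
known ground truth, not performance on real pediatric data.

## Numerical and design choices

* Exhaustive plans are lexicographic, so results are platform-independent;
  sampled plans are reproducible functions of (n, r, cap, seed).
* Binomial coefficients use the multiplicative form, exact in doubles up
  to 2^53 — far beyond any feasible group size.
* Each removal depth (and each size in the power scan) is planned
  independently from a seed derived from the master seed; no nesting
  across depths.
* The Mann–Whitney comparison of DSI distributions (e.g. 100- vs
  1000-design runs) uses mid-ranks for ties, exact enumeration of the U
  null when choose(n1+n2, n1) ≤ 2e5, and the tie-corrected,
  continuity-corrected normal approximation otherwise; p-values are
  Bonferroni-multiplied by the number of scenario comparisons.
* gPOMs, class maps and min-n maps are written as int32 NIfTI-1 volumes,
  t-maps as float64; the input affine is carried into every output; voxel
  reports give 0-based indices plus world mm through the affine.
* The min-n sentinel on disk is 0 ("not significant in the full design");
  in memory it is NA.
* Default mask when none is supplied: voxels finite for all subjects with
  non-zero between-subject variance — an invented stand-in for SPM's
  implicit analysis mask, which is analysis-dependent.

## Problem sizes used by the test suite

The scenario suite simulates cohorts of n = 19, 29, 39 (and 30 for the
power ranking) on the default grid, 20 seeds per scenario, cap 100,
removal depths 1–3 (1, 5, 9 for the threshold-stringency contrast), power
scans from n−1 down to 12. These sizes mirror the group sizes the method
is aimed at while keeping a full run of the suite to minutes on one CPU.

## Known limitations

* Reliability statements are relative to the capped design sample; with
  100 designs the gPOM resolution is 1%.
* No cluster-extent or cluster-level inference: non-stationary smoothness
  makes that a research problem of its own, deliberately out of scope.
* OLS only at the second level — no variance-component or robust
  mixed-effects modeling.
* No between-session reproducibility, ICC, coefficient of variation or
  conjunction machinery; the Dice/gPOM summaries are deliberately simple.
* The power scan reports the sizes that *were* sufficient in this cohort;
  it does not predict the size a future study needs.
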