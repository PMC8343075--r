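---
title: "Along-tract classification of diffusion profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract classification of diffusion profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mild cognitive impairment (MCI) precedes Alzheimer's disease, but only a
minority of MCI patients convert. Along-tract analysis of diffusion MRI
("tractometry") quantifies a diffusion property — fractional anisotropy
(FA), mean/radial/axial diffusivity (MD/RD/AxD) — at 100 equidistant nodes
along each of 20 major white-matter tracts, giving a 100-dimensional
profile per subject, tract and property. `tractclass` implements a
complete, testable pipeline that asks, for each tract and property
separately: *do the along-tract diffusion values discriminate MCI
converters (C) from non-converters (NC), and if so, at which nodes?*

The pipeline has five stages:

1. **Profiling** (optional, when starting from streamlines): clean a fiber
   bundle by outlier rules and summarize it into a 100-node profile.
2. **Classification**: per (tract, property), a leave-one-out
   cross-validated RBF-SVM with nested recursive feature elimination.
3. **Screening**: keep classifiers beating an exact-binomial chance
   threshold on accuracy *and* an AUC floor; confirm survivors by a
   label-permutation test that re-runs the whole pipeline.
4. **Regions**: intersect stably selected nodes with FDR-significant
   node-wise group differences, grouped into consecutive-node regions.
5. **Final classifier**: the same LOOCV procedure restricted to the
   region features pooled across tracts and properties.

## Profile quantification

A streamline bundle is a set of 3-D polylines with one scalar per point.
Each fiber is resampled to `n_nodes` points equally spaced in arc length
(point coordinates interpolated linearly along the polyline, scalar values
by a cubic spline over arc length). Fibers are orientation-aligned by
flipping any fiber whose endpoints better match the first fiber reversed.
The *core trajectory* is the pointwise mean of the resampled fibers, with
a pointwise 3×3 positional covariance.

Cleaning applies two rules per pass, for at most 5 passes or until nothing
is removed:

* **length rule** — drop fibers whose arc length exceeds the bundle mean
  by more than 4 SD;
* **deviation rule** — drop fibers whose *core-deviation score* (the mean
  over nodes of the Mahalanobis distance of the fiber's node point under
  the node's positional covariance) exceeds the score mean by more than
  5 SD.

Both thresholds use the same `mean + k·SD` form. For the deviation rule an
absolute cutoff on the score population ("score > 5·SD of scores") was
rejected during design: the Mahalanobis score of a perfectly regular
Gaussian bundle has mean ≈ 1.6 (a chi-type statistic in 3 coordinates), so
an absolute multiple-of-SD cutoff without centering removes ~1% of healthy
fibers per bundle, violating the requirement that a homogeneous bundle is
left intact. Node covariances are inverted with a Moore–Penrose
pseudo-inverse, so degenerate spreads (identical fibers) give distance 0
rather than an error.

The profile value at a node is the Gaussian-weighted mean of the fibers'
interpolated values, `w = exp(-d²/2)` of the Mahalanobis distance `d` to
the core, normalized per node. Normalization makes each node a convex
combination of fiber values; an unnormalized weighted sum would scale with
fiber count and was rejected.

## The classification engine

For one (tract, property) the data are an `N × 100` matrix `X` with labels
`y ∈ {C, NC}`. For each left-out subject `i`:

1. **Normalization** — per-node mean and sample SD (n−1 denominator) are
   estimated on the `N−1` training rows only and applied to both
   partitions. The held-out row never touches any training statistic.
2. **RFE with correlation-bias reduction (CBR)** — one feature is
   eliminated per iteration until 10 remain. At each iteration an RBF-SVM
   (`K(u,v) = exp(-γ‖u−v‖²)`, `C = 1`,
   `γ = 1/(p · pooled feature variance)` with `p` the current feature
   count) is fitted and each feature is scored by the decrease of the dual
   objective when its kernel contribution is removed with the dual
   coefficients α held fixed:

   `ΔJ(i) = ½ αᵀHα − ½ αᵀH⁽⁻ⁱ⁾α`,

   where `H` is the label-weighted kernel matrix and `H⁽⁻ⁱ⁾` the same
   matrix recomputed without feature `i`. Because the kernel is a product
   over per-feature factors, `H⁽⁻ⁱ⁾` is obtained from `H` by one
   elementwise update, which is what makes exhaustive per-feature scoring
   affordable inside the nested loop.

   *CBR*: smooth profiles make neighboring nodes nearly collinear, and
   plain RFE underestimates every member of a correlated group (removing
   one changes the kernel little when its twins remain). Features are
   therefore grouped greedily, in ascending node order, into cliques whose
   members all satisfy `|r| ≥ 0.9` pairwise on the training data; the
   group is scored by removing *all* members at once and the group score
   is assigned to each member. Connected-component grouping was rejected:
   with smoothly correlated profiles it chains all 100 nodes into a single
   group and the ranking degenerates. The lowest-scored feature is
   eliminated; ties keep the lower node index, so reruns are
   deterministic.
3. **Prediction** — an RBF-SVM trained on the 10 surviving nodes
   classifies the held-out subject; its decision score is recorded
   (positive = C).

Pooled over folds, accuracy is `(TP + TN)/N` with C as the positive class,
and AUC is the rank-based area computed from the pooled decision scores
(ties count ½). Pooled-score AUC is deliberately distinct from accuracy:
a classifier can beat the accuracy threshold while ranking converters
poorly, and the screen requires both.

The quadratic-programming core is a compact SMO solver (maximal-violating-
pair working-set selection, convergence tolerance `1e-3`, the same
stopping rule as standard SVM libraries) operating on precomputed kernel
matrices so that the ~8,000 refits of a single LOOCV run stay fast. The
test suite verifies it against an established SVM implementation: decision
values agree to ~1e-4 and fold-level predictions are identical.

### Hyperparameters

No inner tuning loop is used: with 87 subjects a nested tuning loop would
change the published procedure and burn data. `C = 1` and the
pooled-variance γ rule (which reduces to `1/p` on normalized features) are
fixed defaults; both are exposed as arguments.

## Chance threshold, screen, permutation test

Under a Binomial(n, ½) model of a random classifier, the chance threshold
is the smallest two-decimal accuracy `t` with `P(X/n > t) ≤ α`; for
`n = 87, α = 0.05` this is 0.59. The screen keeps classifiers with
accuracy strictly above the threshold *and* AUC strictly above 0.6.

The permutation test re-runs the *entire* pipeline — normalization, RFE,
SVM — on cohorts whose labels are shuffled preserving the 34/53 class
counts, yielding a null accuracy distribution. Two p-values are reported:
the one-sample t-test of the observed accuracy against the null draws
(reported for comparability, but anti-conservative — it treats the null
draws as the sample) and the empirical permutation p
`(1 + #{null ≥ observed})/(n_perm + 1)`, which is the preferred summary.

**Known limitation.** The Binomial(n, ½) chance model ignores the 34/53
class imbalance: a majority-class guesser already achieves 0.609, and the
LOOCV SVM inherits part of that bias, so null accuracies center above ½
(the empirical permutation test is unaffected — it compares like with
like). This mismatch is documented rather than "fixed", because the
threshold's definition is part of the procedure being implemented. Users
screening their own data should lean on the permutation p-value and the
AUC condition, which are calibrated under imbalance.

## Regions and the final classifier

Because RFE runs inside every fold, each node has a selection frequency
across the N folds. Nodes selected in ≥ 50% of folds (threshold
configurable; no published cutoff exists, so the majority rule was chosen
and is echoed in every report) become candidates. Candidate nodes are
tested for group differences with pooled-variance two-sample t-tests
(df = N−2) and Benjamini–Hochberg FDR control at q = 0.05 across the
tested nodes; testing only the candidates (rather than all 100 nodes) is
the default because the candidate set is the hypothesis the selection
stage produced — a switch tests all nodes instead. Candidate ∩ significant
nodes, grouped into maximal consecutive runs, are the reported *regions*.

The final classifier concatenates the region features across tracts and
properties and re-runs the identical LOOCV procedure with RFE to
`min(10, n_features)`. The union of per-fold selections is reported (a
per-fold selection of 10 can union to more than 10 across folds).

**Known limitation.** Reported regions are systematically *narrower* than
the underlying effects: RFE retains exactly 10 nodes per fold, so the
candidate set for one (tract, property) can never exceed roughly 10 nodes
regardless of how many nodes the true effect spans, and when one tract
carries several affected intervals the budget splits between them. On the
synthetic benchmark the left-ILF implant spans 21 nodes across two
intervals, and the pipeline recovers about half of them; region size
should be read as "where the signal is concentrated", not as the effect's
extent. Region-restricted analyses of this kind characteristically report
far narrower regions than the group differences they sit in, for exactly
this reason.

## The synthetic-cohort generator

The generator is the ground truth against which every stage is validated.
Defaults mirror the target study design: 34 C / 53 NC subjects, 20 tracts,
4 properties, 100 nodes. Baselines are typical white-matter values — FA
0.45 (SD 0.06); MD 0.80, RD 0.60 (SD 0.06); AxD 1.20 (SD 0.08), the
diffusivities in 10⁻³ mm²/s — only the relative structure matters
downstream. Node noise is a stationary Gaussian process with
squared-exponential correlation `exp(-(i-j)²/(2ℓ²))` and `ℓ = 10` nodes by
default, chosen so that profiles are smooth at the scale of the reported
~10-node regions; real profile covariance is not published, so this is a
modeling choice, not a fit. Group effects are additive mean shifts of the
C group by `d × baseline SD` over a node interval (positive `d` raises C
values, matching elevated diffusivity in converters).

The reference benchmark (`benchmark_config()`) implants `d = 1.5` effects
in a spatial pattern characteristic of converters: right cingulum
hippocampus MD at nodes 90–100, right IFOF AxD at nodes 37–45, left ILF
AxD at nodes 1–10 and 80–90.

What the generator does *not* emulate: multi-site/scanner batch effects,
heavy-tailed or heteroscedastic node noise, inter-tract correlation,
missing data, and any coupling between demographics and profiles. Passing
the synthetic benchmarks therefore demonstrates that the *procedure* is
implemented correctly and is calibrated under its own assumptions — not
that real-cohort effect sizes or accuracies are attainable.

## Numerical choices and test-suite problem sizes

* SMO tolerance `1e-3`, iteration cap `1e5` pair updates; solver is
  deterministic, so identical inputs give identical models.
* RFE ties broken toward the lower node index; the correlation matrix
  used for CBR grouping is computed once per fold (the training set is
  fixed within a fold).
* Zero-variance features abort normalization with the feature named;
  degenerate bundles (all fibers removed) abort cleaning.
* Simulation scales in the test suite are chosen to exercise each claim
  at the smallest informative size: null calibration of the LOOCV runs at
  the full 87-subject design (20 replicates); permutation-p uniformity
  runs on 26-subject, 20-node cohorts with 99 permutations (30
  replicates), since accuracy at small n is coarsely discrete and the
  full-size check would need thousands of complete LOOCV pipelines;
  region recovery runs the full 87-subject benchmark for 25 replicates.
* The empirical permutation p with `≥` ties is conservative on coarse
  accuracy grids; the uniformity check therefore uses a cohort size at
  which the grid is fine enough for the discreteness not to dominate.

## Interfaces

Profiles interchange as a long CSV (`subject_id, group, tract_id,
property, node, value`); subjects with incomplete grids are dropped with a
warning, mirroring the exclusion of subjects whose image processing
failed. Bundles interchange as JSON lines (one fiber per line). Run
parameters round-trip through YAML (`run_config()`), and every written
report embeds the configuration and package version. The exported
functions are the command surface; `run_full_pipeline()` executes the
whole procedure and `write_report()` materializes the tables.
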