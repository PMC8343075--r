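# tractclass

Along-tract classification of diffusion MRI tract profiles for predicting
conversion from mild cognitive impairment (MCI) to Alzheimer's disease.

## What it does, and for whom

Tractometry summarizes a diffusion property — fractional anisotropy (FA),
mean/radial/axial diffusivity (MD/RD/AxD) — at 100 equidistant nodes along
each of 20 major white-matter tracts, one 100-vector per subject, tract
and property. `tractclass` is for researchers who have such profiles (or
raw streamline bundles) for two groups — MCI patients who later converted
(C) and who did not (NC) — and want a statistically disciplined answer to:
*which tracts, properties and specific node regions predict conversion?*

The pipeline, exercised end-to-end on synthetic ground-truth cohorts:

1. **Profiling** (optional): clean a streamline bundle (length > mean + 4 SD
   and core-deviation > mean + 5 SD outlier rules, iterated) and quantify a
   100-node profile as a distance-weighted mean across fibers.
2. **Classification**: per (tract, property), leave-one-out
   cross-validation of an RBF-kernel SVM. Inside every fold: per-node
   z-normalization fitted on the N−1 training subjects; recursive feature
   elimination with correlation-bias reduction (SVM-RFE-CBR) down to the 10
   most discriminative nodes, ranked by the dual-objective drop
   ΔJ(i) = ½αᵀHα − ½αᵀH⁽⁻ⁱ⁾α with correlated node groups (|r| ≥ 0.9)
   scored jointly; then an SVM on the selected nodes classifies the
   held-out subject. The held-out subject never touches any training
   statistic.
3. **Screening**: accuracy must exceed the exact Binomial(n, ½) chance
   threshold (0.59 for n = 87 at α = 0.05) *and* pooled-score ROC AUC must
   exceed 0.6; survivors are confirmed by a label-permutation test that
   re-runs the entire pipeline per shuffle.
4. **Regions**: nodes selected in ≥ 50% of folds, intersected with
   FDR-corrected (Benjamini–Hochberg, q = 0.05) pooled-variance t-tests,
   grouped into consecutive runs.
5. **Final classifier**: the identical LOOCV procedure restricted to the
   region features pooled across tracts/properties.

A synthetic-cohort generator (Gaussian-process node noise, configurable
localized group effects in standardized units d) provides the ground truth
that the test suite uses to validate calibration and signal recovery.

## Worked example

Simulate the benchmark cohort (34 C / 53 NC; d = 1.5 effects at right
cingulum-hippocampus MD nodes 90–100, right IFOF AxD 37–45, left ILF AxD
1–10 and 80–90), classify one tract, and locate its predictive region:

```r
library(tractclass)

cohort <- generate_cohort(benchmark_config(d = 1.5, seed = 11))
res <- loocv_classify(cohort, "right_cingulum_hippocampus", "MD")
res
#> <tract_clf_result> right_cingulum_hippocampus / MD: n = 87, accuracy = 0.977, AUC = 0.999

chance_threshold(87, 0.05)    # accuracy a random classifier beats with p <= 0.05
#> [1] 0.59

cand  <- select_candidate_nodes(selection_histogram(res), 0.5)
tests <- node_group_tests(cohort, "right_cingulum_hippocampus", "MD", cand)
define_regions(cand, tests)
#> # A tibble: 1 × 6
#>   tract_id                   property region_id start   end nodes
#>   <chr>                      <chr>        <int> <int> <int> <list>
#> 1 right_cingulum_hippocampus MD               1    90    96 <int [7]>
```

Accuracy 0.977 beats the 0.59 chance threshold and the AUC clears the 0.6
floor, so the pair is predictive; the selected-and-significant nodes 90–96
recover the implanted terminal region (nodes 90–100). On label-independent
cohorts the same procedure yields accuracies near chance and empty or
spurious-but-rare regions; the test suite quantifies both directions.

## Repository layout

```
R/                  pipeline modules (simulation, profiling, classification,
                    evaluation, regions, cohort statistics, IO, driver)
src/                compiled SMO solver + incremental-kernel RFE engine
tests/testthat/     unit, property and end-to-end acceptance tests
scripts/acceptance.R  headline-quantity reproduction script
vignettes/          methods vignette
```
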