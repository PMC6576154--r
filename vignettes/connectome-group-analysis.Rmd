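---
title: "Graph-theoretic group comparison of functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic group comparison of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

connectograph compares resting-state functional brain networks between
subject groups (for example euthymic bipolar patients, recurrent-depression
patients, and healthy controls). The pipeline has five stages:

1. **Quality control and preprocessing.** Subjects whose six-parameter
   rigid-body motion trace exceeds 2 mm of translation or 2 degrees of
   rotation on any axis at any volume are excluded. The first 10 volumes of
   each series are discarded for T1 equilibration, each regional time
   course is linearly detrended, and a 0.01–0.08 Hz band-pass isolates the
   low-frequency fluctuations that carry resting-state signal.
2. **Network construction.** Pearson correlations between all pairs of the
   90 cerebral parcels of the standard anatomical labelling atlas give a
   90 × 90 weighted undirected matrix per subject; negative weights are set
   to zero; the matrix is binarized at every sparsity level from 0.10 to
   0.50 in steps of 0.01 (41 levels), where sparsity *S* retains the
   strongest `round(S · N(N−1)/2)` connections.
3. **Graph metrics.** On each binary graph: global clustering coefficient
   (CC), characteristic path length (PL) and global efficiency (EF), plus
   nodal CC, nodal PL, degree (DEG) and betweenness centrality (BC).
4. **Group inference.** Metric values are residualized on age and sex, then
   compared with label-permutation tests (omnibus F across all groups,
   pairwise pooled-variance t), with Benjamini–Hochberg FDR across the 90
   nodes within each (metric, threshold, contrast) family.
5. **Network Based Statistic (NBS).** Edgewise two-sample t statistics on
   Fisher r-to-z transformed correlations are thresholded at a primary
   t = 3.40; connected components of surviving edges are assigned
   family-wise-error-corrected p-values by comparing their extent (edge
   count) with the maximum component size under label permutation.

A synthetic-cohort generator produces parcellated time series, motion
traces and covariates with *known* planted subnetwork effects, so every
stage can be validated against ground truth.

# The statistical model

## Permutation group tests

For a metric value per subject, the null hypothesis of exchangeability
across groups is tested by randomly reassigning group labels while keeping
the original group sizes, recomputing the statistic each time. The Monte
Carlo p-value is

$$p = \frac{1 + \#\{T^{(b)} \ge T_{\mathrm{obs}}\}}{1 + B},$$

which is strictly positive and valid at any $B$. When the number of
distinct labelings is at most $B$, the test switches automatically to full
enumeration and reports $\#\{T^{(m)} \ge T_{\mathrm{obs}}\}/M$ over all $M$
labelings (the observed labeling is one of them, so $p \ge 1/M$). The F
statistic is the ordinary one-way ANOVA ratio; the t statistic is the
pooled-variance two-sample t, compared two-sided via $|t|$. Parametric
p-values are reported as an auxiliary column but permutation p-values drive
all decisions — a single coherent convention rather than a mix of
parametric software output and permutation results.

## Covariate residualization

Age and sex are removed by ordinary least squares on the full sample
(intercept + age + sex, no group terms) before any group comparison.
Fitting without group terms is deliberate: including them would remove part
of the effect under test and change the permutation null. Sex is coded
0/1; any affine recoding leaves the residuals unchanged.

## Network Based Statistic

NBS controls the family-wise error rate over connected components rather
than single edges, which buys power when effects form contiguous
subnetworks. The implementation uses:

* **Fisher r-to-z transformed raw (unclipped) correlations** as edge values
  — the transform's variance-stabilizing property makes the pooled t
  appropriate; this is the standard choice in the NBS literature and is
  configurable (`transform = "none"`).
* **Component extent** (edge count) as the cluster statistic; intensity
  weighting is not implemented.
* **Separate one-sided runs** for increases and decreases, matching the
  way increased and decreased connectivity subnetworks are reported
  separately.
* The primary threshold t = 3.40 is treated as the operative parameter.
  The conventional description of this threshold as "p < 0.001" does not
  match any standard degrees of freedom for these group sizes (a two-sided
  p = 0.001 at df = 48 gives t ≈ 3.505); `t_for_p()` / `p_for_t()` report
  the exact correspondence for any df so users can state both coherently.

## Demographic summary tests

Cohort tables printed in the literature report group means, standard
deviations and counts. `summary_anova()`, `summary_ttest()` and
`chisq_independence()` reconstruct the exact F, t and chi-squared tests
from those summaries (between-group sums of squares from the means,
within-group from $(n-1)\,\mathrm{sd}^2$), so printed tables can be
verified without raw data. Agreement with raw-data tests is exact: a test
generates samples with exactly the stated moments and reproduces t and F
to 10 decimal places.

# Graph-metric conventions

Choices the literature leaves open were fixed as follows (matching the
Rubinov–Sporns conventions used by the standard brain-connectivity
toolboxes):

* **Binary graphs after thresholding.** Degree is defined as a link count,
  which implies binarization; weighted variants are out of scope.
* **CC of nodes with degree < 2 is 0**, and such nodes stay in the global
  mean.
* **Disconnected graphs** (which occur routinely at sparsity 0.10):
  characteristic and nodal PL average over *finite* distances only, with an
  infinite sentinel for isolated nodes; EF uses $1/\infty = 0$ and needs no
  special casing. Before residualization and permutation testing, infinite
  nodal-PL sentinels are mapped to $N$ (one more than any realizable hop
  distance) so least squares stays defined while isolated nodes still
  register as maximally dis-integrated.
* **Betweenness** is Brandes' algorithm over unordered pairs, endpoints
  excluded, unnormalized. Group tests are scale-invariant, so the
  normalization choice affects reported magnitudes only.
* **Edge-count rounding** is half-away-from-zero on $S \cdot N(N-1)/2$.
* **Ties between equal weights** are broken by ascending lexicographic
  node-pair order. This makes thresholding deterministic and — because
  every sparsity level takes a prefix of one fixed edge ordering — makes
  the 41 edge sets nested by construction.
* **Per-subject thresholding**: each subject's matrix is thresholded at
  each sparsity level (the behaviour implied by per-subject metric tables);
  no group-average network is formed.

The distance and betweenness kernels are compiled (Rcpp) breadth-first
search and Brandes accumulation; both are tested to 1e-9 against an
independent graph library on random graphs, and betweenness additionally
against exhaustive shortest-path enumeration on small graphs.

# The synthetic cohort generator

No patient data accompany the study design this package implements, so the
generator *defines* the validation conditions:

* **Design**: three groups (default 20/15/30 subjects, mirroring a
  BD/MDD/HC cohort), ages uniform on 20–62 years, sex Bernoulli(0.5),
  plausible clinical scores (depression and mania scales, illness
  duration).
* **Signal model**: each volume is an i.i.d. zero-mean multivariate
  Gaussian draw whose correlation matrix has a uniform base correlation
  (default 0.1 — the empirical connectivity distribution is not
  characterized in the literature, so this is a free choice exposed in the
  configuration) and a planted offset `delta` on a chosen edge set (default
  a 5-clique, 10 edges) for one group. The i.i.d. model is the simplest
  whose population Pearson matrix is known exactly. An AR(1) option gives
  the series a nontrivial spectrum so that band-pass filtering is testable;
  scan length defaults to 300 volumes at TR = 2 s.
* **PSD repair**: planted offsets can break positive semi-definiteness;
  eigenvalues are clipped at 1e-8 and the matrix re-normalized to unit
  diagonal, with the repair recorded.
* **Motion traces**: Gaussian jitter (sd 0.05 mm translations, 0.05°
  rotations) that always passes QC; designated outlier subjects get a
  2.5 mm step on one translation axis, an unambiguous failure.
* **Age nuisance**: optionally, a linear effect of age on the signal
  standard deviation of a chosen node set, so residualization can be tested
  against a known slope.

What the generator does **not** emulate: temporal autocorrelation beyond
AR(1), hemodynamic response shapes, physiological noise, spatial
autocorrelation between neighbouring parcels, scanner drift beyond a linear
trend, or realistic motion-artifact coupling into the signal. Passing
recovery tests therefore demonstrates that the *statistical machinery* is
correct and calibrated — not that the pipeline is robust to every artifact
structure of real fMRI.

# Numerical choices

* Thresholds are generated on an integer lattice
  (`s_min + k * step`, `k = 0..round((s_max-s_min)/step)`) to avoid
  floating-point drift producing 40 or 42 levels.
* Pearson matrices are symmetrized (`(C + t(C))/2`) and the diagonal forced
  to zero; exact ±1 correlations are clamped at `1 - 1e-12` before the
  Fisher transform.
* Permutation statistics are computed for all permutations at once via
  indicator-matrix cross-products, with a comparison tolerance of 1e-12
  when counting `perm >= observed` so floating-point ties count as ties.
* Zero-variance edges or metrics yield statistic 0 (not NaN) and a
  warning where the cause is data degeneracy.
* The band-pass is an order-4 Butterworth applied forward and backward
  (zero phase); only the pass band is configurable.

# Validation scale

The packaged tests validate at deliberately modest problem sizes chosen to
exercise every code path while keeping the suite quick to run: metric
oracle checks on 100 random 15-node graphs; permutation calibration on
1,000 null simulations with two groups of 10 and 199 permutations (at
which grain the nominal 0.05 level is attainable exactly); NBS family-wise
error on 200 null cohorts of 2 × 12 subjects, 30 nodes, 120 volumes with
1,000 permutations (correlations taken on the raw i.i.d. draws — the
permutation test's error control does not depend on the signal spectrum, so
filtering is exercised elsewhere); and NBS power on ten cohorts at the full
study geometry (2 × 20 subjects, 90 nodes, 300 volumes) run through the
full preprocessing path. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch at a
fixed seed. Production analyses should use 10,000 permutations (the
default in `run_config()`).

# Known limitations

* Weighted-graph metrics, modularity, small-worldness and rich-club
  coefficients are not implemented (not needed for this design).
* NBS is pairwise only; an F-contrast NBS across three groups is not
  provided.
* The global-metric inference reports per-threshold p-values with an
  FDR-adjusted column across thresholds; there is no area-under-curve
  summary across the sparsity grid.
* Voxel-level preprocessing (slice timing, normalization, nuisance
  regression) is upstream of this package: inputs are parcellated time
  series.
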