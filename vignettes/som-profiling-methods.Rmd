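---
title: "Profiling older adults with self-organizing maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling older adults with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the methods implemented in `somprofiles`: the
profile model, the map and clustering machinery, the inferential cascade,
the association models, and the synthetic-cohort generator that stands in
for participant data. It also records the numerical conventions and the
design decisions that were genuinely open, with the reasoning behind each.

## The profile model

A participant's physical profile is the six-vector (Age, Gait/Height,
Grip/BMI, Balance, LAM%, Fat%). The two ratios adjust the performance
measures for body size: taller people walk faster at the same functional
level, and grip strength scales with body mass. Balance is the one-legged
stance time, capped at 45 s by the measurement protocol; LAM% and Fat% are
DXA-derived percentages of body mass. Each variable is z-scored so that
the map's Euclidean geometry weighs them equally.

Two conventions matter downstream:

* **Standardization is within sex.** The map analysis is split by sex, and
  each map's inputs are centered and scaled for its own population, so a
  woman's profile is judged against women. The per-variable means and sds
  are stored on the `feature_matrix` (and exportable as JSON), which makes
  the transform invertible and lets new individuals be projected onto a
  trained map with the training scaling. The sample sd (n − 1) is used.
* **A fixed direction of worsening** per variable: higher Age and Fat% are
  worse; higher Gait/Height, Grip/BMI, Balance and LAM% are better. This
  drives both the severity ordering of clusters and the orientation of the
  color scale.

Degenerate inputs fail loudly: a constant column cannot be standardized,
non-positive heights or BMIs name the offending record, and eligibility
(age at least 60 years, all profile inputs observed) is applied upstream
with a per-record exclusion log. Condition flags may be partially missing;
they are not map inputs, and the statistics drop them pairwise.

## Map training

The lattice is hexagonal with offset rows (odd rows shifted +0.5, row
pitch sqrt(3)/2), so all nearest neighbors sit at plane distance 1 and
interior units have six neighbors. Neighborhood distances are Euclidean in
these plane coordinates — the standard hexagonal convention.

Defaults, with units and rationale:

| Parameter | Default | Why |
|---|---|---|
| lattice size | ≈ 5·sqrt(n) units; aspect follows sqrt(λ₁/λ₂) of the data covariance (capped at 4) | the usual map-sizing heuristic; the longer side carries the dominant data axis (e.g. n = 412 women → 9×11) |
| mode | batch | deterministic given the initialization, which makes runs reproducible and testable; the classic online rule is kept for fidelity |
| epochs | 50 | the quantization-error trace is flat well before this at cohort sizes of a few hundred to a few thousand |
| σ start → end | max(rows, cols)/2 → 1, linear decay | wide early ordering, unit-scale refinement late; ending near 1 preserves topology (low topographic error) |
| neighborhood | Gaussian exp(−d²/2σ²) | smooth, standard |
| initialization | PCA plane (seeded random data rows as fallback) | deterministic and pre-organized; rank-deficient data falls back with a warning |

The batch update makes each unit a convex combination of data rows, so
weights can never leave the data's bounding box; units whose total
neighborhood mass underflows keep their previous weights. In the σ → 0
limit the batch step reduces to a Lloyd (k-means) step — both properties
are exercised by the test suite. Ties in best-matching-unit search are
broken toward the lowest unit index, everywhere, so results are exactly
reproducible. Non-finite weights abort training with the epoch number.

Map quality is reported as quantization error (mean sample-to-BMU
distance, standardized units) and topographic error (fraction of samples
whose best two units are not lattice neighbors).

## Profile clusters

The codebook is clustered hierarchically (Euclidean distance). Ward
linkage (`ward.D2`) is the default: the published analysis names only
"a hierarchical clustering algorithm", and Ward is the common choice for
SOM codebooks, producing compact groups. Complete and average linkage are
available. k defaults to 7, the number of profile types the analysis
identifies per sex; a silhouette scan over k = 2..10 is provided as a
diagnostic only, not as an automatic selector. Participants inherit their
hexagon's cluster; units with no mapped participants are legal.

Severity ordering formalizes "labeled as the results worsen": each
cluster's score is the mean over its member units and the six variables of
the direction-signed standardized weight, and clusters are relabeled 1..k
by ascending score. Because the score is a composite, individual variables
may still be better in a higher-numbered cluster — such exceptions are
expected, and the package makes no attempt to reproduce any particular
set of them. Ties (rare, but possible in constructed data) give the lower
label to the larger cluster. Cluster adjacency on the lattice is reported
(clusters touching through any unit pair at distance 1) but never
enforced: weights are clustered, not positions, so clusters need not be
contiguous.

## The inferential cascade

Per variable across clusters, the omnibus/post hoc branch is selected by
two gates at α = 0.05 each (the analysis fixes no other level):

1. Shapiro–Wilk within each cluster; any rejection routes to
   Kruskal–Wallis with Dunn post hocs. Clusters with fewer than 3
   observations (Shapiro–Wilk undefined) are flagged and the variable
   routed to the rank branch with a warning. A zero-variance cluster
   counts as non-normal.
2. Otherwise Brown–Forsythe (median-centered Levene, the robust variant):
   equal variances → ANOVA with Tukey HSD; unequal → Welch ANOVA with
   Games–Howell.

Games–Howell refers the pairwise Welch statistic to the studentized range
with Welch–Satterthwaite degrees of freedom. Dunn uses the tie-corrected
rank variance with two-sided normal p-values, Holm-adjusted by default
(the adjustment is configurable, including none): Holm controls the
family-wise error comparably to Tukey, keeping the three branches
consistent. Post hoc tests run regardless of the omnibus p — the pairwise
tables are the published reading surface — with the omnibus p reported for
transparency and a strict-gating flag available. Significant cells carry
the direction of the cluster-mean difference; direction is `none` exactly
when a cell is not significant.

The women-vs-men descriptive stage uses a Kolmogorov–Smirnov normality
check per sex (against a normal with the sample moments), then
Brown–Forsythe to pick the equal- or unequal-variance t-test, otherwise
Mann–Whitney; conditions use Pearson's chi-square without continuity
correction, which reproduces printed cohort-level p-values from the
2×2 counts.

## Association models

Cluster membership is the multinomial outcome and the condition the
predictor, matching the "RRR times more likely" reading of the published
pairwise tables; for a binary condition the RRR equals the per-cluster
odds ratio against the reference, so the orientation is symmetric. The
fit is a Newton–Raphson maximum-likelihood multinomial logit written
in-package: quadratic convergence takes the coefficients to machine
precision, which the test suite pins against closed-form 2×2 odds ratios
at 1e-6 and cross-checks against an independent optimizer. Inference is
Wald (observed information), 95% intervals. Any-pair comparisons
re-reference by coefficient contrast, so RRR(a vs b) equals
RRR(a vs ref)/RRR(b vs ref) exactly, and RRR(a vs b)·RRR(b vs a) = 1.
Zero cells (separation) are flagged non-finite and reported with
one-sided intervals rather than dropped. Comorbidity counts use a Poisson
log-linear model with cluster indicators (IRLS tolerance tightened to
1e-14 so the single-factor rate ratio equals the ratio of sample means to
1e-9); profile-likelihood intervals and multivariable adjustment are out
of scope — the models are deliberately univariate.

## The synthetic-cohort generator

The generator emulates the analyzed study population: per sex, a mixture
of seven profile clusters with the published centroid means and sds, the
published mixture proportions (cluster sizes), per-cluster prevalences of
the profiled conditions, sex-level background prevalences for the rest,
per-cluster mean comorbidity counts, and per-cluster education where
published. Heights and BMIs are drawn from the sex-level normals and used
to back-derive raw gait speed and grip strength, so generated cohorts
pass the cohort schema end to end. `simulate_study_database()` assembles
the full study-shaped file: 562 eligible participants at the published
per-cluster sizes, two incomplete-test records, and 56 under-60s, so the
eligibility filter reproduces the published cohort counts exactly.

Choices and what they imply:

* **Within-cluster independence.** Variables are sampled independently
  within a cluster (no within-cluster covariances are published).
  Real profiles are correlated within clusters; passing tests therefore
  show the pipeline recovers independent mixtures, not that it would
  behave identically on the correlated real data.
* **Truncation by rejection sampling** to the physical bounds (balance
  0–45 s, percentages in (0, 100), positive ratios) and to age ≥ 60,
  since the emulated population is the analyzed 60+ cohort. At the
  published sds the induced bias is visible only where a centroid sits
  near a bound (balance near the 45 s cap); the tests compare sample
  means against the closed-form truncated-normal expectation, not the
  nominal centroid.
* **Comorbidity counts are Poisson** at the mean of the published
  per-cluster count distribution (the printed "≥5" bin is counted as 5
  when computing that mean; the bin cannot be un-binned).
* Bernoulli conditions, fixed or multinomial cluster sizes, and full seed
  determinism: one spec + seed gives a byte-identical cohort CSV.

## Known limitations

* The published per-cluster sds are strongly unequal (for balance, 6.1 s
  in one cluster vs 15.1 s in another). Under such heteroscedastic
  mixtures, any equal-metric hard partition — the SOM codebook cut
  included, but equally k-means or Ward on the raw data — splits large
  diffuse clusters and merges small tight ones, so truth-label recovery
  on synthetic mixtures saturates well below what a model-based
  (per-cluster covariance) classifier achieves. This is a property of the
  Euclidean pipeline itself, which the package implements as published;
  the recovery checks in the test suite document it rather than hide it.
* Exact reproduction of the published map geometry is not attempted: the
  original software's grid size, schedule and initialization are not
  public, and map training is stochastic by nature. The package's
  defaults are chosen for reproducibility and map quality (deterministic
  batch mode, PCA initialization), and validation surfaces are the
  desk-reproducible quantities (count-based RRRs, cohort descriptives,
  the chi-square worked example) plus structural properties of the map.
* The severity composite is one formalization of "worsening results";
  its exception list need not match any particular published narrative.
* Problem sizes in the test suite are calibration choices of this
  package: recovery runs use n = 2000 per sex at k = 7 over a three-seed
  set, the type-I calibration uses 500 simulated matrices, and oracle
  comparisons use small fixtures where exhaustive enumeration is exact.

## Numerical conventions

* Tie-breaks: lowest unit index (BMU search), larger cluster first
  (severity ties).
* Tolerances: weights-sum check 1e-9; Newton–Raphson step tolerance
  1e-12 (max 200 iterations); |coefficient| > 30 flags separation;
  standardization round-trips to 1e-9.
* JSON export of codebooks and scalings keeps full double precision.
* All randomness flows through explicit integer seeds (generator spec,
  initialization, online shuffling); batch training is deterministic
  given its initialization.
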