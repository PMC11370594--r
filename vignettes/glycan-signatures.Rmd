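---
title: "Glycan signatures of PDAC subpopulations: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycan signatures of PDAC subpopulations: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosig)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the design choices made where more than one defensible
construction existed.

## 1. From fraction-positive values to binary signatures

The input is a per-cell table: for each segmented cell, the fraction of
its area positive for each glycan stain in the panel (VVL, CA19-9,
sTRA, GM2, plus the TRA and GSL-II channels that the pruning step
exists to discard). Fractions live in [0, 1]; coordinates are in
micrometers; each cell carries a specimen, a spatial cluster, an ROI,
and a pathologist histology label.

**Threshold selection.** For each glycan we grow, per cross-validation
fold, a CART tree (Gini impurity, balanced class priors, minimum leaf
50 cells) on that glycan's values alone against the cancer/non-cancer
label, and take the glycan's threshold as the median over folds of the
root-split cutpoint. Two alternatives were considered and rejected:

* *Each glycan's shallowest split in one joint tree.* A glycan that is
  marginally informative but conditionally redundant given earlier
  splits (GM2 in our synthetic cohorts) then receives only
  negligible-improvement splits deep in the tree, and "its first
  split" becomes a noise artifact — we observed cutpoints near 0.001
  against a planted bimodal gap near 0.2. The per-glycan root split is
  the marginal optimal cutpoint and is stable across folds.
* *Unlimited-depth extraction.* Unnecessary once the tree is
  per-glycan: the root split is the first split by construction.

The complexity parameter `cp` (default 0.01, rpart's standard) doubles
as the flagging rule: a maximally-selected chance split always shows
*some* improvement, so "no informative split" is necessarily a
statement relative to a complexity floor. Glycans whose trees never
split are flagged and receive no threshold.

**Coding.** Positivity is strict (`fraction > θ`); a cell exactly at
threshold on every glycan is `0000`. Strictness keeps the all-zero
control case stable and matches the blood-side convention. The bit
order VVL, CA19-9, sTRA, GM2 is fixed, so `0100` always reads "CA19-9
alone". Class imbalance is handled by balanced priors rather than
resampling: non-cancer cells dominate the tables and we want thresholds
driven by the class boundary, not prevalence.

**Pruning.** `prune_glycans()` removes, iteratively, the channel with
the lowest CART importance provided cross-validated accuracy drops by
at most 0.5 percentage points (configurable). Ties in importance break
toward the earlier panel position, for deterministic builds. Note an
honest subtlety: under this package's synthetic code pools every
cancer code carries CA19-9 or sTRA, so GM2 (and with scarce ducts,
VVL) is accuracy-redundant and can be legitimately pruned even though
it is marginally informative; the pipeline therefore always encodes on
the full fixed coding order and treats pruning as a report.

## 2. Association statistics

**Cluster-adjusted rank-sum.** ROIs from one specimen are correlated,
so the classical Wilcoxon variance is wrong. We use the centered rank
scores $a_{ij} = r_{ij} - (N+1)/2$ and the statistic
$T=\sum_{g_{ij}=1} a_{ij}$, with variance
$\widehat V = V_W \cdot \dfrac{\frac{M}{M-1}\sum_i (d_i-\bar d)^2}
{\frac{N}{N-1}\sum_{ij} (d_{ij}-\bar d_\cdot)^2}$,
where $d_{ij} = (g_{ij}-n_1/N)a_{ij}$, $d_i$ are their within-specimen
sums, and $V_W$ is the tie-corrected classical rank-sum variance. The
inflation ratio is exactly 1 when every specimen contributes a single
ROI, so the test then *equals* the classical normal-approximation
Wilcoxon to machine precision — that reduction is the correctness
anchor, and it is why we did not adopt an existing
informative-cluster-size estimator wholesale: those estimators are
asymptotically, but not exactly, classical in the singleton limit.
Under within-specimen mixing of the two groups the ratio drops below 1
(specimen effects cancel within specimens), and under specimen-level
grouping it rises above 1; both directions were verified by
calibration simulation (size within the binomial band of 0.05 at 20
specimens × 10 ROIs, intraclass correlation 0.5).

**Discovery.** A classification tree grown to purity on four binary
predictors partitions cells into exactly the 16 codes, so the
"terminal branch majority" rule is implemented directly on that
partition: a code observed in at least `min_cells` cells is labeled
cancer iff more than half of its cells are cancer.

**Bootstrap odds ratios.** The resampling unit is the specimen —
resampling ROIs would understate variance for exactly the reason the
rank-sum needed adjusting. Zero cells get the Haldane–Anscombe 0.5
correction (rare codes produce empty cells routinely). The p-value is
the smallest α at which 1 leaves the (1−α) percentile interval,
computed by bisection at resolution 1e-4 on the stored bootstrap
distribution; by construction `p < 0.05` iff the 95% CI excludes 1,
and null-cohort simulations show ~95% coverage at 30 specimens.

**Mixed model.** Per-code log-odds of a cell-level outcome (e.g.
membership in a uniform cluster) come from a binomial random-intercept
model (`lme4::glmer`, Laplace), reference code `0000`. Codes in
complete separation with the outcome are flagged and their estimates
withheld rather than reported at some arbitrary magnitude.

## 3. Spatial segmentation

Densities are isotropic Gaussian kernels evaluated on a shared regular
grid, under the mass convention (the surface sums to the positive-cell
count times the node area) so thresholds are comparable across
cellularities. Defaults: bandwidth 50 μm (a few cell diameters, the
scale at which neighboring cells of one outgrowth merge into one
region), grid spacing 10 μm (the cell-border expansion scale of the
upstream imaging), density threshold at the 0.75 quantile of
occupied-node densities — a quantile, not an absolute density, so
sparse and dense specimens are treated alike — and a 20-cell minimum
region size. The grid origin is anchored to the cell bounding box, so
segmentation is exactly translation invariant. Regions of constant
mask-overlap pattern become ROIs (8-connectivity); each ROI's code is
the bitwise indicator of the masks covering it, and cells attach to
the ROI containing their nearest grid node. The union of ROIs is
exactly the union of dense regions, and ROIs never overlap — both
properties are asserted on random geometries in the tests.

## 4. Heterogeneity, types, quadrants, survival

The Gini index of a composition over k categories is normalized by
k/(k−1) so a one-hot composition scores exactly 1 ("1 is completely
homogeneous"); the unnormalized value is available via
`normalize = FALSE`. The category set is the cancer-associated codes,
configurable. A cluster is *uniform* at Gini ≥ 0.8, inclusively; the
complementary mixed rule is an independent cutoff rather than the
literal complement, so a deliberately stricter mixed criterion (for
example 0.08) remains expressible without touching the uniform rule.

Between-cluster dispersion is the mean Euclidean distance of a tumor's
cluster compositions to their geometric median (Weiszfeld iteration,
tolerance 1e-8, distance floor 1e-12 so iterates may pass through data
points; two-point configurations give half the pairwise distance for
any point on the segment, so the degeneracy is harmless).
Bray–Curtis was considered for the dissimilarity and rejected as the
default because compositions restricted to a fixed category set are
already on a common scale; Euclidean keeps the two-point closed form
and the grid-search oracle exact.

Tumor types use an explicit dominance rule on the three burden
families — sTRA-exclusive {1010, 1011}, CA19-9-exclusive {1100, 1101,
0100}, dual {0110, 1110, 1111}: the leading burden must exceed twice
the runner-up, otherwise (or when dual leads) the tumor is mixed. A
deterministic rule is testable against planted truth; unsupervised
clustering of burden profiles is not.

Quadrants split the cohort at the medians of mean cluster Gini and
dispersion; ties fall to the lower class deterministically, so the
classification depends only on ranks. Survival uses Kaplan–Meier with
right censoring, the log-rank test for overall survival, and a
rank-sum test on time-minus-progression among progressors.

## 5. Lineage graphs

Occurrence is inclusive ("a minimum of 5%" read literally: 0.05
counts). Edges exist only from a code to codes adding exactly one
glycan — the graph is a sub-DAG of the 4-cube, acyclic by construction
— and the weight is the fraction of units containing the child that
also contain the parent. Nodes (and edges from parents) with zero
occurrences are dropped by default (`keep_empty` restores them). Unit
counts, not cell counts, weight the nodes; cluster-level and
tumor-level graphs are both produced and in our synthetic cohorts show
the same stepwise structure.

## 6. Blood panel

Per-assay cutoffs at an anchored specificity are empirical order
statistics (no parametric fit): the `ceiling(t·n)`-th order statistic
of the controls. For the *combined* any-positive test we anchor at the
panel level: a common within-assay rank level chosen on the
max-across-assays rank, so the combination itself achieves the target
specificity in-sample while each single assay is at least that
specific. This mirrors the observable signature of panel-level
anchoring — combined specificity exactly at target with single-assay
specificities above it. Held-out specificity of any empirical
95%-quantile cutoff has expectation ≈ k/(n+1) ≈ 93.4% at n = 60
controls; that order-statistic bias is a property of the estimator,
not a bug, and the acceptance test checks the band around 0.95
averaged over seeds. Resampled performance re-derives cutoffs inside
each of 1000 resamples, so the reported sensitivity does not borrow
strength from fixed thresholds. Subtype prediction is a two-stage
tree — CA19-9 branch first, then the sTRA branch on the remainder —
with thresholds from a sequential exhaustive midpoint search (a joint
search over four assays is exponential and adds nothing once the tree
order is fixed; order is configurable). Mixed-type tumors sit low on
all four assays and are deliberately "undetermined".

## 7. The synthetic cohort generator

`cohort_config()` defaults define the emulated study conditions: 34
tumor specimens and 4 non-cancer pancreata; tumor types CA19-9 / sTRA /
mixed at equal weights; 3–8 cancer clusters per tumor of 80–250 cells
(desk-scale stand-ins for tens of thousands of cells per tumor);
cluster purity uniform on [0.6, 0.95]; non-cancer histologies acinar
(1000/0001), islet (0001), duct (1000/0100/0001) with coherent
per-cluster dominant codes at purity 0.95 — normal structures are
regions, not per-cell lotteries, and modeling them per-cell makes every
duct ROI CA19-9-positive, which no tissue shows. Fraction-positive
values are beta draws: mean 0.7 in the positive state, 0.02 in the
negative, concentration 20 — bimodality is the minimal structure that
makes thresholding meaningful, and nothing in these defaults is an
estimate of any real dataset. TRA copies the sTRA bit with probability
0.9 and GSL-II is pure background, so pruning has its two designed
victims. Spatial layout is isotropic Gaussian blobs on a 4 mm field.

A quarter of tumors are planted as *heterogeneous-uniform* (≥ 2
distinct high-purity outgrowths, purity 0.85–0.98); other tumors adopt
one tumor-level dominant code with probability 0.8 per cluster.
Survival is exponential with hazards log(2)/324 and log(2)/1991 per
day for the two classes (matching median survivals of roughly 324 and
1991 days), censored at 3000 days; progression occurs at a uniform
0.2–0.8 fraction of survival time. Blood RFU is
(baseline + slope × burden) × exp(subject + assay noise) with a shared
per-subject log-normal factor (σ = 0.6) and per-assay noise
(σ = 0.15): controls vary and are correlated across assays, as real
benign conditions elevate several glycans jointly. Each assay's burden
is the tumor's cell fraction in one subpopulation family, which
reproduces the observed pattern that typed tumors light up their assay
while mixed-type tumors stay low everywhere. The entire cohort is a
deterministic function of the config and one seed (a single RNG
stream, drawn in a fixed order).

**What the generator does not emulate** — hence what green tests do
not show about real data: pixel-level staining and segmentation
artifacts, spatially varying background, irregular (non-Gaussian)
cluster shapes and tissue boundaries, per-specimen staining batch
effects, informative cluster sizes, non-exponential survival, and any
correlation between blood noise and tissue noise. Threshold recovery,
discovery power, and panel performance measured here are therefore
statements about the statistical machinery, not about assay accuracy
in tissue.

## 8. Numerical choices and degenerate inputs

Compositions must be simplex-valued within 1e-12; Gini of an empty
composition is an error, not 0. Weiszfeld stops on iterate displacement
< 1e-8. CI-inversion bisection resolves α to 1e-4. Single-cluster
tumors get dispersion 0, flagged. Degenerate cohorts (all tumors
identical) classify into the lower quadrant classes with a warning.
Constant control values give a degenerate-flagged cutoff at that
constant. Empty ROIs cannot arise from grouping; cells without a unit
id are dropped with a warning and counted. All resampling takes an
explicit integer seed, and problem sizes in the tests (cohorts of
10–30 specimens, 200-replicate calibrations, 1000-replicate bootstraps)
were chosen as the smallest at which the calibration targets are
statistically meaningful.
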