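---
title: "Cellular neighborhood coordination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular neighborhood coordination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind `cncoord`, the
parameters that matter and why their defaults are what they are, the design
choices made where the methodology left genuine freedom, and what the
synthetic-data generator does and does not emulate.

## The data model

The unit of analysis is a **cohort of tissue regions**: each patient
contributes one or more physically disjoint regions (tissue-microarray
cores), each region a set of segmented cells with planar coordinates, a
cell-type label from a fixed panel of T types, and binary positivity flags
for a small set of functional markers (e.g. PD-1, Ki-67, ICOS). Clinical
rows carry a two-level group label, a survival time and an event indicator.
Coordinates are treated as dimensionless planar positions; distances are
Euclidean and are only ever computed within a region, because separate cores
are separate tissues and coordinates are not comparable across them.

## Neighborhood identification

A cell's **window** is the cell itself plus its `window_size - 1` nearest
neighbours within the region (default `window_size = 10`, centre cell
included). The window is summarised as the fraction of its cells of each
panel type; these composition vectors are clustered with batch k-means
(`n_cns = 10` by default, multi-start, pinned iteration caps) and every cell
is assigned its window's cluster — its CN. The CN whose centroid loads most
on a declared imaging-artifact cell type can be removed together with its
cells, reproducing the common practice of segregating poor-quality image
areas into their own cluster and discarding them.

Numerical choices:

* Nearest-neighbour queries use an exact kd-tree; ties in distance are
  broken by input cell order, so gridded fixtures are reproducible. The
  tie set is recovered through a candidate slack of 10 extra neighbours,
  which covers the multiplicities that occur on regular lattices.
* Regions with fewer cells than the window size are excluded with a warning
  (configurable to a hard error). Their cells keep an `NA` label.
* If the window matrix has fewer distinct rows than `n_cns`, the number of
  clusters is reduced to the number of distinct rows rather than erroring;
  the reported `n_cns` is the effective count.
* Clustering is deterministic given the seed. Seeds for every stochastic
  stage are derived from one master seed via a string-hashed substream
  (`stage_seed`), so reordering pipeline stages cannot silently reshuffle
  the randomness of other stages.

Per-patient CN frequencies are means over the patient's regions
("mean of cores"), matching how per-patient summaries of core-level
quantities are usually reported for TMAs.

## Contact statistics

Direct contacts are edges of the Delaunay triangulation of each region's
cell centroids (computed with `deldir`; fewer than three cells or exactly
collinear cells yield an empty graph with a warning). For cell types $i, j$:

$$\mathrm{lr}_{ij} = \frac{N_{ij}\,N_t}{N_i\,N_j}, \qquad
  \mathrm{rf}_{ij} = \frac{N_{ij}}{N_i},$$

with $N_{ij}$ the number of edges between types $i$ and $j$, $N_i = \sum_j
N_{ij}$ and $N_t$ the total. Two margin conventions are implemented because
the printed formulas are ambiguous about homotypic edges:

* `convention = "once"` (default): homotypic edges count once in $N_{ij}$
  and hence once in $N_i$. This is the literal reading of the margin
  formula and reproduces the worked arithmetic used in the unit tests
  (four cells, four edges, $\mathrm{lr}(A,B) = 8/9$).
* `convention = "degree"`: ordered-pair counting — the diagonal of
  $N_{ij}$ is doubled, $N_i$ is the type's endpoint degree, and $N_t$ the
  number of ordered adjacent pairs. Under random labelling the expectation
  of $\mathrm{lr}$ is exactly 1 in this convention, whereas under the
  literal convention it is $2/((2-p_i)(2-p_j))$ for type proportions $p$.
  Calibration checks against complete spatial randomness therefore use the
  degree convention; the default remains the literal one.

Pairs with fewer than `min_unique_contact_cells = 100` unique interacting
cells are masked (flagged, not dropped), and group comparisons are
elementwise log2 ratios with the union of the two masks.

The **mixing score** between CNs $a$ and $b$ is, per region, the fraction
of $a$-cells with at least one $b$-cell among their `window_size - 1`
nearest neighbours and vice versa, the two directions averaged, then
averaged over the patient's cores. "Neighbour" here deliberately reuses the
10-cell window rather than Delaunay adjacency, because the score describes
interdigitation of the window-defined neighborhoods; a Delaunay-based
variant is available (`method = "delaunay"`). Both directional fractions
are returned alongside their mean, since a directional summary is equally
defensible.

## The joint composition tensor and its decomposition

For each patient, the joint distribution over (cell type, CN) among the
patient's cells in non-excluded CNs forms one slice of a patients × types ×
CNs tensor (`normalization = "joint"`). Its marginals are, exactly, the
patient's CN occupancy vector and overall type frequencies — an identity
the tests assert. The alternative `"within_cn"` normalisation (each
(patient, CN) composition summing to 1) discards CN abundance and is kept
behind a flag; the joint form is the default because it lets the
decomposition see both where cells are and how abundant the neighborhoods
are. Follicle-like CNs present in only one group are excluded before
normalisation via `excluded_cns`.

**Non-negative Tucker decomposition** approximates the tensor as a small
non-negative core contracted with non-negative factor matrices per mode,
at ranks (2, 6, 6) by default (patient, type and CN modules). No R package
in the dependency set provides this decomposition, so it is implemented in
the package: multiplicative updates on the Frobenius loss with the
iteration loop compiled (RcppArmadillo), all per-iteration work expressed
as small mode products. Details:

* Initialisation: one HOSVD-style start (magnitudes of leading singular
  vectors, floored at 1e-3) plus `n_starts - 1` random starts; the best
  loss wins. Multiplicative updates are monotone, so the reported loss is
  the best local optimum found.
* Convergence: loss evaluated every 25 iterations; stop when the change
  drops below `tol = 1e-9` relative to the tensor norm, with
  `max_iter = 20000` as the cap. These tight defaults cost little at the
  tensor sizes this package targets (tens × tens × ten).
* Scale indeterminacy: factor columns are normalised to unit maximum with
  the scale absorbed into the core, so factors are comparable across runs;
  component order is arbitrary and tests align components to planted truth
  by cosine similarity.
* The **elbow scan** fits a rank grid in increasing order and warm-starts
  every fit from its coordinate predecessors (padded with small positive
  noise) in addition to the random starts. Because the updates are
  monotone and a padded lower-rank solution is feasible at the higher
  rank, scan losses are non-increasing along any coordinate-wise rank
  increase — the property that makes the elbow interpretable.
* **Tissue modules** are the core slices along the patient mode, read as
  weighted bipartite graphs between CN modules and CT modules. The edge
  display threshold defaults to 20% of the maximum core weight; it is a
  display choice, not an inference.

## Differential enrichment

For CN $n$ and subset $c$ (a cell type, possibly refined by required
positive markers):

$$Y_{n,c} = \beta_0 + \beta_1 X + \beta_3 Y_c + e,$$

with $Y$ log frequencies after adding a pseudocount of $10^{-3}$, $X$ the
0/1 group indicator (reference level = first level, lexicographic unless
configured), and $Y_c$ the log overall frequency. $\beta_1$ is CN-specific
enrichment beyond overall abundance; its OLS p value is reported
unadjusted by default (the reporting convention of this exploratory
screen), with Benjamini–Hochberg behind a flag. The coefficient
naming skips $\beta_2$ deliberately — the model has exactly three
coefficients.

Choices: patients without any cell in a CN contribute
$Y_{n,c} = \log(\text{pseudocount})$ rather than being dropped (a missing
neighborhood is informative; `missing = "drop"` is available); rows need at
least 3 usable patients per group; subset frequencies are normalised to
**all** cells of the (patient, CN), not to the parent type, so features are
comparable across subsets — per-parent-type proportions are provided
separately by `marker_proportions`. The overall frequency $Y_c$ is computed
over non-excluded CNs for consistency with the rest of the pipeline.

## Classification and the alteration score

Features (frequency columns) are transformed $x \mapsto \log(10^{-3} + x)$
and z-normalised across the whole dataset before any split. That global
z-normalisation leaks scale information from test patients into training;
it is retained for fidelity to the established protocol, and a
`leak_free` flag disables it. Each repeated
hold-out (RHO) repetition samples 10 training patients per group, picks the
L1 penalty by 5-fold stratified cross-validation *within the training
sample*, fits, and scores the held-out patients by rank-based AUC; 1000
repetitions by default. Feature importance is the z-score (mean/SD) of the
absolute coefficient across repetitions — never-selected features score 0,
always-selected stable features rank top — with 0.3 as the default
flagging cutoff for downstream survival testing.

The **CN functional state alteration score** of a subset compares, over
200 RHO samples, the AUC of a model using only the subset's overall
frequency against a model that adds its CN-specific frequencies in all
non-excluded CNs; the score is $-\log_{10} p$ of a one-sided t-test that
the richer model has greater mean AUC, and the whole procedure repeats 10
times to expose its own variability. Welch's unequal-variance t-test is
used since nothing guarantees equal AUC variances. Single-feature models
are fitted by appending an inert all-zero column, which leaves the lasso
solution for the real feature unchanged while satisfying the fitting
routine's two-column minimum.

## Communication networks

For each pair of CNs and each patient group, the blocks are the patients'
log CN-specific frequencies of a small set of functional subsets (the four
used by default in the acceptance script: ICOS+, Ki-67+ and PD-1+ CD8+
T cells, and Ki-67+ Tregs). Patients without cells in either CN are
excluded pairwise, and a pair needs at least `max(block dims) + 2` complete
patients. The statistic is the first canonical correlation; its null is
5000 permutations of patient identity of one block (sufficient for
exchangeability), and the permutation p is the fraction of permuted
correlations at or above the observed one. An edge joins pairs whose
observed correlation exceeds the 90th permutation percentile (p < 0.10);
edges with p < 0.02 are tiered "strong" — the strong/weak boundary is a
package choice, as no printed threshold exists. Pairwise Pearson and
Spearman correlations of individual features are available separately.

## Survival

Cox proportional-hazards models with a single covariate
$\log(10^{-3} + f)$ for a CN-specific frequency $f$, Efron tie handling
(the frequency covariate is continuous; ties arise only in time), and the
likelihood-ratio p value as the headline test. Kaplan–Meier curves are
drawn at the **optimal split**: all midpoints between sorted covariate
values with at least 3 patients per side are scanned and the split
minimising the log-rank p is chosen. That p is optimistic because the
split was selected to minimise it; the package reports it as the analysis
convention demands but documents the caveat here and alongside the result.
The proportional-hazards assumption is checked by the scaled-Schoenfeld
test (`survival::cox.zph`, KM time transform); fewer than 3 events yield
`NA` with a warning.

## The synthetic-data generator

The generator's defaults emulate the cohort shape this analysis style was
built for: 35 patients in two groups (17 reference, 18 comparison), 4
cores per patient, ~2000 cells per core, a 28-type panel, 9 planted CNs,
and three functional markers. What it plants:

* **Spatial domains**: per core, zone seed points drawn uniformly in a
  disc (radius 350 length units, ~a TMA core at micrometre scale); zones
  are the Voronoi cells of the seeds, so planted CNs are contiguous with
  irregular, tissue-like boundaries. Cells are uniform in the disc with no
  hard-core repulsion — window statistics are composition-based, not
  density-based, so point-process realism matters less than zone geometry.
* **Mixtures**: each CN has three dominant types holding 75% of the mass
  (disjoint across CNs while the panel allows), background flat. The
  functional T-cell types keep a 5% floor share in every CN — lymphocytes
  infiltrate all neighborhoods in real tissue, and the floor gives
  marker-positive subset frequencies support everywhere.
* **CN abundance variation**: patient-level log-normal CN weights
  (SD 0.35) drive the number of zone seeds per CN, so core composition
  varies across patients; an optional latent factor couples two designated
  CNs' abundances *and* (on the logit scale) the marker-positivity rates
  inside them, planting the correlated CN-specific functional frequencies
  that the communication stage is designed to detect.
* **Marker rates**: baseline positivity per marker (8–12%) with
  (group, CN, type, marker) overrides; the defaults plant group-specific
  functional enrichment of PD-1+/ICOS+ CD4+ T cells in one CN of the
  comparison group, and Ki-67 effects in Tregs and CD8+ T cells elsewhere.
* **Survival**: exponential event times with log-hazard linear in the
  centred log CN-specific frequency of one marker-positive subset
  (coefficient −1.2 by default, i.e. protective), a group main effect, and
  administrative-plus-exponential censoring tuned to produce the
  "18 patients, ~13 deaths" regime in the comparison group.

What it does **not** emulate: segmentation error, marker intensity
continua (only binary flags), spatial anisotropy or density gradients
within cores, cell-size effects on Delaunay adjacency, and correlated
marker noise within cells. Passing tests on synthetic data therefore
demonstrate that the estimators recover the structures they target under
idealised noise, not that real-tissue artefacts cannot bias them.

## Problem sizes used by the tests and the acceptance script

The unit and property tests run at deliberately small sizes (hundreds to a
few thousand cells, tens of simulations) chosen so the full suite completes
in a few minutes while keeping each oracle comparison exact or
well-powered. The acceptance script runs the generator at its full default
cohort (35 patients × 4 cores × ~2000 cells ≈ 280,000 cells) and scales
only the resampling counts (200 RHO repetitions, 2000 permutations per CN
pair, 3 alteration-score repeats) to keep a single-core run within a few
minutes; these counts are configuration values, and the protocol defaults
(1000 repetitions, 5000 permutations, 10 repeats) remain the package
defaults.

## Known limitations

* k-means on window compositions inherits k-means' limitations: spherical
  cluster bias, sensitivity to the choice of k, and no uncertainty on CN
  assignments. The CN count is a modelling choice validated by inspection,
  not an estimate.
* The optimal-split log-rank p is not corrected for split selection.
* Multiplicative-update Tucker fits find local optima; multi-start plus
  the HOSVD start makes runs stable in practice (the tests assert a <5%
  coefficient of variation across seeds on planted tensors), but global
  optimality is not guaranteed.
* The enrichment model treats patients as exchangeable given group —
  there are no per-patient random effects, matching the original linear
  model.
* Permutation CCA p values are lower-bounded by 1/n_perm; with 5000
  permutations the smallest attainable p is 2e-4 and reported zeros mean
  "below resolution".
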