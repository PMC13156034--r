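---
title: "Auditing lesion network mapping: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing lesion network mapping: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimator and its compressed form

Lesion network mapping (LNM) asks what network a set of patient lesions has
in common, by seeding each lesion in a normative functional connectome. In
atlas space with R regions, the conventional pipeline is: (1) map each
lesion to its atlas regions; (2) for every normative subject h, compute the
lesion's seed connectivity profile — the mean of the subject's connectome
rows over the lesioned regions, in Fisher-z units — and combine the
profiles across subjects with a one-sample t test against zero, optionally
thresholded at |t| > 7; (3) combine per-lesion maps into a group map, either
by averaging or by a consistency rule (a region is retained when at least a
fraction G, conventionally 75%, of lesions pass the threshold with a common
sign).

`lnmaudit` implements this full route (`lnm(lesions, subjects = H)`) and
its exact linear compression (`lnm(lesions, connectome = C)`). The
compression rests on two observations. First, per-subject seed profiles are
rows of precomputable matrices, so the subject loop reduces to matrix
products. Second, if the per-edge variance across subjects is equal — which
the package's subject generator makes exactly true, and which holds to a
good approximation in real normative cohorts — the one-sample t statistic
is a strictly monotone function of the per-edge mean, so the t step can be
replaced by the mean, i.e. by the group matrix C itself. The whole pipeline
then collapses to

    LNM = sum over patients of (m_s x C) = column aggregation of M x C,

with M the S x R row-normalized lesion matrix (entries 1/|m_s| on lesioned
regions). Multi-region lesions of one patient form one seed (the inner mean
of the row convention), not several. Final maps are reported as means over
patients by default; sums are available (`scale = "sum"`), and every
correlation-based diagnostic is invariant to that choice.

Two algebraic degeneracies anchor the audit and are tested to machine
precision: the identity lesion matrix yields exactly the degree
(row-summation) vector of C, and a single-region lesion copies exactly one
row of C. The symptom-weighted variant (`slnm()`) computes, per region, the
Pearson correlation across patients between the columns of M x C and a
standardized symptom vector; regions with zero variance across lesions are
marked undefined (NA) and excluded from downstream correlations, with a
logged count. Values in the atlas domain are treated as already Fisher-z
transformed; no r-to-z step is applied internally, and time-series
simulation is deliberately out of scope.

Thresholded per-lesion t maps retain their signed values before mean
aggregation, and the consistency rule counts sign agreement; sign-free
binarization is available but not the default, because the sign carries the
anticorrelation structure the audit is about. Zero-variance cells in the t
computation yield signed infinity with a warning rather than an error, so
that degenerate no-noise fixtures remain legal inputs; an infinite t counts
as passing any threshold.

## What the synthetic generators emulate

All analyses run on synthetic data generated by the package, so the study
conditions are explicit and reproducible.

**Atlas** (`generate_atlas()`). Centroids are a Fibonacci lattice on the
unit sphere with small seeded jitter — a stand-in for a cortical surface on
which spin permutation is well defined without meshes. Modules are
spatially contiguous Voronoi cells of farthest-point seeds, balanced by
Lloyd iterations. A contiguous cluster of regions (default 10%) is flagged
subcortical; subcortical regions are excluded from spin rotation, matching
the practice of spinning cortical data only. Each region stores its k
nearest centroids (default 8) for lesion dilation.

**Group connectome** (`generate_connectome()`). The weight matrix is the
sum of three parts. (a) A module block term: +0.2 within modules and a
negative offset between modules; by default every pair of distinct modules
receives the offset (`opposing = "all"`), which places the anticorrelated
edges between networks — where they live in real group connectomes — and
keeps the planted partition the modularity optimum; a label-order pairing
(`opposing = "paired"`) is available. (b) A low-rank gradient term
`sum_k s_k g_k g_k^T` with `g_k` low-order polynomials of the spherical
coordinates (0.4 + z, x, 2xy) and scales (0.5, 0.3, 0.15); the positive
offset in the first pattern emulates the globally positive mean
connectivity component, which simultaneously creates hubs and ties the
leading principal component to degree. (c) Symmetric Gaussian edge noise
(sd 0.1). The between-module offset is then tuned by bisection (at most 50
steps) until the off-diagonal negative-edge fraction is within ±0.05 of the
target, default 0.47 — the anticorrelated-edge fraction reported for
empirical normative connectomes; an unreachable target is an error naming
the achievable range. Passing `target_negative_fraction = NULL` disables
tuning, which homogeneous toy matrices require.

These defaults were fixed once, by matching the stylized facts the audit
needs the synthetic connectome to share with real data: a tunable ~47%
anticorrelated edge fraction, |r(PC1, degree)| ≈ 0.98 (strong overlap of
the first gradient with degree, as in empirical data), a single-region
degree trace around 0.75-0.8, and planted modules recoverable by Newman
modularity with adjusted Rand index above 0.9. What the generator does not
emulate: spatial autocorrelation beyond the smooth gradients, voxel-level
structure, subject-level covariance, or realistic lesion anatomy. Passing
tests therefore demonstrate properties of the method, not of any clinical
dataset.

**Subjects** (`generate_subject_set()`). Each subject matrix is C plus
symmetric i.i.d. Gaussian noise with one global sd per edge — the
equal-variance assumption in its exact form. A zero noise sd is rejected
because it breaks the t test downstream.

**Lesions**. Random lesions anchor uniformly (P = 1/R, with replacement
across lesions) and include the anchor's `dilation` nearest parcels
(default 4, i.e. five-region lesions, the conventional dilation for
parcel-level lesion simulation). Overlapping sets boost the first lesion's
anchor: lesions 2..n anchor at the first anchor with probability
(1 + q)/(R + q) and at each other region with probability 1/(R + q). This
normalization was an open choice — the overlap boost is only loosely
specified in the field — and was chosen because it is a proper probability
distribution that reduces exactly to the uniform scheme at q = 0 and
concentrates all lesions on one site as q → ∞, the two limits that matter.

**Symptoms** (`generate_symptoms()`). Either pure standard-normal noise or
scores linearly coupled to the projection of each patient's lesion
connectivity onto a target map; the coupled mode exists for
parameter-recovery checks of `slnm()`. Output is always standardized
(mean 0, unit sd); constant raw scores are an error.

## Elementary properties and the nine-factor model

`connectome_degree()` is the signed row sum of the unthresholded matrix.
`principal_components()` is a column-centered, unscaled PCA (C is already
in a common z unit), with unit-norm components and a deterministic sign
convention (largest-magnitude loading positive). `detect_modules()` runs
Newman modularity maximization on the positive part of the matrix
(negative weights zeroed, the standard convention for signed functional
connectivity): the leading-eigenvector, greedy-agglomeration and
multilevel maximizers are each followed by a Kernighan–Lin style node
sweep — the fine-tuning stage of Newman's spectral method — and the
partition with the highest modularity is kept; communities beyond the
requested count are merged smallest-first into their most strongly
connected neighbor. This portfolio was adopted because a single spectral
pass occasionally stalls in a local optimum on gradient-rich matrices.

`build_elementary_factors()` assembles the nine-factor design used to ask
how much of a map is generic structure: mean connectivity to subcortical
regions, mean connectivity to cortical regions, mean connectivity to each
of four modules, and the first three principal components.
Self-connections are excluded from every mean. The second factor follows
the "cortical mean" reading; a whole-brain variant (equal to
degree/(R − 1) exactly) is exposed behind `whole_brain = TRUE`, since both
conventions circulate. Exactly four module labels are required — merge
with `detect_modules()` first — and a missing subcortex is a configuration
error rather than a silent substitution. `factor_regression()` is ordinary
least squares with an intercept (plain explained variance is the quantity
of interest; no regularization), and a rank-deficient design is an error
naming the collinear columns.

## Null models

**Spin permutation.** Uniform random rotations (QR of Gaussian matrices,
determinant +1) rotate the cortical centroids; each region is reassigned to
the nearest original centroid. Duplicate targets are allowed (standard
nearest-centroid spin); when spun lesions collide, weights merge so row
sums stay exactly 1. p values are two-sided with the +1 convention,
`(1 + #{|r_null| ≥ |r_obs|})/(n_perm + 1)`, hence never zero; calibration
under independence is verified by a Kolmogorov–Smirnov check in the test
suite.

**Rewiring.** The matrix is binarized at weight > 0.2 and randomized by
Maslov–Sneppen double-edge swaps (10 attempts per edge by default),
preserving every node's binary degree exactly; a graph with no legal swap
is returned unchanged with a warning. Signed weighted rewiring is out of
scope. **Full randomization** permutes the upper-triangle weights and
mirrors them, conserving the weight multiset while destroying degree.
**Module-preserving shuffles** redraw each lesioned region uniformly
within its module, without replacement inside a lesion, so lesion sizes
and the module histogram are preserved exactly. **Mixed pools** draw
lesions without replacement from pooled sets.

## The conjunction sweep and its design choices

`conjunction_sweep()` simulates the conventional statistical battery as a
function of lesion overlap. For each overlap level q it draws lesion sets
(50 lesions, dilation 4), computes per-lesion one-sample t maps against a
synthetic subject set, forms the sensitivity (consistency) map at |t| > 7
with G = 75%, contrasts the set against a matched random control set with
a pooled two-sample t at |t| > 10 (specificity), and intersects the two
(conjunction). A set counts as significant when the conjunction map is
non-empty — the weakest reproducible criterion, since the field does not
define one; a cluster-size parameter is exposed. Sets are binned by their
average pairwise Dice overlap (default bin width 0.04; the acceptance
checks use 0.2-wide bins so every bin holds at least 200 sets); empty bins
are omitted, not reported as zero. Controls are fresh q = 0 sets of
matched size and dilation with derived seeds. No multiple-comparison
correction is applied inside the sensitivity or specificity tests: the
liberality of the conventional thresholds is part of what is being
audited.

The sweep's normative set uses 60 subjects at edge sd 0.1. With these
conditions the per-lesion t values are far above the |t| > 7 threshold
almost everywhere (the test suite and acceptance script report ~99% of
cells supra-threshold), reproducing the known widespread-significance
behavior of large normative cohorts; the proportion of significant sets
rises monotonically with overlap. Absolute percentages are not comparable
to voxel-wise results at R ≈ 1000: with 200 regions there are fewer
opportunities for a region to pass both tests, so significance onsets at
higher overlap than in published voxel-level simulations.

## Problem sizes and other numerical choices

All property checks run at R = 200 with four modules and fixed seeds:
large enough for stable spatial statistics, small enough that the full
suite completes in a few minutes. Specific sizes: full-versus-compressed
equivalence uses 1000 subjects at edge sd 0.01 and 50 lesions; the
convergence curve uses 500 random sets per size at sizes 1, 5, 10, 25, 50;
the spin-lesion null uses 200 permutations; spin calibration uses 200
replicates of 99 permutations; the sweep uses 200 sets per overlap level.
The exact rank equivalence of t and mean aggregation is checked on a
subject set with exactly equal per-edge variance (a centered scalar
sequence times a fixed ±1 pattern), where the equivalence is an algebraic
identity.

Numerical conventions worth knowing: thresholds drop entries with
|value| ≤ threshold (strictly greater survives, matching the |t| > 7
convention); symmetry is enforced at 1e-10 for in-memory matrices and
symmetrized up to 1e-6 on file ingest (beyond that, an error); matrices
are written to TSV at full precision so round trips are bit-exact; region
indices are 1-based everywhere, including on-disk `region_id` columns; all
randomness flows from explicit seeds through `derive_seed()`, and every
generator restores the caller's RNG state.

## Known limitations

The package audits the method, not the brain: its synthetic connectomes
lack realistic spatial autocorrelation, its lesions are parcel sets rather
than anatomical masks, and its subject noise is i.i.d. Gaussian. Voxel-wise
processing, NIfTI ingestion and surface-mesh spin tests are out of scope
(the spin null operates on centroid geometry); variogram-matching
surrogate maps are not implemented — `spin_pvalue()`'s map-in/map-out
interface is the natural adapter point. Real-data replication of published
headline numbers requires the external normative dataset and lesion
collections and is outside the desk-scale scope of this package.
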