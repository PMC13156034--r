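# lnmaudit

Auditing lesion network mapping against the elementary properties of the
connectome it samples.

## The problem

Lesion network mapping (LNM) is a widely used technique in lesion-symptom
research: the lesions of a patient group are projected onto a normative
group functional connectome (e.g. a 1000-subject resting-state dataset
parcellated into R regions), and the average connectivity profile of the
lesion sites is reported as the "lesion network" of the studied condition.
In atlas space the whole three-step pipeline — seed the lesion, compute its
functional connectivity across all normative subjects, combine per-lesion
maps in a group analysis — compresses without loss into a single linear
form:

```
LNM = Σ (M × C)
```

where `M` is the S×R row-normalized lesion indicator matrix (row `s` has
weight `1/|m_s|` on the regions lesioned in patient `s`) and `C` is the R×R
group connectivity matrix in Fisher-z units. The symptom-weighted variant
(sLNM) correlates the columns of `M × C` with a standardized symptom score
vector `sv`, so it scales with `sv × (M × C)`.

This linearity has a sobering consequence: LNM output is constrained to the
elementary structure of `C`. When `M` approaches the identity (many
spatially heterogeneous lesions), the map *is* the degree (row-summation)
vector of `C`; for clustered lesions it is the sum of the selected rows
(the row-induced subgraph `Cm`); and sLNM maps align with the leading
principal components of `C`. `lnmaudit` implements the pipeline, the
compressed form, and a battery of generators, null models and diagnostics
that quantify exactly how much of an LNM result is generic connectome
structure rather than anything condition-specific.

## What is in the package

- **Synthetic data**: `generate_atlas()` (spherical parcellation with
  contiguous modules and a subcortical cluster), `generate_connectome()`
  (modular blocks, tuned anticorrelated edge fraction, low-rank gradients,
  hubs), `generate_subject_set()` (equal edge-variance subject matrices),
  `generate_random_lesions()` / `generate_overlapping_lesions()` (uniform
  anchors, neighbor dilation, a tunable overlap parameter `q`),
  `generate_symptoms()`.
- **The estimator**: `lnm()` fits a lesion network map through the
  compressed linear route (given a connectome) or the full per-subject
  one-sample-t route (given a subject set); `slnm()` fits the
  symptom-weighted variant. Both return classed objects with `print`,
  `summary`, `coef` and `plot` methods. `lesion_tmaps()`,
  `threshold_map()`, `lnm_settings()` expose the pieces.
- **Elementary properties**: `connectome_degree()`,
  `principal_components()`, `detect_modules()` (Newman modularity with
  fine-tuning), `anticorrelation_fraction()`, `row_subgraph_sum()`,
  `build_elementary_factors()` (the nine-factor design: subcortical and
  cortical mean connectivity, four module means, three gradients).
- **Null models**: `build_spin()` / `spin_lesions()` / `spin_pvalue()`
  (spatial spin permutation), `rewire_preserving_degree()`
  (Maslov–Sneppen rewiring of the binarized graph), `randomize_full()`,
  `shuffle_lesions_preserving_modules()`, `mixed_lesion_null()`.
- **Diagnostics**: `spatial_correlation()`, `convergence_to_degree()`,
  `single_region_degree_trace()`, `factor_regression()`,
  `sensitivity_test()` / `specificity_test()` / `conjunction()`,
  `dice_average()`, and `conjunction_sweep()` — the full conventional test
  battery as a function of lesion overlap.
- **IO and pipeline**: TSV/JSON readers and writers for connectomes,
  atlases, lesion sets and maps; `run_config()` / `run_pipeline()` for a
  seeded, manifest-tracked end-to-end audit.

## Worked example

```r
library(lnmaudit)

atlas <- generate_atlas(200, n_modules = 4, subcortical_fraction = 0.1, seed = 1)
C     <- generate_connectome(atlas, seed = 1)
C
#> Group connectome: 200 x 200 signed weights
#>   negative edge fraction: 0.479 | weight range: [-0.706, 1.313]
#>   provenance: generate_connectome (seed 1)

lesions <- generate_random_lesions(atlas, n_lesions = 50, dilation = 4, seed = 2)
fit <- lnm(lesions, C)
summary(fit)
#> lnm map over 200 regions (50 lesions, compressed route)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -0.15166 -0.03239  0.07351  0.07629  0.18496  0.29413
#> strongest regions:
#>  region     value
#>       5 0.2941264
#>       2 0.2895019
#>       1 0.2809983
#>       7 0.2787096
#>       8 0.2768666

spatial_correlation(fit, connectome_degree(C))
#> [1] 0.992085
```

Fifty random lesions produce a map that correlates at r = 0.99 with the
degree vector of the input matrix (printed above as 0.992) — the map reflects the connectome, not
the lesion set. The nine elementary factors absorb essentially all of its
variance:

```r
factors <- build_elementary_factors(C, atlas, detect_modules(C, 4, seed = 1))
factor_regression(fit, factors)$r_squared
#> [1] 0.9967544

convergence_to_degree(C, atlas, set_sizes = c(1, 5, 10, 25, 50),
                      n_runs = 200, seed = 3)
#> Convergence to degree (200 runs per size, dilation 0):
#>  size  mean     sd    q25 median   q75
#>     1 0.301 0.6186 -0.366  0.602 0.860
#>     5 0.628 0.4068  0.510  0.808 0.905
#>    10 0.725 0.3546  0.692  0.868 0.934
#>    25 0.915 0.1113  0.912  0.959 0.973
#>    50 0.959 0.0442  0.952  0.973 0.984
```

Already at 10 heterogeneous lesions the mean correlation with degree is
0.73, rising to 0.92 at 25 — the convergence the audit is about. See the
methods vignette (`vignettes/lnm-audit-methods.Rmd`) for the model behind
the generators, the null models, and every numerical choice.

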