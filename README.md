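# exprdrift

Distance-based classification and prognosis from whole-transcriptome
expression profiles.

## The problem and the approach

Gene-expression signatures — small panels of genes selected to discriminate
disease from health — are notoriously irreproducible: with tens of
thousands of genes and tens of patients (the p ≫ n regime), different
training sets yield nearly disjoint "predictive" panels. `exprdrift`
implements the opposite strategy: use **all** genes and no selection.

Each sample's expression profile is a point in gene-expression space. A
subset of samples (normal tissue, tumor, metastasis, tumor grade, ...) has
a **centroid** — the arithmetic mean of its member profiles — and the
centroid of the normal subset is the *homeostatic center*. For a sample
$X$ and centroid $C$ the package computes any of four distances:

- Euclidean: $D^2 = \sum_i (x_i - c_i)^2$
- Scaled: $D^2 = \sum_i (x_i - c_i)^2 / M_i^2$, with $M_i^2 = \langle x_i^2\rangle$ over the dataset
- Pearson (cosine, the default): $D = 1 - X\cdot C \,/\, (|X||C|) = 1 - \cos\angle(X, C)$ — magnitude-free, and in $[0,1]$ for non-negative data
- Mahalanobis: $D^2 = (X-C)^\top S^{-1} (X-C)$, with pseudo-inverse or ridge regularization when $S$ is singular

From the per-sample distance profile $(r_1, \dots, r_k)$ to all $k$
centroids the package derives: nearest-centroid classification (with
leave-one-out centroids for honest accuracy), barycentric/ternary
coordinates when $k = 3$, group-separation tests on the distance-to-normal
(Welch or Mann-Whitney), and a linear prognostic model
$\text{survival} = a + b\,r_\text{normal}$ fitted by ordinary least
squares — the drift-away-from-homeostasis score as a continuous predictor
of survival. A synthetic-cohort generator with tunable group drift and
dispersion makes the whole pipeline testable end-to-end without any
external data.

Intended users: bioinformaticians analyzing bulk or single-cell expression
matrices (microarray or RNA-seq, any consistent normalization) who want a
signature-free, geometry-based classifier and prognostic score.

## Worked example

```r
library(exprdrift)

design  <- simulation_design(n_genes = 300, seed = 7)   # normal/tumor/metastasis, 8 each
cohort  <- generate_cohort(design)
centers <- compute_centers(cohort$matrix, cohort$metadata)
centers
#> center_set: 3 centers over 300 genes; metric = pearson
#>   groups: metastasis (n=8), normal (n=8), tumor (n=8)

profiles <- distance_profiles(cohort$matrix, centers)
meta     <- attach_survival(cohort$metadata, profiles, design)
res <- run_pipeline(run_config("normal", out_dir = "results", plots = FALSE),
                    cohort$matrix, meta)

head(res$profiles[, 1:5], 3)
#>   sample_id  group r_metastasis r_normal r_tumor
#> 1 normal_01 normal       0.0291 0.001483  0.0387
#> 2 normal_02 normal       0.0270 0.000832  0.0370
#> 3 normal_03 normal       0.0271 0.000862  0.0368
```

Normal samples sit two orders of magnitude closer to their own center
(Pearson distance ~0.001) than to the tumor or metastasis centers (~0.03):
the normal cluster is compact while the diseased clusters have drifted
away. The pairwise tests on distance-to-normal confirm the separation:

```r
res$comparisons[, c("group_a", "group_b", "p_value", "p_adjusted")]
#>      group_a group_b  p_value p_adjusted
#> 1 metastasis  normal 5.96e-11   1.72e-10
#> 2 metastasis   tumor 6.71e-08   6.71e-08
#> 3     normal   tumor 1.15e-10   1.72e-10

res$survival_fit
#> survival ~ distance (ordinary least squares)
#>   slope     = 556.337 days per unit distance
#>   intercept = 1280.19 days
#>   p (slope) = 0.956
#>   R-squared = 0.0002
#>   n         = 16
```

With only 16 patients the planted drift-survival coupling is undetectable —
as expected when the true $R^2$ is 0.09. At realistic cohort sizes the
estimator recovers it reliably: `sim_survival_study(n_reps = 200)` refits
400-tumor cohorts and recovers the planted slope (−13 500 days per unit
distance) with the nominal 95% CI coverage.

The same pipeline runs from the shell:

```sh
Rscript scripts/exprdrift.R simulate --survival --seed 7 --out demo
Rscript scripts/exprdrift.R all --matrix demo/matrix.tsv \
    --metadata demo/metadata.tsv --normal-label normal --out demo/results
```

writing `profiles.tsv`, `barycentric.tsv` (three groups), `comparisons.tsv`,
`survival_fit.txt`, plots, and a `provenance.txt` recording the full
configuration and input checksums.

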