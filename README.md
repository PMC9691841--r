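# mrnet: master-regulator inference from transcriptional networks

`mrnet` reconstructs transcription-factor (TF) regulatory networks from
gene-expression matrices, infers which TFs act as disease **master
regulators (MRs)**, and links them to clinical outcomes. It implements the
joint network-deconvolution + protein-activity workflow used in
case/control transcriptome studies (e.g. diseased vs. normal liver
cohorts): an ARACNe-style mutual-information network per cohort, a
VIPER-style regulon-enrichment activity test per TF, intersection of
significant MRs across cohorts, and downstream association of MRs with
ordinal pathology grades, survival and cell-type infiltration scores. It
is aimed at computational biologists who want the full pipeline — or any
single stage — as plain, tested R functions, with a synthetic-cohort
generator that plants known regulators so every stage can be validated
against ground truth.

## The method

**Network reconstruction.** For each candidate regulator *x* and gene *y*,
mutual information MI(*x*, *y*) is estimated with a bivariate Gaussian
kernel density on copula-transformed margins (ranks mapped to (0,1),
Silverman-type bandwidth), making the estimate exactly invariant to
monotone transforms of either profile. Significance comes from a
permutation null with an exponential tail fitted to its upper 5%, so the
conventional ARACNe edge threshold *P* < 1e-8 (raw or Bonferroni-corrected
for the number of tested pairs — both are exposed) is reachable by
extrapolation. Indirect edges are trimmed by the data processing
inequality: edge (*x*, *y*) is removed when a regulator *z* exists with

    MI(x, y) < (1 − tolerance) · min[ MI(x, z), MI(z, y) ],   tolerance = 0.1

evaluated in a single pass against the original edge list. Surviving
targets form each TF's **regulon**, with a mode of action (sign of the
Spearman correlation between TF and target) and a confidence weight
(edge MI normalized to max 1 within the regulon).

**Activity inference.** A case-vs-control signature is computed per gene
(Welch *t* mapped to a z-score). Each regulon is scored against the
signature by weighted rank-based enrichment

    NES = Σᵢ wᵢ · modeᵢ · q(targetᵢ) / √(Σᵢ wᵢ²)

where *q* are standard-normal quantiles of the signature ranks; NES > 0
means the TF's program is activated in cases. Significance comes from
re-computing all NES under label permutations (default 1000), pooling the
per-TF standardized null scores, and Benjamini–Hochberg adjustment across
TFs. MRs significant in every cohort with a concordant direction form the
cross-cohort consensus.

**Clinical association.** Pearson correlation of TF expression with
ordinal inflammation/fibrosis grades (0–3), single-covariate Cox
proportional-hazards regression (Breslow ties, via the survival package)
for native-liver survival, and Pearson correlation of per-sample TF
activity with ssGSEA cell-type infiltration scores (weighted
ECDF-difference scores over expression-ranked genes).

**Synthetic benchmarks.** `generate_network()` / `generate_cohort()` plant
a known network (regulons with signed modes and strengths, a configurable
number of case-activated and case-repressed TFs), clinical variables driven
by a designated driver TF (latent-correlated ordinal grades, exponential
proportional-hazards survival with administrative censoring), and cell-type
signature genes tracking latent abundances — everything downstream can be
scored against this truth.

## Worked example

```r
library(mrnet)

net <- generate_network(n_tf = 8, n_genes = 400, regulon_size = c(20, 40),
                        frac_activated = 0.5, frac_repressed = 0.25, seed = 1)
co  <- generate_cohort(net, n_case = 100, n_control = 60,
                       effect_size = 2, seed = 2)

null     <- fit_mi_null(co$expression, n_perm = 1000, seed = 3)
edges    <- apply_dpi(build_edge_list(co$expression, net$regulators,
                                      p_threshold = 1e-8, null = null,
                                      corrected = FALSE), tolerance = 0.1)
regulons <- edges_to_regulons(edges, co$expression, min_size = 10)
act      <- permutation_pvalues(co$expression, co$labels, regulons,
                                n_perm = 200, seed = 4)
act
#> Activity table: 8 regulator(s), 5 activated / 3 repressed at face value
#>     tf       nes           p      p_adj direction
#> 3 TF03 11.469357 0.005621487 0.02248595 activated
#> 5 TF05 12.380191 0.005621487 0.02248595 activated
#> 7 TF07 12.336288 0.018113679 0.04830314 activated
#> 4 TF04 -9.195057 0.024984385 0.04996877 repressed
#> 1 TF01  7.059476 0.034353529 0.05496565 activated
#> 8 TF08 -9.562637 0.043098064 0.05746408 repressed
#> ...
```

The four TFs passing `select_mrs(act, alpha = 0.05)` (TF05, TF07, TF03,
TF04) are all planted regulators with the correct direction; the two
remaining planted TFs sit just above the adjusted-p cutoff, and the two
unperturbed TFs rank last. Clinical association then recovers the planted
driver (TF07):

```r
grade_associations(co$expression, co$clinical, co$driver)   # fibrosis row
#>     tf variable         r            p   n
#> 2 TF07 fibrosis 0.5425188 5.527443e-09 100
survival_associations(co$expression, co$clinical, co$driver)
#>     tf      beta      hr           p converged
#> 1 TF07 0.6214952 1.86171 6.00193e-08      TRUE

scores <- ssgsea_scores(co$expression, co$cell_signatures)
a      <- sample_activity(co$expression, regulons[co$driver])
activity_cell_correlation(a, scores)
#>     tf cell_type             r            p   n
#> 1 TF07 celltype1  0.6411244530 6.728533e-20 160
#> 2 TF07 celltype2 -0.0851445751 2.843925e-01 160
#> ...
```

The fibrosis correlation (r ≈ 0.54), the hazard ratio (HR ≈ 1.9 per
activity unit) and the infiltration correlation with the linked cell type
(r ≈ 0.64) all reflect the planted latent correlations (ρ = 0.6, β = 0.7).

A whole multi-cohort study (per-cohort networks → activity → consensus →
clinical/infiltration/enrichment, with a reproducibility manifest) runs
from one YAML config via `run_pipeline("config.yaml")`; a thin shell
front end with the same verbs lives at `inst/scripts/mrnet`.

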