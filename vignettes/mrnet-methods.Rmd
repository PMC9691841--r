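---
title: "Methods: network deconvolution, regulon activity and clinical association in mrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network deconvolution, regulon activity and clinical association in mrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `mrnet`, the choices made where
the methodology is genuinely open, and what the package's synthetic
benchmarks do and do not establish.

## Mutual-information network reconstruction

### Estimator

For a candidate regulator $x$ and gene $y$ observed over $n$ samples,
both profiles are first mapped to copula margins: values are replaced by
$r_i/(n+1)$ where $r_i$ is the within-gene rank (ties broken by
position). Mutual information is then estimated as the average
log-density ratio over the data points,

$$\widehat{MI}(x,y) = \frac{1}{n}\sum_{i=1}^n
  \log\frac{\hat f_{XY}(u_i, v_i)}{\hat f_X(u_i)\,\hat f_Y(v_i)},$$

with $\hat f$ Gaussian kernel density estimates using the bivariate
rule-of-thumb bandwidth $h = \hat\sigma\, n^{-1/6}$. Because the copula
margins are the same grid for every gene, the marginal terms are a
shared constant and the estimate depends only on the joint ranking —
giving exact symmetry and exact invariance under strictly monotone
transforms of either profile (the properties the test suite asserts
bit-for-bit). Estimates are clipped at zero; the small positive bias for
independent pairs is irrelevant because all thresholding is done against
a null built with the same estimator.

Kernel boundary effects on $[0,1]$ are not corrected: they cancel to
first order between the joint and marginal terms, and any residual bias
is common to observed and permuted statistics.

### Independence null and the 1e-8 threshold

The null distribution of $\widehat{MI}$ under independence depends only
on $n$ (the estimator is rank-based), and is sampled by permuting the
sample order of one member of randomly drawn gene pairs
(`fit_mi_null()`, default 1000 draws). Edge p-values of order $10^{-8}$
are far beyond empirical resolution, so an exponential tail is fitted to
the exceedances over the empirical 95th percentile (the tail window is
widened when fewer than 20 exceedances would remain) and survival
probabilities beyond the threshold are extrapolated:
$P(MI > m) = S_t\, e^{-\lambda (m - t)}$ with $\lambda$ the reciprocal
mean exceedance. The p-value map is monotone non-increasing in MI and
continuous at the tail threshold.

Whether the conventional 1e-8 edge threshold applies to the raw
independence p-value or to the Bonferroni-corrected one (correction over
the $|\text{regulators}| \times (|\text{genes}|-1)$ tested pairs) is
ambiguous in the literature this pipeline follows; `build_edge_list()`
exposes both (`corrected`, default `TRUE`), and the package's own
benchmarks use the raw reading, which matches common ARACNe practice and
yields edge F1 around 0.85 (versus roughly 0.8 corrected) on the planted
benchmark. Candidate pairs are restricted to (regulator, gene) pairs;
regulator–regulator edges are kept because the intermediate node of a
data-processing-inequality path must itself be a regulator.

### DPI trimming

For every retained edge $(x, y)$ and every regulator $z$ with both legs
$(x,z)$ and $(z,y)$ present, the edge is removed when
$MI(x,y) < (1-\text{tolerance})\min[MI(x,z), MI(z,y)]$ (tolerance 0.1).
Three semantic details the inequality itself leaves open are fixed as:
all comparisons use the *original* edge list (single pass, no cascade of
removals), exact ties keep the edge, and edges are treated as undirected
for path lookup since MI is symmetric. A brute-force triple-enumeration
oracle verifies the implementation exactly on random instances.

### Regulon assembly

Surviving targets form each regulator's regulon with
`mode` = Spearman correlation sign/magnitude between TF and target
expression and `likelihood` = edge MI divided by the regulon's maximum
MI. Regulators with fewer than `min_size` targets (default 25, the
conventional floor; the desk-scale benchmarks lower it to 10 — see
below) are dropped.

## Regulon activity and master-regulator selection

The case/control signature is the per-gene Welch $t$ (case minus
control) mapped through the $t$ CDF to a z-score, computed on log scale;
within-group variances are floored at $10^{-8}$ so constant genes do not
produce infinities. The enrichment of a regulon with weights $w_i$
(likelihood) and modes $m_i$ against signature quantiles
$q_i = \Phi^{-1}(\mathrm{rank}_i/(N+1))$ is

$$NES = \frac{\sum_i w_i m_i q_i}{\sqrt{\sum_i w_i^2}},$$

which has mean $\approx 0$ and variance $\approx 1$ over random target
placements, so scores are comparable across regulon sizes. This is a
single-tail simplification of the three-tail aREA combination: modes
derived from Spearman signs are near $\pm 1$, so the two-tail term for
weak-mode targets is deliberately omitted. Pleiotropy ("shadow")
correction is not implemented — the CLI flag is reserved and errors —
because no parameterization is given in the source methodology and a
silent approximation would be unverifiable.

Significance uses label permutations: the signature and all NES are
recomputed for each of `n_perm` shuffles (default 1000; benchmarks use
100–200), null scores are standardized per TF and pooled across TFs, and
the two-sided p-value is $(1 + \#\{|z_{null}| \ge |z_{obs}|\})/(N_{pool}+1)$.
The pooled denominator is the coherent generalization of the usual
$(n_{perm}+1)$ pseudocount once nulls are pooled; it sharpens resolution
to $1/(n_{TF}\, n_{perm}+1)$. Selection uses Benjamini–Hochberg adjusted
p-values (raw p is reported alongside); consensus across cohorts
requires adjusted significance in *every* cohort with concordant NES
sign, and sign-discordant TFs are excluded and reported separately.

An important property of this null, worth stating explicitly: regulon
targets are co-expressed, so permuted-label NES is heavy-tailed (per-TF
null standard deviations of 3–5 are typical in the synthetic cohorts
rather than 1). Standardized observed scores therefore saturate around
2–3 even for strongly perturbed regulators, and single-TF p-values
rarely reach the pooled minimum; recovery of planted regulators is
driven by the pooled tail plus BH, not by vanishing p-values. Label-swap
antisymmetry is exact end-to-end: swapping case and control labels
negates every signature z, every NES and every null draw, leaving all
p-values unchanged.

## Clinical association

Ordinal grades (0–3) enter Pearson correlation as numeric values; the
reported p uses the $t$ transform with $n-2$ degrees of freedom.
Survival uses single-covariate Cox proportional-hazards regression with
Breslow tie handling, delegated to `survival::coxph()` (tolerance
$10^{-8}$, up to 50 iterations); non-convergence and monotone-likelihood
warnings are surfaced as a `converged` flag rather than an error, while
a constant covariate is rejected as non-identifiable. Parameter recovery
and confidence-interval coverage are verified by simulation (bias below
0.05 at $n=500$; coverage at the nominal 95% within binomial error).

Cell-type infiltration is scored by a single-sample rank-based
enrichment: genes are ordered by expression within each sample, the gene
at descending position $j$ receives weight $(n-j+1)^{\alpha}$
($\alpha = 0.25$), and a set's score is the summed difference between
the weighted in-set cumulative distribution and the unweighted
out-of-set one, normalized by the global score range (raw scores are
kept as an attribute). Per-sample TF activity — needed to correlate
activity with infiltration — is the regulon NES of each sample's
one-vs-rest z-signature (gene value minus cohort mean over cohort SD).
This definition is one of several reasonable choices; it is recorded in
the run manifest.

## Over-representation analysis

Target-set enrichment against user-supplied GMT collections uses the
upper-tail hypergeometric probability within an explicit, mandatory
universe (results are universe-sensitive, so no default genome is
assumed; the pipeline uses the union of expression genes). Sets are
size-filtered after universe intersection (defaults 5–2000).
"FDR" adjustment is Benjamini–Hochberg step-up (with Bonferroni as an
option), via `stats::p.adjust`.

## The synthetic-cohort generator

`generate_cohort()` draws per-sample latent TF activities
$a_t \sim N(0,1)$, shifted by $\pm$`effect_size` in cases for planted
TFs; a TF's own transcript is $a_t$ plus noise and each target is
$\sum_t s_t m_t a_t$ plus noise ($s$ strength, $m$ mode). Clinical
variables attach to a designated driver TF: ordinal grades threshold a
Gaussian latent $\rho$-correlated with driver activity at fixed quartile
cutpoints; survival is exponential with log-hazard $\beta a_{driver}$
(baseline scale 36 months) and administrative censoring at the 70th
percentile of event times (~30% censored — no external censoring
information was available to emulate). Cell-type signature genes track
latent abundances, one abundance $\rho$-linked to the driver. An
optional count mode re-emits expression as $\log(1+\text{Poisson})$ of
exponentiated values to mimic RNA-seq quantization.

What this emulates: TF-driven co-expression with signed modes,
case-only activity shifts, grade/survival/infiltration linkage to one
driver. What it does not: batch and platform artifacts, probe effects,
non-linear regulation, overlapping biological programs, realistic
cell-type proportions, or gene-gene dependence beyond the planted
single-layer network. Passing the planted benchmarks therefore
demonstrates correctness and calibration of the inference machinery
under the stated generative model, not performance on real cohorts.

## Benchmark configurations and problem sizes

The package's acceptance benchmarks (mirrored in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) use:

* **Network recovery**: 20 TFs, 1000 genes, 200 samples, strengths in
  $[0.5, 1]$, noise SD 0.5; edge F1 against truth $\ge 0.7$ (observed
  ~0.8–0.9 across seeds).
* **Consensus recovery**: one planted network of 30 TFs (14 activated,
  8 repressed, 8 unperturbed), 1000 genes, two independent cohorts of
  100 cases + 100 controls, effect size 2; full reconstruction route
  with the raw 1e-8 threshold, regulon floor 10, 200 activity
  permutations. These sizes were chosen because the network-recall
  stage, not the activity test, is the power bottleneck at desk scale:
  with fewer than ~150 samples or the corrected threshold the
  1e-8 edge cut leaves too few targets per regulon, and planted TFs
  drop out of the regulon set before activity is ever tested. The
  chosen configuration recovers 22/22 planted TFs with correct
  directions and no false positives on every probe seed.
* **Null calibration**: 40 replicate null cohorts (effect 0), 200
  permutations; type-I error at 0.05 within [0.03, 0.07] and p-value
  uniformity by Kolmogorov–Smirnov.
* **Driver recovery**: 20 replicate clinical cohorts (100 cases),
  $\rho = 0.6$, $\beta = 0.7$; fibrosis, survival and linked-cell
  associations each recovered in $\ge 90\%$ of replicates, unlinked
  TF–cell pairs significant at ~5%.

All benchmark randomness derives from one top-level seed; pipeline stage
seeds are deterministic functions of it, and a rerun with the same
config and seed is byte-identical (verified by checksum).

## Numerical and degenerate-input conventions

* Constant-expression genes are dropped before MI with a logged count;
  a constant vector passed directly to `estimate_mi()` or
  `pearson_assoc()` is an error naming the offender.
* Rank ties: MI uses position-order tie breaking (a permutation is
  required for the shared-grid kernel); signatures and ssGSEA use
  average ranks.
* Duplicate gene ids in input files are collapsed by mean with a
  message; sample-id mismatches between expression, labels and clinical
  tables are fatal.
* Degenerate label permutations (a single-group shuffle) cannot occur
  with fixed group sizes but are guarded against anyway.
* Regulons mapping fewer than `min_targets` (default 10) genes into a
  signature universe are skipped with a message.

## Known limitations

* The MI estimator is $O(n^2)$ per pair; cohorts beyond a few hundred
  samples or candidate universes beyond a few thousand genes will be
  slow in pure R.
* The exponential tail extrapolation to $10^{-8}$ is a modeling
  assumption; its rate estimate from ~20–50 exceedances carries ~15–20%
  relative error, which translates into seed-to-seed variation in edge
  counts near the threshold.
* No pleiotropy/shadow correction, no bootstrap-consensus network, no
  single-sample VIPER beyond the one-vs-rest construction described
  above, and no multivariable or penalized Cox.
* Gene identifiers are matched as exact strings; no alias resolution.
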