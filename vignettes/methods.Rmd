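---
title: "Multi-phenotype microbiota association scanning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phenotype microbiota association scanning: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miwas)
```

## The problem

Population cohorts with uniform gut microbiota profiling make it possible to
compare microbiota associations *across* many diseases and medications,
rather than one condition at a time. The statistical obstacles are the same
in every such cohort: microbiota variables are high-dimensional and heavily
inter-correlated; binary health phenotypes are self-reported, incomplete,
and themselves correlated through comorbidity and co-prescription; and the
abundance measurements carry technical structure (extraction batch,
collection method, sequencing run, sequencing depth) and family structure
(twin pairs) that must not leak into the associations.

`miwas` implements the full chain: encoding questionnaire responses into
binary statuses, assembling a trait matrix, pruning it to a minimal
marker set on a correlation network, residualizing markers against
confounders, scanning all phenotype-by-marker pairs with logistic
regression under FDR control, clustering the association profiles with
bootstrap support, and quantifying disease–medication overlap.

## Phenotype encoding and the phi coefficient

A sample is *positive* for a condition if any questionnaire wave records a
yes, *negative* if it only records no, *unknown* if no wave was answered
(`encode_any_yes`). Ordinal frequency items (0–4) split at 3
(`encode_ordinal_threshold`); composites such as hearing loss are positive
if any of their indicators is (`encode_any_of`). Phenotypes below a
prevalence threshold (default 1% of a reference cohort) are dropped.

Correlation between binary statuses uses the phi coefficient — Pearson's
correlation specialized to a 2×2 table,

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
{\sqrt{n_{1\cdot}\,n_{0\cdot}\,n_{\cdot 1}\,n_{\cdot 0}}},$$

computed on pairwise-complete samples. P-values use the relation
$n\phi^2 \sim \chi^2_1$ without continuity correction; an exact test would
change little at cohort scale and the chi-square form keeps the FDR
machinery uniform. This choice is configurable in spirit (the p-value
enters only eligibility filters), and the identity of phi with Pearson's
$r$ on 0/1 codings is enforced by a property test.

## Trait assembly

Taxon counts are collapsed at class and family level; taxa without a
complete lineage assignment through the target rank are excluded rather
than pooled into pseudo-taxa. Collapsed counts become log relative
abundances with a pseudocount:

$$x_{ij} = \log\frac{c_{ij} + \tfrac12}{d_i + \tfrac12\,T},$$

where $d_i$ is the sample's depth and $T$ the number of taxa. The
pseudocount (default 0.5, configurable) is needed because zero counts are
ubiquitous in collapsed tables; the adjusted relative abundances still sum
to one per sample. Alpha diversity enters as Shannon index (base 2 by
default, so values read in bits; switchable to natural log), observed
richness, and — because it requires a phylogeny — phylogenetic diversity
only as a precomputed input column. Beta diversity enters as the first six
principal-coordinate axes per distance matrix, computed by classical
scaling; negative eigenvalues from non-Euclidean distances are dropped
with a warning, the standard practice for metric scaling.

## Marker selection

Spearman correlations are computed between all trait pairs and thresholded
into a graph: traits are nodes, and an edge joins two traits whose
correlation magnitude *strictly* exceeds 0.8. The absolute value is the
default because a strongly negatively correlated trait is just as
redundant as a positively correlated one; a signed variant is available
for sensitivity analysis. Markers are then chosen greedily: pick the
highest-degree surviving node (uniform seeded tie-break), remove it and
its surviving neighbours, recompute degrees on the reduced network, and
repeat. Degrees are recomputed each iteration because the selection
operates on the *remaining* redundancy structure; a static-degree variant
exists behind a flag for comparison.

The output is, by construction, an independent dominating set: markers are
pairwise non-adjacent and every discarded trait is adjacent to at least
one marker. `verify_coverage()` re-checks this after every selection, and
the test suite verifies it against a brute-force adjacency scan on 200
random graphs. No claim of minimality is made — minimum dominating sets
are NP-hard and the greedy heuristic is the contract.

## Residualization and the association scan

Each marker trait is modelled as the response of a Gaussian mixed model
with random intercepts for DNA extractor, collection method, sequencing
run, sex and family, and fixed effects for log sequencing depth plus,
depending on the scan variant, age and/or BMI (`full`, `no_bmi`,
`no_age`, `neither`). Sex enters as a random intercept deliberately,
mirroring the modelling convention this pipeline reproduces, even though a
two-level random effect is unconventional; with two levels the fitted
variance component behaves like a shrunken fixed effect and the residuals
are insensitive to the choice. Depth is adjusted in *all* variants.
Factors left with a single level are dropped with a warning, and a trait
whose mixed fit fails falls back to a fixed-effects-only fit, recorded in
the fit log. Model fitting uses `lme4`, with the first successful fit
recycled via `refit()` across traits for speed.

The scan itself is one logistic regression per (phenotype, trait) pair —
status on intercept plus residualized trait — on the samples where both
are observed. Wald slope, standard error and p-value are recorded; pairs
without both cases and controls are emitted as `skipped`, and separated
or unconverged fits are flagged rather than dropped, and excluded from
the multiplicity count. FDR control is Benjamini–Hochberg, by default
jointly across the whole phenotype × trait matrix within a variant
(per-phenotype scope is available); the same `bh_adjust()` is reused for
the phi-correlation table so there is exactly one FDR implementation in
the package. Antibiotic use is treated as a phenotype to scan, never as a
covariate.

## Clustering association profiles

The matrix of logistic slopes (traits × phenotypes) is sparsified:
coefficients from associations with $p \ge 0.05$ are set to zero and
traits or phenotypes left without any nonzero entry are removed. Profiles
are compared by cosine distance, $d = 1 - \cos(u, v) \in [0, 2]$, which
depends only on profile direction and is therefore little influenced by
the zeros; complete-linkage clustering builds the dendrogram. For heatmaps
only, coefficients are arcsine-transformed (scaled by the matrix maximum
when it exceeds 1, since arcsin is defined on $[-1,1]$) to stretch
contrast between small coefficients and exact zeros — the transform never
feeds the clustering.

Cluster support uses the multiscale bootstrap. The resampling unit is the
profile coordinate — the phenotype axis when clustering traits — because
those coordinates are the observations defining the dissimilarity. For
each scale $r$ in a default grid of 10 values in $[0.5, 1.4]$,
$\mathrm{round}(r\,n)$ coordinates are resampled with replacement
`n_boot` times and the fraction of replicate trees containing each
original cluster gives its per-scale bootstrap probability
$\mathrm{BP}_r$. Writing $z_r = \Phi^{-1}(1-\mathrm{BP}_r)$, the model
$z_r = v\sqrt{r} + c/\sqrt{r}$ is fitted by weighted least squares over
the scales where BP lies strictly inside (0, 1), and the approximately
unbiased support is $\mathrm{AU} = 1 - \Phi(v - c)$. Two numerical edge
cases need care: a cluster never recovered at any scale gets AU = 0, and
a cluster whose BP is pinned at 0 or 1 at (nearly) every scale leaves the
probit fit unidentified — the $v$/$c$ split of a constant is arbitrary and
naive clamping would report AU ≈ 0.5 for a *maximally* supported cluster —
so support is then read off the majority BP directly (0 or 1). Clusters
with AU-based $p < 0.05$ are flagged significant. Dendrograms export as
Newick with AU values as internal node labels.

## Disease–medication overlap

Every disease × medication pair is scored by (i) phi correlation of the
status vectors with FDR over all pairs in the table, and (ii) the Jaccard
index of the two phenotypes' nominal association sets (traits with
$p < 0.05$). A pair is *eligible* for overlap interpretation when its phi
is FDR-significant and both sets contain at least 10 traits. The Jaccard
of two empty sets is defined as 0 with a warning (it cannot arise under
the eligibility rule). Patterns of interest separate cleanly: a disease
with a near-uniform treatment shows high phi *and* high Jaccard, while a
non-specific treatment can share most of a disease's associations at low
phi.

## The synthetic cohort generator

Everything above is exercised end to end on simulated twin cohorts, so
the generator is first-class, tested code. Its defaults emulate the kind
of cohort this pipeline targets: mostly female (90%), age 60 ± 12,
BMI 26 ± 5, twin pairs sharing age and sex, binary phenotypes at
prevalences of a few to forty percent, technical factors (3 extraction
batches, 2 collection methods, 8 runs, log-normal depth), and a
configurable fraction of unknown phenotype entries reflecting incomplete
questionnaires.

Phenotypes come from a Gaussian copula. Each phenotype has a latent
standard normal score, correlated across phenotypes and within twin pairs
(intraclass correlation 0.25 by default); the score maps to a uniform
$U$. A sample is a case when

$$U < \mathrm{logit}^{-1}\!\big(\alpha + \textstyle\sum_k \beta_k
\tilde{t}_k\big),$$

with $\alpha$ solved numerically so the realized prevalence matches its
target. Two consequences drive the design. First, with no planted
effects this reduces to thresholding the latent normal at the prevalence
quantile, so target pairwise phi values can be controlled exactly by
solving for the latent (tetrachoric) correlation of each pair — done by
one-dimensional quadrature of the bivariate normal rectangle plus root
finding, with infeasible targets rejected by name. Second, a planted
`log_odds_per_sd` is *exactly* the conditional logistic slope on the
standardized clean trait, so parameter-recovery tests compare estimates
against the planted value directly, with no liability-scale conversion.
Because the planted effects must rewrite case status conditional on the
traits, `simulate_traits_and_effects()` returns the updated phenotype
table alongside the traits and covariates; `simulate_cohort()` is the
orchestrating constructor.

Traits are standard normal with equicorrelated blocks (a shared factor
per block; default 12 blocks of 5 at Pearson ρ = 0.9, plus 8 singletons,
giving 68 traits) and a family component (ICC 0.3). The *observed* traits
add per-trait batch-level offsets (SD 0.3), a loading on standardized log
depth (SD 0.2), and small age/BMI loadings (SD 0.1) — so residualization
has real confounding to remove; the clean signal is kept as an attribute
for oracle comparisons. One point is worth making explicit: this
technical noise attenuates the observed between-trait correlations, so
whether a ρ = 0.9 block collapses to a single marker at the 0.8 edge
threshold depends on how much noise is configured. The marker-selection
recovery checks therefore use noise-free blocks (the property under test
is the selection, not the noise), while the end-to-end fixture keeps the
noise and simply requires the marker count to land between the block
count and the trait count.

What the generator does *not* emulate: raw sequence reads, compositional
closure of real abundance data, zero inflation, phylogenetic structure,
or non-Gaussian trait margins. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to every
property of real 16S data.

## Problem sizes and determinism

The test and acceptance workloads use cohorts of 1000–2000 samples, 68
traits and up to 20 phenotypes, 100–200 replicates for calibration and
power, and 1000 bootstrap iterations per scale for cluster support —
sizes at which every quantity of interest (prevalence, phi, power, AU)
has comfortably small Monte-Carlo error while a full run stays in the
minutes range on one CPU. Under the global null the scan's mean nominal
positive rate is checked against [0.035, 0.065]; per-replicate rates are
judged in aggregate because correlated trait blocks reduce the effective
number of tests, inflating the replicate-to-replicate spread beyond the
independence bound.

A single run seed fans out deterministically to per-stage seeds (a
counter scheme kept inside 32-bit integer range), tie-breaks in the
greedy selection are seeded and logged, complete-linkage ties resolve by
`hclust`'s deterministic merge order, and run manifests record the config
hash and seed but no timestamps — so one config + seed reproduces a run
byte for byte.

## Known limitations

* Cross-sectional associations only; nothing here supports causal
  attribution of overlap to disease versus medication.
* The Wald logistic p-value is slightly liberal at very low case counts;
  rare phenotypes near the 1% prevalence floor inherit that behaviour.
* AU support values are asymptotic approximations; with few profile
  coordinates (phenotypes), supports are noisy and should be read
  qualitatively.
* The mixed-model residualization assumes Gaussian trait residuals;
  heavy-tailed traits are handled only through the rank-based selection
  step, not the scan itself.
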