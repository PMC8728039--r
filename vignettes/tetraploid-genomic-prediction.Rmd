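---
title: "Genomic prediction in a finite-size autotetraploid breeding program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in a finite-size autotetraploid breeding program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragebv)
```

## The problem

Clonal crops such as tetraploid potato are bred by crossing selected
parents and then discarding most of the resulting seedlings over successive
clonal field generations (T1, T2, ..., Tn). Phenotyping is the cost
bottleneck in the earliest generations, when the number of genotypes is
largest and the number of plants per genotype smallest. Genomic selection
promises to replace part of that phenotyping: estimate marker effects from
the genotyped-and-phenotyped material (the training set), then rank
unphenotyped candidates by their genomic estimated breeding values (GEBVs).

`tetragebv` implements the full analysis chain needed to evaluate that
promise in a small breeding program: tetraploid dosage QC, population
structure, a Bayesian Ridge Regression (BRR) sampler producing GEBVs,
entry-mean broad-sense heritability from multi-location trials, and three
accuracy-evaluation designs (cross-generation, cross-family, repeated
k-fold cross-validation). Because the interesting failure modes — limited
genetic overlap between generations, strong family structure, selection on
phenotype — are properties of the population, the package also ships a
simulator of a finite-size autotetraploid breeding program so every stage
is testable end to end without external data.

## The simulator

### Tetrasomic meiosis

Each genotype carries four allele copies per biallelic locus; its dosage is
the count of the alternate allele, 0–4. A gamete receives, per locus and
independently across loci,

* with probability $1-\alpha$: two of the four copies drawn without
  replacement (random chromatid segregation — all six unordered pairs
  equally likely);
* with probability $\alpha$: one copy drawn uniformly and duplicated
  (double reduction).

$\alpha$ is bounded by $1/6$, the theoretical maximum under random
chromatid segregation. Two consequences are used as test oracles: a duplex
(AAOO) parent produces AA gametes with frequency $1/6$ at $\alpha = 0$, and
a simplex (AOOO) parent produces AA gametes with frequency exactly
$\alpha/4$ — at $\alpha = 0$ a simplex parent can never produce an AA
gamete, which is an exact, not statistical, property.

Loci are simulated without linkage. The downstream analysis never uses map
positions, so linkage would add cost and complexity without touching any
quantity the package computes; chromosome labels are carried only to make
output files realistic.

### Program structure

The default configuration (`sim_config()`) reproduces the structure of a
small public potato program: five bi-parental T1 full-sib families of sizes
51, 51, 149, 152, 62 (465 unselected seedlings) with overlapping parents —
three of the five female parents are themselves full sibs from one
grandparental cross, and four named parents/grandparents are genotyped
alongside the offspring; a once-selected T2 cohort of 138; a multi-cycle
selected T3–7 cohort of 62; and five check cultivars planted at every
location. Founder allele frequencies are drawn Uniform(0.1, 0.9) so that
the marker panel surviving the MAF filter is stable across seeds.

Selection is not specified by any published rule, so the simulator uses
truncation selection on a single unreplicated seedling phenotype (genetic
value plus residual noise), emulating visual field selection. The selected
fraction defaults to 0.3, chosen to match the ratio of the T2 cohort to the
T1 cohort (138/465 ≈ 0.30). The default double-reduction rate is
$\alpha = 0.05$: positionally averaged rates reported for potato lie
between 0 (centromeric loci) and the 1/6 ceiling (telomeric loci), and a
small positive value keeps the phenomenon present without dominating
segregation. The default marker count is 2,000 — dense enough that GEBV
accuracy is relationship-limited rather than marker-limited in populations
of this size; study-scale panels (>10k) can be configured.

### Phenotypes

Plot records follow the random-effects trial model

$$y_{ijk} = \mu + g_i + l_j + (gl)_{ij} + \varepsilon_{ijk}$$

with independent normal location, genotype-by-location and residual
effects. Genetic values are additive in dosage, $g = X\beta$, with the
marker-effect vector rescaled so the unselected T1 cohort has genetic
variance $\sigma^2_g$ exactly. Default components (1, 0.5, 0.5, 1 for
$\sigma^2_g, \sigma^2_{loc}, \sigma^2_{g\times e}, \sigma^2_E$) give an
entry-mean heritability of about 0.7 in the default 3-location, 2-replicate
design — typical of the better-behaved tuber traits.

What the simulator deliberately does not emulate: linkage and LD decay,
dominance and epistasis (the genetic value is purely additive in dosage, as
is the prediction model), genotyping error, shared micro-environment within
field rows, and unbalanced trait availability across generations. Passing
tests therefore demonstrate internal correctness of the statistical
machinery under the stated model, not robustness to those real-data
features.

## Marker QC

The QC order is fixed and mirrors standard dosage-array practice:

1. **Missingness filter** — markers with strictly more than 10% missing
   calls are removed.
2. **Population-mode imputation** — each remaining missing call is replaced
   by the marker's most frequent dosage class; ties break deterministically
   to the lowest dosage.
3. **MAF filter** — markers with minor allele frequency strictly below 0.05
   are removed.

Allele frequency at a tetraploid marker is dosage-weighted:
$p = \sum_i x_i / (4 n)$ over non-missing calls, and MAF $= \min(p, 1-p)$.
Frequencies are computed on exactly the sample set passed in, so
subsetting samples changes the retained panel — this is intentional and
reproduces the behaviour of per-subset marker counts in real analyses.
The pipeline is idempotent and its report counts balance exactly
(`markers_in = removed_missingness + removed_maf + markers_out`).
Duplicate-sample concordance (`pairwise_difference`) is the fraction of
jointly observed markers with unequal calls: technical duplicates should
differ at well under 0.5% of markers, unrelated clones at around 50%.

## Population structure

Genetic distances are plain Euclidean distances between dosage vectors, and
`pcoa()` is classical metric scaling: double-center $-D^2/2$,
eigendecompose, scale eigenvectors by the square roots of their
eigenvalues. For exact Euclidean input this equals centered PCA of the
dosage matrix, which is the package's cross-check oracle. Percent variance
per axis is computed over positive eigenvalues only; numerically negative
eigenvalues are excluded from the denominator and reported. Axis signs are
fixed by making each axis's largest-magnitude coordinate positive so output
is reproducible across BLAS implementations.

## Phenotype processing

* **ATW** (average tuber weight) is derived per plot as TW/TN; plots with
  zero tubers yield missing ATW with a warning.
* **Location adjustment** is additive centering on check-cultivar means:
  each record is shifted by its location's check-mean deviation from the
  unweighted grand mean of the per-location check means. Additive rather
  than multiplicative adjustment was chosen because it preserves trait
  units and within-location contrasts exactly, and has no degenerate case
  at zero-valued checks. Late-blight scores are not adjusted: they are
  recorded per plant in a single trial.
* **AUDPC** integrates repeated disease severity scores by the trapezoidal
  rule, in score·days; it is additive over adjacent intervals and monotone
  in every single score.

## The Bayesian Ridge Regression model

GEBVs come from the whole-genome regression

$$y = 1\mu + X\beta + e, \qquad \beta \sim N(0, \sigma^2_\beta I), \qquad
e \sim N(0, \sigma^2_e I),$$

where $X$ holds raw allele dosages $x_{ij} \in \{0,\dots,4\}$. All marker
effects share one shrinkage variance, which makes the model equivalent to
GBLUP with genomic relationship $X_c X_c' \sigma^2_\beta$ — an equivalence
the test suite verifies to $10^{-6}$ via the closed-form fixed-variance
limit (`blup_marker_effects`).

The Gibbs sampler (C++, single-site updates with running residuals, so one
sweep is $O(np)$) updates $\mu$, each $\beta_j$, then
$\sigma^2_\beta \mid \beta \sim$ scaled-inv-$\chi^2(\nu_\beta + p,
(\sum_j\beta_j^2 + \nu_\beta S_\beta)/(\nu_\beta + p))$ and
$\sigma^2_e$ analogously from the residuals. Hyperpriors default to
$\nu = 5$ for both variances with scales solved from a prior variance
split $R^2 = 0.5$:
$S_\beta = R^2\,\mathrm{var}(y)\,(\nu_\beta+2)/(\nu_\beta \sum_j
\mathrm{var}(x_j))$ and
$S_e = (1-R^2)\,\mathrm{var}(y)\,(\nu_e+2)/\nu_e$ — the convention of the
widely used Bayesian whole-genome regression software, so defaults behave
the way practitioners expect. Columns of $X$ are mean-centered internally
(the intercept absorbs the shift; GEBV contrasts are unchanged), there is
no thinning, and all draws go through R's RNG so a seed reproduces a fit
bit-identically.

Defaults are 45,000 iterations with 15,000 burn-in. Tests and the
pipeline run reduced chains (typically 3,000/1,000): for point predictions
of GEBVs the posterior mean stabilises long before the variance chains are
publication-quality, and the test-suite oracles compare against
Monte-Carlo standard errors, which makes the chain length explicit in
every assertion. Training always excludes test individuals from the
likelihood entirely; they are predicted afterwards as
$\hat g = X_{c,\text{new}}\hat\beta\,(+\,\hat\mu)$, which matches the
missing-response treatment of the reference software for point prediction.

## Heritability

Variance components for the multi-location model
`y ~ genotype + location + genotype:location + replicate%in%location + e`
(all random, fixed intercept) are estimated by the EM form of REML, with
per-iteration updates
$\sigma_k^2 \leftarrow \sigma_k^2 + \sigma_k^4/q_k\,
(y'PZ_kZ_k'Py - \mathrm{tr}(Z_k'PZ_k))$, which are non-negative by
construction. Convergence is declared at a maximum relative change of
$10^{-8}$ (cap 500 iterations). EM approaches the zero boundary only
hyperbolically, so a component that is persistently pushed below
$5\times10^{-3}\,\mathrm{var}(y)$ with a negative REML score is clamped to
zero rather than crawled toward it; on balanced interior data the
estimates match the ANOVA (expected-mean-squares) solution to $10^{-6}$,
and on unbalanced data they match an independent REML implementation
(`lme4`). EM was preferred over average-information updates for
robustness on very small trials (tens of genotypes), where AI steps
routinely overshoot the parameter space.

Broad-sense heritability is reported on the entry-mean basis

$$H^2 = \frac{\sigma^2_g}
{\sigma^2_g + \sigma^2_{g\times e}/Hm_1 + \sigma^2_E/Hm_2},$$

with $Hm_1$ the harmonic mean of replicates per genotype-by-location cell
and $Hm_2$ the harmonic mean of total replicates per genotype. The
denominator divides (rather than multiplies) by the harmonic means: that
is the standard entry-mean form, and dividing is the only reading under
which $H^2$ increases with replication, as it must.

## Accuracy evaluation

Prediction accuracy is the Pearson correlation between observed
(location-adjusted genotype means) and predicted values. Three designs are
provided:

* **Cross-generation** (`split_by_generation` + `cross_generation_eval`):
  deterministic partitions by clonal generation, training on the later
  cycles; the four parents/grandparents can be appended to the training
  set to increase genetic overlap.
* **Cross-family** (`cross_family_eval`): train on one full-sib family,
  predict the other, both directions reported. The marker panel can be
  re-filtered by MAF within the two families' own samples, mirroring
  subset-specific panels.
* **Repeated k-fold CV** (`kfold_cv`): per replicate, a fresh random
  partition into five near-equal folds; every individual is predicted by a
  model trained on the other folds, and one correlation is computed on the
  assembled prediction vector (not per fold and then averaged — the
  assembled-vector convention follows from predicting "until all
  individuals have a value" and is the documented choice here). The mean
  and standard deviation over replicates are reported.

Negative accuracies are reported as-is and flagged "not predictable", never
clipped: a negative mean correlation is the honest summary of a trait the
training set cannot predict.

## Numerical and design choices, in brief

* Mode-imputation ties break to the lowest dosage (deterministic).
* Filter thresholds are strict inequalities ("more than 10%", "smaller
  than 0.05").
* PCoA axis signs are fixed by the largest-magnitude loading.
* One top-level seed drives the pipeline; per-stage seeds are derived from
  it by a seeded draw, so any stage can be reproduced in isolation.
* The EM-REML boundary clamp is the one deliberate deviation from textbook
  EM; without it, null components (e.g. a replicate term fitted to data
  that has none) stall the iteration without affecting the estimand.

## Problem sizes used in the test suite

The suite exercises every oracle at desk scale, chosen so the full run
stays in the tens of minutes: the gamete laws at 50,000 draws; the
fixed-variance Gibbs-vs-ridge oracle at 150 samples x 200 markers with
8,000 iterations; heritability recovery over 200 simulated 38-genotype,
3-location, 1–2-replicate trials; and the null-calibration check as 100
replicates of permuted-phenotype 5-fold CV at 120 x 150 with 3,000-sweep
chains. The same computations, at the same sizes, are what
`scripts/acceptance.R` re-runs from scratch.

## Known limitations

* The simulator's selection rule (truncation on a single noisy plot) is a
  stand-in; real visual selection is multi-trait and spatially correlated.
* The additive-dosage genetic model ignores digenic and higher-order
  intra-locus effects, which are believed to matter for tetraploid yield
  traits; both the simulator and the predictor share this assumption, so
  cross-validated accuracy here cannot reveal it.
* EM-REML reports no standard errors for components.
* `pcoa` forms the full distance matrix in memory; it is intended for
  hundreds to a few thousand samples, not biobank scale.
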