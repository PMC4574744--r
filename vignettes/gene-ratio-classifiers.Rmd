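---
title: "Gene-ratio classifiers of drug sensitivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-ratio classifiers of drug sensitivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grepredict)
```

## The problem

Single-gene expression thresholds are fragile biomarkers: a cutoff learned
on one platform (say, MAS5-normalized microarrays) rarely survives
translation to another platform or model system, because absolute
intensities carry sample- and platform-specific scale. Ratios of two genes
measured in the same sample cancel that scale exactly, and often reflect
the biology directly — a death receptor's signal relative to its inhibitor
matters more than either level alone.

`grepredict` implements GREP (Gene Ratio Expression Prediction): a
pipeline that builds a logistic classifier of drug sensitivity from
pairwise gene-expression log-ratios, together with the screen-processing
rules that produce its training labels and the interpretation layer that
reads the fitted model back as a regulatory network.

## From raw screens to labels

Dose-response curves are summarized by a variable-slope sigmoid with the
lower plateau fixed at 0% inhibition,

$$y(d) = \frac{A_{max}}{1 + (EC_{50}/d)^{h}},$$

fit by Levenberg-Marquardt least squares with multi-start initialization
from data quantiles (`fit_dose_response()`). $A_{max}$ is the fitted upper
plateau (% inhibition: 0 = untreated growth, 100 = total kill), $EC_{50}$
the inflection dose at half-$A_{max}$, and $IC_{50}$ the dose where the
fitted curve crosses 50% inhibition — set to the maximum tested dose when
$A_{max} < 50$, since the curve never reaches half-kill in the tested
range. Sensitivity calls use closed boundaries: $A_{max} \ge 70$ sensitive,
$\le 50$ insensitive, the open interval between intermediate. Replicate
inhibition values are averaged per dose before fitting (configurable);
fitting before averaging gives nearly identical plateaus for the noise
levels we simulate, and averaging first is the cheaper, more stable
default.

Per-screen calls are aggregated per cell line by strict majority vote
(`consensus_call()`). A tie among distinct calls — including the two-screen
sensitive/insensitive pattern, and the one-of-each three-screen pattern —
is a `conflict`; intermediate votes as its own class. Conflicting and
intermediate lines are removed downstream, before modeling, not inside the
vote. Lineage enrichment of sensitivity and of insensitivity is tested by
one-sided Fisher's exact tests in each direction separately, on lineages
with at least 10 lines.

In vivo, anti-tumor activity uses the treated/control tumor-volume changes
$\Delta T = T_{final} - T_{initial}$ and $\Delta C$: %T/C $= 100\,\Delta
T/\Delta C$ when the treated arm grew, %Regression $= 100\,\Delta
T/T_{initial}$ when it shrank; a model responds on stasis (%T/C < 10) or
regression (%REG < 10).

## The GREP pipeline

1. **Gene filtering** (`filter_genes()`): drop genes with 75th percentile
   < 250 or IQR < 500 across the training samples. Quantiles interpolate
   linearly between order statistics (R type 7) — the convention matters
   because the 75th-percentile rule can sit exactly on a threshold at
   small n, so it is declared rather than left implicit. Filters run
   inside each cross-validation training fold, never on pooled data, to
   avoid leakage.
2. **Ratio features** (`compute_log_ratios()`): for every unordered pair
   of hypothesis genes, $v = \log\frac{x_{num}+c}{x_{den}+c}$ (natural
   log; the base only rescales coefficients). The pseudocount $c$ damps
   ratio artifacts at low expression; its default 32 sits near the noise
   floor of MAS5-like data and well below the baseline of 150. $c = 0$
   makes features exactly scale-invariant. The quotient is taken before
   the log so that a power-of-two rescaling of a sample leaves the feature
   bit-identical; arbitrary rescalings agree to floating-point rounding
   (~1e-15), which is the best any log implementation can do.
3. **Association** (`ratio_t_stats()`, `permutation_significance()`):
   two-sample t statistics (Welch by default; the pooled-variance form is
   an option), signed so positive means ratio-high-in-sensitives.
   Significance comes from 100 joint label permutations — permuting labels,
   not features, preserves the strong correlation among ratios that share
   genes. Per-feature p-values use +1 smoothing, so the smallest attainable
   p is 1/101; a pooled counting mode borrows resolution across the family.
   q-values follow the permutation plug-in: expected null exceedances over
   observed exceedances at each |t|, clipped to [0, 1] and made monotone.
4. **Exemplar clustering** (`affinity_propagation()`,
   `cluster_exemplars()`): ratios passing FDR < 0.1 are re-oriented
   positive and clustered by affinity propagation on their Pearson
   correlation; damping 0.9, up to 1000 iterations, convergence declared
   after 50 iterations of an unchanged exemplar set. The generic
   `affinity_propagation()` keeps the algorithm's standard preference
   default (median off-diagonal similarity), but the *pipeline* sets the
   preference to a fixed correlation floor of 0.5. The distinction
   matters: clustering exists here to deduplicate highly correlated
   ratios, and the median default is relative — on a small significant
   set of weakly correlated ratios (say five informative ratios at
   r ≈ 0.26) it happily merges them and throws information away, which
   measurably costs cross-validated AUC. A floor of 0.5 says "ratios
   sharing less than a quarter of their variance are distinct evidence";
   below it they stay separate, above it they merge. The reference
   algorithm breaks degeneracies with random jitter; we instead subtract a
   vanishing, index-ordered perturbation from the preferences, which makes
   clustering deterministic and resolves exact ties toward the
   lower-indexed feature. Non-convergence falls back to all-singletons
   (no merging — conservative) and is flagged.
5. **Classification**: one exemplar per cluster enters a ridge-penalized
   logistic regression (Newton/IRLS, penalty $\tfrac{\lambda}{2}\lVert
   \beta\rVert^2$ on slopes, default $\lambda = 1$). The light penalty
   keeps coefficients finite when a handful of exemplars separates a small
   training set perfectly; $\lambda = 0$ is available with separation
   detection. Sensitive is called at probability > 0.5.

Cross-validation (`cross_validate()`) refits *every* stage — filtering,
selection, clustering, regression — inside each of 5 stratified folds and
reports only pooled out-of-fold metrics. Stratification is not optional at
23% prevalence: unstratified folds can lose an entire class. A fitted
model is applied to new expression values as-is, with no rescaling — the
point of ratio features is that this is safe across platforms.

## Baselines and ablations

`ablation_suite()` compares GREP against four comparators on shared folds,
each swapping exactly one stage: a standard single-gene classifier over
all genes; the same over the hypothesis genes; a hybrid that selects
features as ratios but classifies on the component genes' log expression;
and a two-gene median rule. The single-gene variants reuse the identical
selection/clustering/regression machinery with $\log(x+c)$ features, so
differences are attributable to the feature space alone. The two-gene rule
calls sensitive when both genes sit strictly above their training medians;
its ranking score is $\min(x_a - m_a,\; x_b - m_b)$ — a reconstruction, as
a median rule has no native continuous score; it crosses zero exactly at
the decision boundary. Its genes are chosen data-driven as the top two by
differential expression in the training fold.

## The synthetic generator

`generate_expression()` emulates the structure the method assumes, not any
real cohort: log-normal expression, labels at 23% prevalence, and
`n_true_ratios` planted gene pairs whose class-conditional mean log-ratio
differs by `effect_size * noise_sd` (numerator up, denominator down in
sensitives). Two further mechanisms make the planted structure behave the
way the method's premise says real regulator/inhibitor pairs behave.
First, the two genes of a planted pair are strongly *co-regulated*: they
share a latent log-normal factor (`pair_coupling_sd`, default 3 log
units — order-of-magnitude co-variation, as receptor expression shows
across a pan-cancer panel). The factor cancels exactly in the planted
ratio but inflates the variance of any ratio pairing a planted gene with
an unrelated partner, so the planted pair is the *identifiable* feature:
it carries the top t statistic while its one-gene-shared neighbours are
diluted out of significance. Without this coupling, every cross-pair of
planted genes is statistically equivalent to a planted pair and exact
recovery of the planted list is impossible in principle. Second,
per-sample multiplicative scale factors (log-uniform over
`per_sample_scale_range`) are applied to all genes of a sample. Together
they confound absolute levels while leaving ratios clean — making
"ratios beat genes" a designed, testable property rather than an anecdote.
The `baseline` parameter (150, linear scale) acts as the platform floor;
gene mean intensities are drawn log-normally at multiples of it (hypothesis
genes somewhat higher, as curated pathway genes typically are) so that a
realistic fraction of genes passes the 250/500 filters — a matrix centered
literally at the floor would be filtered away entirely. What the generator
does *not* emulate: real co-expression structure, lineage composition,
RNA-seq count noise. Passing tests therefore demonstrate algorithmic
correctness and calibration, not clinical performance.

`generate_screens()` draws per-line sigmoid curves whose plateau falls in
the band of the line's label (sensitive 75–95, intermediate 55–65,
insensitive 15–45, all safely clear of the 70/50 boundaries), with an
explicit `concordance_noise` flip rate; curve-point noise defaults to 0 so
the zero-noise label round-trip is exact by design. The default dose grid
is 11 points in 2.5-fold dilutions from 20 nM.

## Validation design and problem sizes

The package validates itself on three synthetic regimes, chosen once:

- **Null calibration**: 64 label-independent hypothesis genes (2016
  ratios), n = 200 at 23% prevalence, 100 permutations, 20 seeds.
  Permutation p-values pooled across seeds are uniform; q < 0.1 selections
  are rare (median 0 per run — ratios sharing a gene can clump in a tail,
  so single runs occasionally select a correlated handful); and the
  *distribution* of null cross-validated AUCs is centered at 0.5 with mean
  inside [0.42, 0.58]. Calibration is a distributional property over
  replicates: any single null replicate can stray, and the suite asserts
  the aggregate.
- **Planted recovery**: n = 400, 300 genes, 60 hypothesis genes, 5 planted
  ratios at effect size 2, 10 seeds: planted pairs (or exemplars
  correlated ≥ 0.9 with them) are recovered, out-of-fold AUC exceeds 0.90
  per seed, and leave-one-gene-out importance localizes to the planted
  genes. Importance uses fixed fold partitions (deltas reflect gene
  removal, not fold noise) and three CV repetitions; the z score is the
  mean paired fold-level AUC delta over its standard error, so a gene is
  flagged when its removal consistently costs accuracy.
- **Ablation contrast**: a confounded dataset where only ratios carry
  signal (pair co-regulation plus per-sample scale factors bury the
  single-gene effects), and an unconfounded dataset with one dominant
  marker gene (4 SD log effect, no scale factors) where both feature
  spaces saturate. With a *moderate* single-gene marker the exemplar step
  condenses the redundant marker/x ratio cluster to a single
  representative and pays a denominator-noise penalty of up to ~0.1 AUC —
  a real limitation of exemplar condensation, worth knowing when the
  signal is univariate.

These sizes keep the full suite within a desktop-scale run while giving
each statistical assertion comfortable margins.

## Known limitations

- The permutation q-value estimator is anticonservative under the strong
  dependence of ratio families in small feature sets; the 100-permutation
  resolution floors per-feature p-values at 1/101.
- Affinity propagation's cluster count depends on the preference; the
  median-similarity default is standard but not tuned per dataset.
- The two-gene rule's AUC depends on the reconstructed score; other
  monotone surrogates would give slightly different rankings.
- Probability calibration (Platt/isotonic) is out of scope; probabilities
  are raw logistic outputs.

## A minimal run

```{r example, eval = FALSE}
d <- generate_expression(synthetic_config(seed = 1))
cfg <- grep_config(seed = 1)
cv <- cross_validate(d$X, d$labels, d$hypothesis_genes, cfg)
cv
model <- fit_grep(d$X, d$labels, d$hypothesis_genes, cfg)
net <- build_ratio_network(model$significant[model$significant$t > 0, ],
                           model$pairs)
net
```
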