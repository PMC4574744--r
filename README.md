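# grepredict

Gene Ratio Expression Prediction (GREP) of drug sensitivity: classifiers
built from pairwise gene-expression log-ratios rather than absolute
expression levels.

## Why ratios

Expression-threshold biomarkers rarely translate: a cutoff tuned on one
platform or model system drifts with per-sample and per-platform scale.
The ratio of two genes measured in the same sample cancels that scale
exactly, and often *is* the biology — a death receptor's level relative to
its negative regulator predicts apoptotic response better than either
level alone. GREP turns this into a pipeline for anyone building
drug-response classifiers from pharmacologic screens of cell-line panels:

1. **Labels from screens** — each dose-response curve is summarized by a
   variable-slope sigmoid $y(d) = A_{max} / (1 + (EC_{50}/d)^h)$;
   sensitivity is called from the fitted plateau ($A_{max} \ge 70$%
   sensitive, $\le 50$% insensitive, in between intermediate) and
   per-screen calls are merged by strict majority vote.
2. **Features** — for a hypothesis gene set, all pairwise log-ratios
   $\log\frac{x_{num}+c}{x_{den}+c}$ (pseudocount $c = 32$ by default).
3. **Selection** — two-sample t statistics against the labels, with
   p/q-values from 100 joint label permutations (inter-gene correlation
   preserved); ratios with q < 0.1 are kept and oriented positive.
4. **Condensation** — affinity propagation clusters correlated ratios;
   one exemplar per cluster survives.
5. **Classification** — ridge-penalized logistic regression on the
   exemplars; sensitive at probability > 0.5; all stages refit inside
   each fold of stratified 5-fold cross-validation.

The fitted model applies to new expression matrices *without any
rescaling* — the package's invariance tests show predictions are exactly
unchanged under per-sample rescaling at $c = 0$ and perturbed by < 0.05
probability for two-fold scale swings at realistic expression levels.

Also included: baseline comparators (single-gene pipelines, a two-gene
median rule) and ablations, a ratio-network/leave-one-gene-out
interpretation layer, xenograft %T/C and %Regression response calls,
lineage enrichment by Fisher's exact test, and a synthetic-data generator
with planted ratio structure that makes every claim above testable
offline.

## Worked example

```r
library(grepredict)

d   <- generate_expression(synthetic_config(seed = 1))  # 300 genes x 400 samples,
                                                        # 5 planted ratios, 23% sensitive
cfg <- grep_config(seed = 1)

cv <- cross_validate(d$X, d$labels, d$hypothesis_genes, cfg)
cv
#> GREP cross-validation: 400 samples, 5 folds
#>   pooled out-of-fold AUC = 0.974, PPV = 0.911, recall = 0.818

model <- fit_grep(d$X, d$labels, d$hypothesis_genes, cfg)
model
#> GREP model: 11 exemplar ratio(s), pseudocount 32, threshold 0.5
#>          ratio      coef
#> 1  G0019/G0049 2.0508779
#> 2  G0045/G0004 1.5737002
#> 3  G0023/G0039 1.5242892
#> ...

net <- build_ratio_network(model$significant[model$significant$t > 0, ],
                           model$pairs)
net
#> ratio network: 60 genes, 75 oriented ratios (11 in model)
```

The out-of-fold AUC (0.974) and PPV (0.911) say the classifier ranks and
calls unseen samples almost perfectly on this planted-signal dataset; the
exemplar table lists the oriented ratios (numerator up in sensitives) with
their logistic coefficients, and all five planted pairs of this simulation
(`d$truth`) appear among the exemplars. The network view summarizes each
gene's degree and positivity (fraction of its ratios where it is the
numerator): positivity near 1 marks a positive regulator of response, near
0 a negative one.

A thin command-line front end over the same functions lives in
`inst/cli/grep_cli.R` (`simulate`, `fit`, `predict`, `cv` subcommands).

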