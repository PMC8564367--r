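# episelect

Interaction-based genetic risk modelling for case/control cohorts:
a prior-knowledge-graph-guided search for epistatic genotype
combinations, benchmarked against the clumping+thresholding polygenic
risk score it aims to beat.

## The problem

A polygenic risk score (PRS) is a weighted allele count,
`PRS_i = Σ_j β̂_j g_ij`, with weights from a genome-wide association
scan — an additive model that cannot represent epistasis, where the
effect of a genotype *combination* (say, heterozygous at two specific
variants) deviates from the sum of the marginal effects. Testing all
genotype-exact combinations is statistically hopeless at cohort scale,
so `episelect` constrains the search with a prior knowledge graph over
variants, genes and pathways: variant sets that are biologically
connected are proposed preferentially, every proposed hypothesis
(a conjunction of exact genotype conditions) is scored by the deviance
improvement of `phenotype ~ carrier-indicator`, strong hypotheses are
refined by local edits, and variant sampling propensities receive
multiplicative-weights updates so productive graph regions are explored
more. After convergence, fewer than 100 hypotheses survive; a
multiplicity-adjusted Fisher screen removes selection optimism and an
L1-penalized logistic regression (`glmnet`) over the surviving
indicator features gives the final model, evaluated on a held-out test
set with bootstrap AUC confidence intervals and a Youden-optimal
operating point.

The package is aimed at statistical geneticists who want a desk-scale,
fully reproducible implementation of this idea — including the QC
pipeline (missingness, autosome, two-stage Hardy–Weinberg exact test,
LD pruning, heterozygosity, IBD relatedness), PLINK/VCF input, the PRS
baseline, and a synthetic-data generator with planted interactions and
a partially informative prior graph for calibration and power studies.

## Worked example

Simulate a 436-sample cohort (120 variants in LD blocks) whose disease
architecture is purely epistatic — one planted heterozygote/heterozygote
two-variant interaction whose carriers reach 95% case probability —
with a prior graph that links the interacting pair through a shared
gene node, then run the whole pipeline on a 367/33/36
train/validation/test split:

```r
library(episelect)

sim <- simulate_study(preset_config("epistatic_ppmi_like", seed = 7))
sim$dataset
#> <genotype_dataset> 436 samples (281 cases / 155 controls) x 120 variants; 1.00% missing
sim$graph
#> <prior_graph> 129 nodes (gene: 9, variant: 120); 32 edges

out <- run_pipeline(sim$dataset, sim$graph, seed = 7, n_boot = 10000)

out$prs_model
#> <prs_model> threshold 0.4: 52 variants; validation AUC 0.587
out$prs_eval
#> <eval_report> AUC 0.515 [0.309; 0.718] | acc 0.53 sens 0.39 spec 0.77 | J 0.16
```

The additive baseline finds nothing real: its test AUC interval spans
one half. The interaction search, in contrast, converges after 16
rounds (2319 hypotheses scored), and its top-scoring hypothesis is the
planted combination:

```r
head(as.data.frame(out$selected)[, c("id", "carriers", "fit_score")], 3)
#>                              id carriers fit_score
#> 1           snp0015:1;snp0085:1       70      41.6
#> 2 snp0015:1;snp0054:1;snp0085:1       34      31.6
#> 3 snp0015:1;snp0039:1;snp0085:1       32      29.6

nrow(out$screened)       # hypotheses surviving the Fisher/Bonferroni screen
#> [1] 6
coefficient_report(out$model, out$selected)[, c("id", "coefficient", "direction")]
#>                              id coefficient direction
#> 1 snp0015:1;snp0054:1;snp0085:1       1.241      risk
#> 2 snp0015:1;snp0039:1;snp0085:1       1.172      risk
#> 3 snp0015:1;snp0085:1;snp0087:1       1.099      risk
#> 4 snp0015:1;snp0085:1;snp0100:0       0.933      risk
#> 5 snp0015:1;snp0037:1;snp0085:1       0.615      risk
#> 6           snp0015:1;snp0085:1       0.263      risk

out$model_eval
#> <eval_report> AUC 0.587 [0.521; 0.673] | acc 0.47 sens 0.17 spec 1.00 | J 0.17
recovered_interaction(out$selected, sim$truth$interactions[[1]])
#> [1] TRUE
```

Every nonzero model term contains the planted pair `snp0015:1;snp0085:1`
(the `vid:genotype` notation means "heterozygous at both variants"),
all terms are risk-directed, and the interaction model's test AUC beats
the PRS baseline's. Genotype-combination contingency tables in the
style of a case/control stratification — how the carriers of each
combination split into cases and controls — come from `combo_table()`;
`write_plink()`, `write_prior_graph()` and `end_to_end_fixture()`
export everything as PLINK bed/bim/fam plus a graph TSV and a truth
JSON.

A thin command-line front end over the same functions lives at
`inst/cli/episelect.R` (`simulate`, `convert`, `merge`, `qc`, `gwas`,
`prs`, `select`, `fit`, `eval`).

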