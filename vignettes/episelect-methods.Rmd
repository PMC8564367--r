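---
title: "Interaction-based feature selection for case/control genotype data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-based feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(episelect)
```

## The problem

Polygenic risk scores (PRS) model disease liability as a weighted sum of
single-variant allele dosages and therefore cannot represent epistasis —
joint effects of genotype *combinations* that deviate from the sum of the
marginal effects. Searching for such combinations naively is hopeless at
cohort scale: with $m$ variants and genotype-exact conditions there are
$\binom{m}{2}\cdot 3^2$ two-variant hypotheses alone, and case/control
cohorts of a few hundred subjects cannot support that multiplicity.

`episelect` implements the alternative explored here: use a prior
knowledge graph over variants, genes and pathways to concentrate the
search on biologically connected variant sets, score each proposed
genotype-combination hypothesis with a simple likelihood-ratio measure,
let the graph *learn* which regions of hypothesis space are productive,
and hand the surviving (< 100) hypotheses to an L1-penalized logistic
model. The package also provides everything around that core: genotype
I/O and merging, the QC pipeline, a per-variant association scan, the
clumping+thresholding PRS baseline it is compared against, held-out
evaluation with bootstrap confidence intervals, and a synthetic-data
generator with planted interactions that serves as the test bed.

## Data model

A `genotype_dataset` is a samples × variants matrix of alternative-allele
dosages (0/1/2, `NA` missing) with variant metadata (chrom, pos, id,
ref/alt) and a binary phenotype (1 = case). Dosage counts the
alternative allele everywhere — the bim A1 column on PLINK input — and
this coding is shared by the scan, the PRS and the hypothesis encoder,
so effect signs are comparable across modules.

A `prior_graph` is an undirected weighted graph over nodes of kind
`variant`, `gene` or `pathway`. Variant nodes that match the dataset
carry a positive *sampling propensity* — the search's mutable state.
Two variants are "neighbors" when they are connected within two edges
(variant–gene–variant or variant–pathway–variant).

## Quality control

Steps run in a fixed order: missingness (variants before samples, both
at fraction 0.02 by default), autosome restriction, Hardy–Weinberg
filtering, LD pruning (to obtain a near-independent marker set),
heterozygosity-rate outliers, and relatedness.

* **HWE exact test.** The conditional-on-allele-counts exact test: all
  heterozygote counts compatible with the observed allele totals are
  enumerated through a two-sided recurrence from the mode, and the
  p-value sums the probabilities no larger than the observed count's. No
  mid-p correction (the canonical published formulation). Filtering is
  two-stage: p < 1e-6 in controls only, then p < 1e-10 in all samples —
  genotyping artefacts inflate HWE deviation in controls, whereas strong
  true associations deviate in cases.
* **LD pruning.** Sliding windows of 50 variants, step 5, within
  chromosome. While any surviving pair in a window has squared genotype
  correlation above 0.2, the pair found first in map order loses its
  lower-MAF member (tie: the later variant). Monomorphic variants have
  undefined correlation and are always kept.
* **Heterozygosity.** Per-sample rate = heterozygous calls / non-missing
  calls over the pruned set; one-pass mean/SD; |z| > 3 removed. The
  mean/SD are not recomputed after exclusions.
* **Relatedness.** Method-of-moments IBS→IBD per pair:
  $\hat Z_0 = N_{IBS0}/E[N_{IBS0}\,|\,IBD{=}0]$ and so on, with
  PI_HAT $= Z_1/2 + Z_2$. Because allele frequencies come from the same
  sample, the IBS expectations use unbiased estimators of the
  allele-probability products (falling-factorial ratios of allele
  counts); plug-in frequencies visibly inflate PI_HAT at small n.
  Even so, $\hat Z$ clamping at 0 leaves a noise floor of a few
  hundredths of PI_HAT when only hundreds of markers are available —
  relatedness filtering is meaningful from roughly a thousand pruned
  markers upward, and the tests use ≥ 1500. Of a flagged pair, the
  member with the higher missingness is removed (tie: later sample).

A `qc_report` logs per-step removals; the totals reconcile exactly with
the dimension change. The pipeline is idempotent away from threshold
boundaries; near a boundary, removing samples changes a variant's
missing-fraction denominator and can push it across the cut — an
integer-discreteness effect inherent to the step ordering, not a bug.

## Association scan and PRS baseline

The scan fits `phenotype ~ dosage` per variant by logistic regression
and reports the Wald test. Monomorphic variants and non-converged or
separated fits yield flagged `NA` rows. No covariates by default (a
covariate matrix hook exists); no mixed-model machinery — the package
targets unrelated desk-scale cohorts.

The PRS baseline is clumping + thresholding: greedy clumping keeps the
best remaining p-value as an index and discards same-chromosome
variants within 250 kb with r² > 0.1 to it; significance gates are
disabled because the threshold grid (0.001, 0.05, 0.1, 0.2, 0.4, 0.5)
does the filtering. Each threshold's score is
$\mathrm{PRS}_i = \sum_j \hat\beta_j \, g_{ij}$ with missing dosages
imputed at twice the scoring dataset's effect-allele frequency
(self-contained scoring). A one-feature logistic calibration is fitted
on the training split, and the threshold with the highest validation
AUC wins (ties → smaller threshold).

## The hypothesis search

A *hypothesis* is a conjunction of exact genotype conditions,
`vid:genotype` pairs over distinct variants (order 1–4 by default); its
canonical id is the sorted condition list. A sample is a *carrier* iff
every condition matches a non-missing genotype. Hypothesis quality is
the likelihood-ratio improvement of `phenotype ~ carrier-indicator`:
`fit_score = null deviance − residual deviance`, asymptotically
$\chi^2_1$ under the null — so scores are comparable across hypotheses
and rounds. Hypotheses with fewer than `min_carriers` (default 5)
carriers or non-carriers are degenerate and score 0, which keeps
perfect-separation artifacts from dominating.

Each round:

1. **Propose** `n_per_round` (45) unseen hypotheses. Order is drawn with
   weights (0.35, 0.4, 0.15, 0.1) — low orders carry the marginal signal
   that seeds refinement. The first variant is drawn proportional to
   propensity; each co-member comes from the graph neighborhood of the
   variants already chosen with probability ρ = 0.9 (propensity-weighted
   within the pool), otherwise from all variants. Genotype conditions
   are drawn uniformly from the genotypes observed at least
   `min_carriers` times.
2. **Score** the batch; archive every score under its canonical id (an
   id is never rescored).
3. **Refine** the best-scoring archived hypotheses not yet expanded
   (budget: 25% of the round size). Refinement enumerates the
   edit-distance-1 neighborhood — change one genotype, swap one variant
   for a graph neighbor, drop one condition, add one condition on a
   graph neighbor — and scores up to `refine_k` (20) unseen neighbors.
   Because refinement draws from the archive, a good hypothesis found by
   an earlier refinement keeps climbing in later rounds.
4. **Update propensities** multiplicatively: for each variant `v`,
   `propensity_v ← propensity_v · exp(η · (mean score of this round's
   hypotheses containing v − round mean))`, then renormalize to sum to
   the variant count. η = 0.25. Variants absent from the round have zero
   advantage. This is a multiplicative-weights / exponentiated-gradient
   step: productive variants are proposed more, unproductive ones decay,
   and propensities stay positive and finite by construction.

**Convergence.** The per-round mean score of *newly proposed* hypotheses
is tracked; when its moving average (window = patience = 6) fails to
strictly increase for `patience` consecutive rounds — or at `max_rounds`
= 40 — the search stops and returns the top `max_selected` = 99 archived
hypotheses by score. The whole search owns a single RNG stream seeded
from its config, so results are bit-reproducible.

## The final model and the leakage problem

The hypotheses were *selected on the training labels*: their scores are
maxima over everything the search explored, so they carry selection
optimism, and any penalty tuning internal to the training set —
including cross-validation — inherits it. On label-noise data the
train-CV lasso over the raw selected set kept dozens of "significant"
indicator features in every run we simulated. Two designs address
this; the pipeline composes the first with an ordinary CV fit.

**Multiplicity screen (`screen_hypotheses`, the pipeline default).**
Before the lasso, every selected hypothesis's carrier/case 2×2 table is
tested with Fisher's exact test — valid at any stratum size, unlike the
deviance score's χ² approximation, which is anti-conservative for
small carrier counts — and only hypotheses with
$p < \alpha / n_{\text{scored}}$ survive, Bonferroni-corrected over
*everything the search scored*, not just the returned head. α defaults
to 0.01 rather than the conventional 0.05 because the search is
adaptive: hill-climbing steers scoring toward high-scoring regions, so
the effective multiplicity exceeds the realized score count (measured
on label-noise runs, the 0.05 screen still passed something ~10–15% of
the time; at 0.01 it was empty in every run). Under a global null the
screened set — and hence the final model — is almost always empty,
while a planted interaction of practical size passes the cut by many
orders of magnitude (deviance improvements of 40–70 against a null-max
of ~16). If nothing survives, the final model is the intercept-only
null model.

**Penalty choice.** Surviving hypotheses become binary indicator
columns (`build_features`; duplicates collapse to the first id) and
the final model is an L1-penalized logistic regression (`glmnet`),
with λ from stratified 5-fold `cv.glmnet` on the training split
(`fit_l1_cv`; one-SE rule by default, deviance minimum available). An
alternative tuner (`fit_l1_valid`) fits the path on training data and
picks the heaviest penalty within one SE of the *validation-set*
deviance minimum — the validation split's hyperparameter-tuning role —
but with 33 tuning samples it prunes real but modest interactions
(~8 validation carriers sit near one SE of deviance), so it is not the
default.

Signed coefficients are reported sorted by magnitude — negative =
protective combination, positive = risk — together with the count of
distinct variants across nonzero terms.

## Evaluation

AUC is the Mann–Whitney statistic (ties count ½). Confidence intervals
are percentile bootstrap over (score, label) pairs, 10⁴ iterations by
default, single-class resamples redrawn and counted; both the plug-in
AUC and the bootstrap-mean AUC are reported. The operating point
maximizes Youden's J = sensitivity + specificity − 1 (ties → higher
specificity); accuracy uses the evaluation set's actual class mix.
`combo_table` cross-classifies samples by named genotypes of a variant
set (each variant contributes its listed genotypes plus a "-" = any
other stratum, so the strata partition the cohort), with row-percentage
shares to one decimal. Splits are class-stratified by largest-remainder
apportionment and deterministic given a seed.

## The simulator

`simulate_genotypes` uses a latent-Gaussian threshold model: per LD
block, each of a sample's two haplotype latents shares an exchangeable
correlation ρ_LD across the block's variants; thresholding at
`qnorm(MAF)` gives alleles, and the two alleles sum to the dosage. This
yields exact Hardy–Weinberg marginals at each variant's MAF and
tunable within-block r², independent across blocks. It does **not**
emulate recombination maps, allele-frequency spectra, rare variants or
ancestry structure — it is a controllable test bed for the method's
operating characteristics, not a population-genetic simulation, and
passing tests on it say nothing about confounding that real cohorts
carry (stratification, batch effects, differential missingness).

`simulate_phenotype` draws labels from
`logit(p) = β₀ + Σ β_a · dosage + Σ β_I · [conditions met]`. A planted
interaction can be specified by target carrier *penetrance* instead of
β_I; the effect is then obtained by inverting the logistic link against
the carriers' realized background risk, so the realized carrier case
rate lands on the target by construction. `simulate_prior_graph` links
the variants of a fraction `c` of planted interactions through a shared
synthetic gene node and adds a configured number of noise edges among
non-causal variants; `c = 1` is the informative graph, `c = 0` the
uninformative control.

**Presets.** All presets use 436 samples (a two-chip cohort after QC),
120 variants in LD blocks of 10, ~1% missingness, and a case fraction
held near 296/436 by offsetting the baseline logit against the mean
effect shift. `"null"` has no genetic effects. `"additive_only"` plants
eight additive variants at log-OR 0.5 (MAF 0.2–0.5) — strong enough
that a 367-sample training scan ranks them reliably, which is what the
PRS-recovery property needs. `"epistatic_ppmi_like"` plants one
heterozygote/heterozygote two-variant interaction at target carrier
penetrance 0.95 with MAF 0.3–0.5 (≈ a fifth of the cohort carries it;
the printed combination strata this mirrors reach 87.5–100% case
share) and **no** additive background: the architecture is purely
epistatic, so the additive PRS baseline has essentially nothing to
find, mirroring a study in which the PRS barely beat chance while the
interaction model did not. Splits are 367/33/36.

## Problem sizes and determinism

The test suite exercises the search and pipeline at the preset scale
(436 × 120, 50 + 50 replicates for the recovery comparison, 20 seeds
for null calibration, 200 outer replicates for bootstrap coverage at
n = 36, 10⁴ bootstrap iterations where a confidence interval is itself
the quantity under test and 300–2000 where it is not) — sizes chosen so
the full suite runs on a single CPU in minutes while keeping
Monte-Carlo error well inside the asserted margins. Every stochastic
component (simulation, splits, search, CV folds, bootstrap) takes an
explicit seed and restores the caller's RNG state, so any reported
number is reproducible from its seed.

## Known limitations

* Hypotheses are conjunctions of exact genotype matches; dominance-style
  conditions ("at least one alt allele") are expressible only as two
  hypotheses, and disjunctions are not represented.
* Scoring on the training set follows the source procedure and accepts
  in-sample optimism; the honest numbers are the held-out test metrics.
* The association scan is plain logistic regression: no kinship or
  stratification adjustment, no saddlepoint correction for extreme
  case/control imbalance.
* IBD estimates are noisy below ~1000 markers (see above).
* With a 33-sample tuning split the final model is conservative;
  cohorts with a larger validation set will retain more signal.
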