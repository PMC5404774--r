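---
title: "Methods: consensus SNP selection for continuous phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SNP selection for continuous phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model and its assumptions

`snpconsensus` targets candidate-gene association data: a few hundred
samples, a few thousand SNPs (p > n), and a continuous, approximately
Gaussian phenotype. Genotypes enter every stage numerically as additive
codes 1/2/3 (major homozygous / heterozygous / minor homozygous), so all
regression stages share the additive linear model

$$ y = \beta_0 + X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I), $$

and the forest stages treat the same codes as ordered numeric predictors.
The additive coding is an assumption, not a convenience: dominance or
epistatic action is only detected to the extent it projects onto the
additive axis (the forests can exploit some non-additivity; the regression
ensemble cannot). Phenotypes are used as provided — the package never
re-standardises them — because the intended inputs are already
approximately standard-normal responses.

# The procedure

Each iteration of the tree schedule is self-contained:

1. **Forest filter.** A regression random forest (ranger) is fitted on all
   p SNPs plus any covariates; predictors are ranked by *raw* permutation
   variable importance (mean increase in out-of-bag squared error when the
   column is permuted, unscaled) and the top k survive. The model is scored
   by out-of-bag percent variance,
   $100\,(1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2)$, which is negative
   whenever the forest predicts worse than the phenotype mean — the typical
   outcome for the all-p fit on weak-signal data, and the reason the metric
   is computed on out-of-bag predictions rather than in-sample.
2. **Regression ensemble** on the top-k set: forward stepwise, ridge and
   lasso, each reduced to per-SNP p-values (details below) and thresholded
   at 0.01.
3. **Shadow-feature selection** (Boruta-style) on the same top-k set,
   yielding confirmed / tentative / rejected statuses; only confirmed SNPs
   vote.

After the final iteration, SNPs flagged by at least 3 of the 4 methods form
the consensus key-SNP set; the cross-iteration appearance count (at most
methods × iterations = 16 under the defaults) divided by that maximum is the
confidence score, with scores above 0.5 marking likely true positives. Both
filters are reported — consensus membership and confidence — because they
fail differently: consensus is a single-iteration snapshot, confidence
rewards stability across the whole schedule.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ntree_schedule` | 500, 1000, 2000, 3000 | trees per iteration; rising so later iterations give more stable importance rankings, with the final iteration treated as converged |
| `k` | 40 | top-k cut-off of the forest filter, read as ≈ √p at the motivating scale p ≈ 1400 |
| `mtry_fraction` | 1/3 | per-split candidate fraction, the regression-forest convention |
| `significance_cutoff` | 0.01 | per-SNP p-value threshold of the regression methods |
| `stepwise_entry_alpha` | 0.05 | partial-F-to-enter threshold of forward stepwise |
| `cv_folds` | 10 | lasso cross-validation folds; the λ minimising CV error is used (not the 1-SE rule) |
| `ridge_lambda_grid` | 10^−4 … 10^6, 121 points | grid of the automatic GCV ridge selector |
| `boruta_max_runs` / `boruta_alpha` / `boruta_ntree` | 100 / 0.01 / 500 | shadow-selection budget, decision level, trees per internal forest |
| `consensus_min_methods` | 3 | votes needed for a key SNP |
| `confidence_threshold` | 0.5 | strict lower bound for the true-positive flag |
| `seed` | — | one integer, expanded into per-stage substreams |

No convergence detection is attempted: the pipeline runs the fixed schedule
and reports per-iteration metrics, leaving convergence judgement to the
reader of the metrics table, which is how the protocol is meant to be read.

# Design choices where the design was open

* **Per-SNP inference for ridge.** Shrinkage has no exact finite-sample
  tests. Ridge uses Wald statistics with the sandwich covariance
  $\sigma^2 (X'X+\lambda I)^{-1} X'X (X'X+\lambda I)^{-1}$, residual
  degrees of freedom $n - \mathrm{edf} - 1$ with
  $\mathrm{edf} = \sum d_i^2/(d_i^2+\lambda)$ from the SVD, and σ²
  estimated from the penalised residuals. The automatic λ minimises
  generalised cross-validation error over a fixed logarithmic grid because
  GCV is deterministic, standard, and reduces exactly to OLS at λ = 0.
* **Per-SNP inference for lasso.** The nonzero-coefficient set at the
  cross-validated λ is tested sequentially in decreasing |β̂| order, each
  SNP by partial F-test against the model of previously *accepted* SNPs.
  This is the least arbitrary reading of testing "relatively large"
  coefficients "in a stepwise manner": every nonzero SNP gets a p-value,
  and acceptance order matches effect size.
* **Stepwise p-values** are Wald tests on the final selected model, not the
  entry tests; entry uses partial-F at α = 0.05. Entry and reporting are
  deliberately decoupled so that a SNP entering early but deflated by later
  entrants is not over-reported.
* **Shadow-feature decisions** use two-sided binomial tests on hit counts
  with step-down Bonferroni (Holm) correction across the still-undecided
  SNPs, the reference algorithm's scheme; rejected SNPs leave subsequent
  runs; tentative SNPs never vote, since only a confirmed status means
  "identified by the method".
* **Iterations are independent.** The top-k refit never feeds back into the
  next iteration's full-p fit; the only cross-iteration object is the
  appearance tally.
* **Covariates** are appended as predictor columns in every stage (additive
  model), flagged in all outputs, excluded from the vote matrix and key
  list, and reported in a separate trace.

# Numerical choices and degenerate inputs

* Percent variance errors out on a constant observed vector (undefined
  denominator) rather than returning NaN.
* Importance ties and tied top-k boundaries break by input column order
  (stable sort); imputation ties break toward the smaller genotype code
  (deterministic, and usually the major-allele class). A SNP column with no
  observed genotypes is an error, not a guess.
* With very small forests a sample can be in-bag in every tree; its missing
  out-of-bag prediction falls back to the forest prediction so the variance
  metric stays defined. At the default schedule this path is never taken.
* A rank-deficient design is an error in OLS, a tie-broken skip in stepwise
  (collinear candidates cannot enter), a p = 1 call in the lasso follow-up
  (no added fit over the accepted set), and a non-issue in ridge for λ > 0.
* Randomness discipline: one user seed is expanded by a seeded
  `sample.int` into independent substream seeds per iteration × stage
  (full fit, refit, lasso folds, shadow runs), so outputs are reproducible
  end-to-end and adding draws to one stage cannot perturb another.

# The synthetic generator

`simulate_null(n, p, seed)` draws per-SNP minor allele frequencies from
Uniform(0.05, 0.5), genotypes from Hardy–Weinberg proportions
$((1-m)^2,\,2m(1-m),\,m^2)$, and an independent standard-normal phenotype;
`simulate_with_effects()` plants additive effects
$y = \sum_j \beta_j\,\mathrm{code}_j + \varepsilon$ and returns the causal
truth set. `effect_for_pve()` converts a target per-SNP share of phenotypic
variance into an effect size using
$\mathrm{Var}(\mathrm{code}) = 2m(1-m)$.

What the generator emulates: the shape (hundreds of samples, ~1400 SNPs),
the 1/2/3 coding with realistic genotype class imbalance, a standard-normal
phenotype, and additive effects. What it does not emulate: linkage
disequilibrium between SNPs (columns are independent), population
structure, dominance and epistasis, genotyping error and missingness
patterns. Tests passing on this generator therefore show the machinery
works under the stated model; they do not show robustness to LD-induced
collinearity beyond what the ridge component is designed for.

# What the validation runs show — and their sizes

The test suite exercises three tiers, with problem sizes chosen as a
deliberate compromise between statistical resolution and a test run that
completes in minutes:

* **Closed-form oracles** (machine precision): ridge at λ = 0 against OLS,
  ridge shrinkage and lasso soft-thresholding on orthonormal designs, the
  percent-variance formula, Wald and partial-F against `lm`/`anova`.
* **Small-scale behavioural checks**: recovery of planted effects by each
  stage and by the whole pipeline at n ≈ 150–250, p ≈ 10–80, reduced
  schedules, 10–20 replicates.
* **Protocol-scale runs**: null pipelines at n = 460, p = 1400 with the
  full default configuration (2 seeds), and planted-effect recovery at
  n = 460, p = 300 with five causal SNPs each explaining ≈ 6 % of
  phenotypic variance (2 seeds).

A property worth stating plainly: because the top-k set is selected on the
same data the ensemble then tests, *all* downstream methods inherit
selection bias under the null — each flags several of the RF-chosen SNPs at
p ≤ 0.01, and the shadow-feature stage confirms spuriously correlated ones.
The consensus-and-confidence stage restricts this set substantially but
does not reduce it to zero; null runs can and do produce a handful of
"confident" key SNPs. This mirrors the behaviour of the protocol itself (a
pure-noise validation set still yields a short consensus list) and is the
reason key SNPs are candidates for follow-up, not discoveries.

# Known limitations

* Not suitable for genome-wide inputs (millions of SNPs) without an
  upstream subspace reduction; all forests are fitted on the full matrix.
* No post-selection inference correction: reported p-values are conditional
  on the RF filter and are comparable *within* the protocol, not calibrated
  against an unconditional null.
* Rare variants (very low MAF) are poorly served by both the forest filter
  and the additive regressions; burden-style methods are the right tool.
* The confidence denominator assumes the fixed 4-method ensemble; changing
  the ensemble changes the score scale (handled automatically, but scores
  are then not comparable across configurations).
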