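# snpconsensus

Consensus selection of key SNPs associated with continuous phenotypes in
high-dimensional (p > n) candidate-gene association data.

## The problem

Candidate-gene association studies often genotype a few thousand SNPs in a
few hundred individuals and measure a continuous trait — for example platelet
activation responses measured by flow cytometry. With more SNPs than samples,
single-SNP tests miss jointly-acting variants, forward stepwise regression is
unstable, and any single multivariate selector has its own blind spots
(stepwise drops variants in strong linkage disequilibrium; lasso picks one of
a correlated group; random-forest importance is noisy). `snpconsensus`
implements a consensus pipeline that stacks these methods and keeps only the
SNPs on which they agree.

Genotypes are coded additively: 1 = major homozygous, 2 = heterozygous,
3 = minor homozygous. The working model is the additive linear model

    y = β₀ + X β + ε,  ε ~ N(0, σ²I)

with `X` the n × p genotype-code matrix.

## The pipeline

For each iteration of a rising tree schedule (default ntree =
500, 1000, 2000, 3000):

1. **Forest filter** — fit a regression random forest on all p SNPs, rank by
   raw permutation variable importance, keep the top k (default 40 ≈ √p at
   the motivating scale). Out-of-bag % variance,
   `100·(1 − Σ(y−ŷ)²/Σ(y−ȳ)²)`, is recorded for the all-p fit (often near
   or below zero) and the top-k refit (substantially higher).
2. **Regression ensemble** on the top-k SNPs:
   forward stepwise (partial-F entry at α = 0.05, Wald p-values on the final
   model), ridge `β̂ = (X′X + λI)⁻¹X′y` with λ chosen automatically by
   generalised cross-validation (Wald p-values from the sandwich covariance),
   and lasso at the 10-fold cross-validation optimal λ with nonzero
   coefficients tested sequentially by partial F-test. Calls are significant
   at p ≤ 0.01.
3. **Shadow-feature selection** (Boruta-style, up to 100 runs at α = 0.01):
   permuted copies of every SNP column act as importance null references;
   SNPs repeatedly beating the best shadow are `confirmed`, the rest
   `rejected` or `tentative`. Only confirmed SNPs vote.

After the final iteration, a SNP flagged by **at least 3 of the 4 methods**
is a consensus *key SNP*. Each SNP's appearance count over all methods ×
all iterations (maximum 4 × 4 = 16) yields a confidence score

    confidence = count / (n_methods × n_iterations)

and a score **> 0.5** marks a likely true positive. Covariates (e.g. age)
ride through every stage as extra predictors and are reported separately,
never as key SNPs.

## Worked example

```r
library(snpconsensus)

# 200 samples x 80 SNPs, three planted additive effects
spec <- simulation_spec(n = 200, p = 80, maf = 0.3,
                        causal = c(5, 20, 61), beta = c(0.6, 0.6, 0.6),
                        noise_sd = 1, seed = 11)
d <- simulate_with_effects(spec)
d$truth
#> [1] "X5"  "X20" "X61"

cfg <- pipeline_config(ntree_schedule = c(200, 300), k = 15,
                       boruta_max_runs = 40, seed = 4)
report <- run_pipeline(d$genotypes, d$phenotype, config = cfg)
report$key_snps
#>   snp_id n_votes frequency confidence is_true_positive_candidate
#> 1    X20       4         8          1                       TRUE
#> 2     X5       4         8          1                       TRUE
#> 3    X61       4         8          1                       TRUE
```

All three planted SNPs are selected by all four methods in both iterations
(frequency 8 of a possible 4 methods × 2 iterations = 8, confidence 1) and
survive the 3-of-4 consensus with confidence > 0.5. `report$iteration_metrics`
holds the per-iteration out-of-bag % variances; `write_report_tables(report,
"out/")` serialises everything to TSV plus a JSON run manifest.

Command line, over the same functions:

```sh
Rscript inst/scripts/snpconsensus-cli.R simulate --n 460 --p 1400 --seed 1 --out sim.csv
Rscript inst/scripts/snpconsensus-cli.R run --input sim.csv --phenotype pheno --seed 1 --out-dir results/
```

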