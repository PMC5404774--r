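# Seed substream discipline: every exported function that consumes randomness
# takes one integer seed and expands it into independent per-stage seeds with
# derive_seeds(), so stages are individually reproducible and adding draws to
# one stage never perturbs another.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Specify a synthetic genotype/phenotype simulation
#'
#' Defines the generative model used by [simulate_with_effects()]: `n` samples
#' by `p` SNPs with independent genotypes drawn per SNP from Hardy-Weinberg
#' proportions, and an additive phenotype
#' `y = sum_j beta_j * code_j + epsilon`, `epsilon ~ N(0, noise_sd^2)`,
#' where `code_j` is the numeric 1/2/3 genotype code.
#'
#' Per-SNP minor allele frequencies default to Uniform(0.05, 0.5) draws, which
#' gives realistic genotype class imbalance; explicit per-SNP genotype
#' probabilities over the codes 1/2/3 can be supplied instead.
#'
#' @param n,p sample and SNP counts (`>= 1`).
#' @param maf optional per-SNP minor allele frequencies (length 1 or `p`);
#'   genotype probabilities follow Hardy-Weinberg:
#'   `((1-m)^2, 2m(1-m), m^2)` for codes 1, 2, 3.
#' @param genotype_probs optional `p x 3` matrix of genotype probabilities
#'   (rows sum to 1); overrides `maf`.
#' @param causal integer indices (`< p`) of causal SNPs.
#' @param beta effect sizes, one per causal SNP.
#' @param noise_sd residual standard deviation (> 0).
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n, p, maf = NULL, genotype_probs = NULL,
                            causal = integer(0), beta = numeric(0),
                            noise_sd = 1, seed = 1) {
  stopifnot(n >= 1, p >= 1, noise_sd > 0, length(causal) == length(beta))
  if (length(causal) > 0 && (any(causal < 1) || any(causal > p)))
    stop("causal SNP indices must lie in 1..p", call. = FALSE)
  if (!is.null(genotype_probs)) {
    genotype_probs <- matrix(genotype_probs, ncol = 3)
    if (nrow(genotype_probs) == 1) genotype_probs <-
        genotype_probs[rep(1, p), , drop = FALSE]
    stopifnot(nrow(genotype_probs) == p,
              all(abs(rowSums(genotype_probs) - 1) < 1e-8),
              all(genotype_probs >= 0))
  }
  if (!is.null(maf)) {
    maf <- rep_len(maf, p)
    stopifnot(all(maf > 0), all(maf <= 0.5))
  }
  structure(list(n = as.integer(n), p = as.integer(p), maf = maf,
                 genotype_probs = genotype_probs, causal = as.integer(causal),
                 beta = as.numeric(beta), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

hwe_probs <- function(maf) {
  cbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# draw the n x p code matrix column-wise; probs is p x 3
draw_genotypes <- function(n, p, probs) {
  codes <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    codes[, j] <- sample.int(3L, n, replace = TRUE, prob = probs[j, ])
  }
  colnames(codes) <- paste0("X", seq_len(p))
  codes
}

#' Simulate a null dataset (no genotype-phenotype association)
#'
#' Genotypes are drawn independently per SNP under Hardy-Weinberg proportions
#' with minor allele frequency Uniform(0.05, 0.5); the phenotype is standard
#' normal, independent of all genotypes. This is the configuration used to
#' study the pipeline's false-positive behaviour.
#'
#' @param n,p sample and SNP counts.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A list with `genotypes` ([genotype_table]) and `phenotype`
#'   (numeric vector of length `n`).
#' @examples
#' d <- simulate_null(100, 50, seed = 7)
#' dim(d$genotypes)
#' @export
simulate_null <- function(n, p, seed = 1) {
  stopifnot(n >= 1, p >= 1)
  seeds <- derive_seeds(seed, 3)
  set.seed(seeds[1])
  maf <- stats::runif(p, 0.05, 0.5)
  set.seed(seeds[2])
  codes <- draw_genotypes(n, p, hwe_probs(maf))
  set.seed(seeds[3])
  y <- stats::rnorm(n)
  list(genotypes = genotype_table(codes), phenotype = y)
}

#' Simulate a dataset with planted additive SNP effects
#'
#' Draws genotypes under the configured genotype law and a phenotype
#' `y = sum_j beta_j * code_j + epsilon` with Gaussian noise, returning the
#' ground-truth causal SNP set for recovery testing. With an empty causal set
#' this reduces to the null generator up to the noise scale.
#'
#' @param spec a [simulation_spec].
#' @return A list with `genotypes`, `phenotype`, `truth` (character vector of
#'   causal SNP ids) and `maf` (the realised per-SNP minor allele
#'   frequencies, `NULL` when explicit genotype probabilities were given).
#' @export
simulate_with_effects <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  seeds <- derive_seeds(spec$seed, 3)
  maf <- spec$maf
  probs <- spec$genotype_probs
  if (is.null(probs)) {
    if (is.null(maf)) {
      set.seed(seeds[1])
      maf <- stats::runif(spec$p, 0.05, 0.5)
    }
    probs <- hwe_probs(maf)
  }
  set.seed(seeds[2])
  codes <- draw_genotypes(spec$n, spec$p, probs)
  set.seed(seeds[3])
  eps <- stats::rnorm(spec$n, 0, spec$noise_sd)
  signal <- if (length(spec$causal) > 0)
    as.numeric(codes[, spec$causal, drop = FALSE] %*% spec$beta) else 0
  y <- signal + eps
  list(genotypes = genotype_table(codes), phenotype = y,
       truth = colnames(codes)[spec$causal], maf = if (is.null(spec$genotype_probs)) maf)
}

#' Effect size giving a target proportion of phenotypic variance
#'
#' For a single SNP with genotype-code variance `v` in a model with total
#' planted genetic variance `g` from other SNPs and residual variance
#' `noise_sd^2`, the effect `beta` such that this SNP explains fraction `pve`
#' of total phenotypic variance solves
#' `beta^2 v = pve * (beta^2 v + g + noise_sd^2)`.
#' Used to construct recovery benchmarks with interpretable per-SNP
#' variance shares.
#'
#' @param pve target proportion of phenotypic variance for the SNP (0 < pve < 1).
#' @param code_var variance of the SNP's genotype code (for Hardy-Weinberg
#'   minor allele frequency `m`, this is `2 m (1 - m)`).
#' @param other_var genetic variance contributed by the other causal SNPs.
#' @param noise_sd residual standard deviation.
#' @return The positive effect size `beta`.
#' @export
effect_for_pve <- function(pve, code_var, other_var = 0, noise_sd = 1) {
  stopifnot(pve > 0, pve < 1, code_var > 0)
  sqrt(pve * (other_var + noise_sd^2) / (code_var * (1 - pve)))
}
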