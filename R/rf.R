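#' Percent variance explained
#'
#' The forest-evaluation metric used across iterations:
#' `100 * (1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))`.
#' Computed on out-of-bag predictions this can be negative — a model worse
#' than predicting the phenotype mean, which is typical when all p noisy SNPs
#' enter the full model.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return A scalar percentage (may be negative).
#' @export
pct_variance <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed vector is constant; percent variance undefined", call. = FALSE)
  100 * (1 - sum((observed - predicted)^2) / ss_tot)
}

#' Fit a regression random forest with permutation importance
#'
#' Fits a bootstrap-resampled regression forest on the numeric 1/2/3 genotype
#' codes (plus any appended covariate columns), computing raw (unscaled)
#' permutation variable importance and the out-of-bag percent variance via
#' [pct_variance()]. The per-split candidate count defaults to `floor(p/3)`,
#' the regression-forest convention.
#'
#' @param x numeric predictor matrix with column names; no missing values.
#' @param y numeric response vector, `length(y) == nrow(x)`.
#' @param ntree number of trees (>= 1).
#' @param seed integer seed; identical seeds give identical forests.
#' @param mtry_fraction fraction of predictors tried per split (default 1/3).
#' @return A list of class `rf_fit`: `forest` (the ranger object),
#'   `oob_predictions`, `pct_var` (out-of-bag percent variance),
#'   `importance` (named numeric, raw permutation importance), `ntree`.
#' @export
fit_rf <- function(x, y, ntree, seed = 1, mtry_fraction = 1/3) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), ntree >= 1)
  if (nrow(x) < 2) stop("need at least 2 samples to fit a forest", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values in predictors or response; impute first", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  mtry <- max(1L, floor(ncol(x) * mtry_fraction))
  forest <- ranger::ranger(x = x, y = y, num.trees = ntree, mtry = mtry,
                           importance = "permutation",
                           scale.permutation.importance = FALSE,
                           num.threads = 1, seed = seed, verbose = FALSE)
  oob <- forest$predictions
  # with very small ntree a sample can be in-bag everywhere; fall back to its
  # overall prediction so pct_variance stays defined
  if (anyNA(oob)) {
    miss <- is.na(oob)
    oob[miss] <- stats::predict(forest, data = x[miss, , drop = FALSE],
                                num.threads = 1)$predictions
  }
  structure(list(forest = forest, oob_predictions = oob,
                 pct_var = pct_variance(y, oob),
                 importance = forest$variable.importance,
                 ntree = as.integer(ntree)),
            class = "rf_fit")
}

#' Rank SNPs by permutation variable importance
#'
#' Orders predictors by the raw permutation importance of a fitted forest:
#' the mean increase in out-of-bag squared error when a predictor's column is
#' permuted. Ties break by input column order (stable).
#'
#' @param fit an `rf_fit` from [fit_rf()].
#' @return A data frame (`snp_id`, `importance`) in non-increasing
#'   importance order, one row per fitted predictor.
#' @export
rank_importance <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"))
  imp <- fit$importance
  ord <- order(-imp)  # stable: ties keep input order
  data.frame(snp_id = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Select the top-k SNPs from an importance ranking
#'
#' @param ranking a data frame from [rank_importance()].
#' @param k number of SNPs to keep (>= 1); truncated to the number ranked.
#' @return Character vector of the first `min(k, p)` SNP ids, ranking order
#'   preserved.
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(k >= 1)
  ranking$snp_id[seq_len(min(k, nrow(ranking)))]
}

#' Run the iterative random-forest filtering schedule
#'
#' For each tree count in the schedule: fit a forest on all p predictors,
#' rank by permutation importance, select the top-k, refit on the top-k
#' alone, and record both out-of-bag percent variances together with the
#' selected SNP list. Iterations are independent — each restarts from the
#' full predictor set — and the default schedule 500/1000/2000/3000 trees is
#' the protocol under which the final iteration is taken as converged.
#'
#' @param x numeric predictor matrix (genotype codes, plus covariates if any).
#' @param y numeric response.
#' @param schedule integer vector of tree counts, one per iteration.
#' @param k top-k cut-off (default 40, roughly `sqrt(p)` at the motivating
#'   scale p ~ 1400).
#' @param seed integer seed expanded into per-iteration substreams.
#' @param mtry_fraction per-split candidate fraction, passed to [fit_rf()].
#' @return A list of per-iteration records, each with `iteration`, `ntree`,
#'   `pct_var_all`, `pct_var_topk`, `top_k` (character vector) and
#'   `ranking`.
#' @export
run_rf_iterations <- function(x, y, schedule = c(500L, 1000L, 2000L, 3000L),
                              k = 40, seed = 1, mtry_fraction = 1/3) {
  stopifnot(length(schedule) >= 1)
  x <- as.matrix(x)
  seeds <- matrix(derive_seeds(seed, 2 * length(schedule)), ncol = 2)
  records <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    full <- fit_rf(x, y, ntree = schedule[i], seed = seeds[i, 1],
                   mtry_fraction = mtry_fraction)
    ranking <- rank_importance(full)
    top <- select_top_k(ranking, k)
    refit <- fit_rf(x[, top, drop = FALSE], y, ntree = schedule[i],
                    seed = seeds[i, 2], mtry_fraction = mtry_fraction)
    records[[i]] <- list(iteration = i, ntree = as.integer(schedule[i]),
                         pct_var_all = full$pct_var,
                         pct_var_topk = refit$pct_var,
                         top_k = top, ranking = ranking)
  }
  records
}
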