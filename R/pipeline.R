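#' Pipeline configuration
#'
#' Defaults reproduce the reference protocol: tree schedule
#' 500/1000/2000/3000, top-k cut-off 40, significance cut-off 0.01,
#' shadow-selection budget 100 runs at alpha 0.01, consensus 3-of-4 and
#' confidence threshold 0.5.
#'
#' @param ntree_schedule tree counts, one per iteration.
#' @param k top-k cut-off of the forest filter.
#' @param mtry_fraction per-split candidate fraction of all forests.
#' @param significance_cutoff per-SNP p-value cut-off of the regression
#'   methods.
#' @param stepwise_entry_alpha partial-F-to-enter threshold of forward
#'   stepwise.
#' @param cv_folds lasso cross-validation folds.
#' @param ridge_lambda_grid candidate grid of the automatic ridge selector.
#' @param boruta_max_runs,boruta_alpha,boruta_ntree shadow-selection budget,
#'   decision level and trees per run.
#' @param consensus_min_methods methods required for a consensus key SNP.
#' @param confidence_threshold confidence level above which a SNP is a
#'   likely true positive.
#' @param seed integer seed expanded into per-stage substreams.
#' @param out_dir optional directory; when set, [run_pipeline()] writes all
#'   report tables there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ntree_schedule = c(500L, 1000L, 2000L, 3000L),
                            k = 40,
                            mtry_fraction = 1/3,
                            significance_cutoff = 0.01,
                            stepwise_entry_alpha = 0.05,
                            cv_folds = 10,
                            ridge_lambda_grid = 10^seq(-4, 6, length.out = 121),
                            boruta_max_runs = 100,
                            boruta_alpha = 0.01,
                            boruta_ntree = 500,
                            consensus_min_methods = 3,
                            confidence_threshold = 0.5,
                            seed = 1,
                            out_dir = NULL) {
  cfg <- list(ntree_schedule = as.integer(ntree_schedule), k = as.integer(k),
              mtry_fraction = mtry_fraction,
              significance_cutoff = significance_cutoff,
              stepwise_entry_alpha = stepwise_entry_alpha,
              cv_folds = as.integer(cv_folds),
              ridge_lambda_grid = ridge_lambda_grid,
              boruta_max_runs = as.integer(boruta_max_runs),
              boruta_alpha = boruta_alpha,
              boruta_ntree = as.integer(boruta_ntree),
              consensus_min_methods = as.integer(consensus_min_methods),
              confidence_threshold = confidence_threshold,
              seed = as.integer(seed), out_dir = out_dir)
  stopifnot(length(cfg$ntree_schedule) >= 1, all(cfg$ntree_schedule >= 1),
            cfg$k >= 1, cfg$significance_cutoff > 0,
            cfg$consensus_min_methods >= 1, cfg$consensus_min_methods <= 4,
            cfg$boruta_max_runs >= 1)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults.
#'
#' @param path path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full consensus SNP-selection pipeline
#'
#' Orchestrates the complete protocol on one phenotype: for each iteration
#' of the tree schedule, fit a regression forest on all p SNPs (plus
#' covariates), select the top-k by permutation importance, then screen the
#' top-k with forward stepwise, ridge, lasso and shadow-feature selection;
#' after the final iteration, build the vote matrix, apply the 3-of-4
#' consensus rule, tally cross-iteration appearance frequencies over all
#' iterations, and attach confidence scores. Covariate columns ride through
#' every stage as additional predictors; their calls are reported separately
#' and never enter the SNP vote matrix or key list.
#'
#' @param genotypes a [genotype_table] with no missing cells (run
#'   [impute_missing()] first if needed).
#' @param phenotype numeric response vector, one value per sample.
#' @param covariates optional numeric matrix of covariate columns.
#' @param config a [pipeline_config()].
#' @param phenotype_name label used in reports.
#' @return A list of class `consensus_report`: `iteration_metrics` (data
#'   frame mirroring the per-iteration evaluation table), `calls` (all
#'   method calls across iterations, with `is_covariate`), `vote_matrix`,
#'   `consensus_snps`, `frequency` (long breakdown), `confidence` (per-SNP
#'   scores), `key_snps` (consensus SNPs annotated with confidence),
#'   `boruta` (final-iteration `boruta_result`), `covariate_trace`,
#'   `config`, `elapsed_seconds`.
#' @export
run_pipeline <- function(genotypes, phenotype, covariates = NULL,
                         config = pipeline_config(),
                         phenotype_name = "phenotype") {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  x_snp <- as_code_matrix(genotypes)
  if (anyNA(x_snp))
    stop("rf_stage: genotype table has missing cells; run impute_missing() first",
         call. = FALSE)
  if (length(phenotype) != nrow(x_snp))
    stop("datamodel: phenotype length does not match sample count", call. = FALSE)
  covariate_names <- character(0)
  x <- x_snp
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates))
      stop("datamodel: covariates must be numeric", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    covariate_names <- colnames(covariates)
    x <- cbind(x_snp, covariates)
  }
  storage.mode(x) <- "double"
  n_iter <- length(config$ntree_schedule)
  seeds <- matrix(derive_seeds(config$seed, 4 * n_iter), ncol = 4)

  all_calls <- list()
  metrics <- vector("list", n_iter)
  final_boruta <- NULL
  for (i in seq_len(n_iter)) {
    ntree <- config$ntree_schedule[i]
    full <- fit_rf(x, phenotype, ntree = ntree, seed = seeds[i, 1],
                   mtry_fraction = config$mtry_fraction)
    ranking <- rank_importance(full)
    top <- select_top_k(ranking, config$k)
    refit <- fit_rf(x[, top, drop = FALSE], phenotype, ntree = ntree,
                    seed = seeds[i, 2], mtry_fraction = config$mtry_fraction)

    # the ensemble sees the top-k SNPs plus every covariate (always appended)
    ens_cols <- union(top, covariate_names)
    xe <- x[, ens_cols, drop = FALSE]

    sw <- stepwise_forward(xe, phenotype,
                           entry_alpha = config$stepwise_entry_alpha,
                           cutoff = config$significance_cutoff, iteration = i)
    rd <- ridge_fit(xe, phenotype, lambda_grid = config$ridge_lambda_grid,
                    cutoff = config$significance_cutoff, iteration = i)
    ls <- lasso_fit(xe, phenotype, n_folds = config$cv_folds,
                    seed = seeds[i, 3], cutoff = config$significance_cutoff,
                    iteration = i)
    bo <- run_boruta(xe, phenotype, max_runs = config$boruta_max_runs,
                     alpha = config$boruta_alpha, ntree = config$boruta_ntree,
                     seed = seeds[i, 4], mtry_fraction = config$mtry_fraction)
    if (i == n_iter) final_boruta <- bo

    all_calls[[i]] <- rbind(sw$calls, rd$calls, ls$calls, boruta_calls(bo, i))
    metrics[[i]] <- data.frame(
      iteration = i, ntree = ntree,
      pct_var_all = full$pct_var, pct_var_topk = refit$pct_var,
      stepwise_r2 = sw$fit$r2, stepwise_model_p = sw$fit$model_pvalue,
      ridge_pct_var = 100 * rd$fit$r2, ridge_lambda = rd$fit$lambda,
      lasso_r2 = ls$fit$r2, lasso_model_p = ls$fit$model_pvalue,
      n_topk = length(top), stringsAsFactors = FALSE)
  }

  calls <- do.call(rbind, all_calls)
  calls$is_covariate <- calls$snp_id %in% covariate_names
  snp_calls <- calls[!calls$is_covariate, , drop = FALSE]

  votes <- build_vote_matrix(snp_calls, final_iteration = n_iter)
  consensus <- consensus_select(votes, config$consensus_min_methods)
  freq <- count_frequency(snp_calls)
  conf <- if (nrow(freq$counts) > 0)
    cbind(snp_id = freq$counts$snp_id,
          confidence(freq$counts$count, n_methods = 4, n_iterations = n_iter,
                     threshold = config$confidence_threshold))
  else data.frame(snp_id = character(0), count = integer(0), score = numeric(0),
                  is_true_positive_candidate = logical(0))

  key <- conf[conf$snp_id %in% consensus, , drop = FALSE]
  key <- data.frame(snp_id = key$snp_id, n_votes = rowSums(votes)[key$snp_id],
                    frequency = key$count, confidence = key$score,
                    is_true_positive_candidate = key$is_true_positive_candidate,
                    row.names = NULL, stringsAsFactors = FALSE)
  key <- key[order(-key$confidence, key$snp_id), , drop = FALSE]

  covariate_trace <- if (length(covariate_names) > 0)
    calls[calls$is_covariate, , drop = FALSE] else NULL

  report <- structure(list(
    iteration_metrics = do.call(rbind, metrics),
    calls = calls, vote_matrix = votes, consensus_snps = consensus,
    frequency = freq$breakdown, frequency_counts = freq$counts,
    confidence = conf, key_snps = key, boruta = final_boruta,
    covariate_trace = covariate_trace, config = config,
    phenotype_name = phenotype_name, n_samples = nrow(x_snp),
    n_snps = ncol(x_snp),
    elapsed_seconds = as.numeric(Sys.time() - t0, units = "secs")),
    class = "consensus_report")

  if (!is.null(config$out_dir)) write_report_tables(report, config$out_dir)
  report
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus_report for '%s': %d samples x %d SNPs, %d iterations\n",
              x$phenotype_name, x$n_samples, x$n_snps,
              nrow(x$iteration_metrics)))
  cat(sprintf("  consensus key SNPs (>= %d of 4 methods): %s\n",
              x$config$consensus_min_methods,
              if (length(x$consensus_snps) > 0)
                paste(x$consensus_snps, collapse = ", ") else "(none)"))
  ntp <- sum(x$key_snps$is_true_positive_candidate)
  cat(sprintf("  of which confidence > %.2f: %d\n",
              x$config$confidence_threshold, ntp))
  invisible(x)
}
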