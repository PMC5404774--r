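PIPELINE_METHODS <- c("stepwise", "ridge", "lasso", "boruta")

#' Build the final-iteration vote matrix
#'
#' One row per SNP that received at least one significant/confirmed call in
#' the final iteration; one logical column per ensemble method. A cell is
#' `TRUE` iff that method flagged the SNP significant (regression methods,
#' p <= cutoff) or confirmed (shadow-feature selection) in the final
#' iteration.
#'
#' @param calls a method-call data frame (`method`, `snp_id`, `statistic`,
#'   `significant`, `iteration`).
#' @param final_iteration the iteration index to vote on (default: the
#'   largest iteration present).
#' @param methods the fixed method columns.
#' @return A logical matrix, SNP ids as rownames, methods as colnames.
#' @export
build_vote_matrix <- function(calls, final_iteration = NULL,
                              methods = PIPELINE_METHODS) {
  if (is.null(final_iteration)) {
    if (nrow(calls) == 0) final_iteration <- 1L
    else final_iteration <- max(calls$iteration, na.rm = TRUE)
  }
  fin <- calls[!is.na(calls$iteration) & calls$iteration == final_iteration &
                 calls$significant, , drop = FALSE]
  snps <- unique(fin$snp_id)
  votes <- matrix(FALSE, nrow = length(snps), ncol = length(methods),
                  dimnames = list(snps, methods))
  for (i in seq_len(nrow(fin)))
    votes[fin$snp_id[i], fin$method[i]] <- TRUE
  votes
}

#' Select consensus key SNPs from a vote matrix
#'
#' A SNP becomes a key SNP when at least `min_methods` of the ensemble
#' methods voted for it in the final iteration (default 3 of 4).
#'
#' @param votes logical vote matrix from [build_vote_matrix()].
#' @param min_methods minimum number of agreeing methods (1..ncol).
#' @return Character vector of selected SNP ids, row order preserved.
#' @export
consensus_select <- function(votes, min_methods = 3) {
  stopifnot(min_methods >= 1, min_methods <= ncol(votes))
  rownames(votes)[rowSums(votes) >= min_methods]
}

#' Count cross-iteration appearance frequencies
#'
#' For each SNP, counts the (method, iteration) pairs with a significant or
#' confirmed call; a method contributes at most one appearance per
#' iteration, so with 4 methods and 4 iterations the maximum attainable
#' count is 16. SNPs never called significant are absent.
#'
#' @param calls a method-call data frame spanning >= 1 iteration.
#' @return A list: `counts` (data frame `snp_id`, `count`, decreasing) and
#'   `breakdown` (long data frame `snp_id`, `iteration`, `method` of distinct
#'   appearances).
#' @export
count_frequency <- function(calls) {
  sig <- calls[calls$significant & !is.na(calls$iteration), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(list(counts = data.frame(snp_id = character(0), count = integer(0),
                                    stringsAsFactors = FALSE),
                breakdown = data.frame(snp_id = character(0),
                                       iteration = integer(0),
                                       method = character(0),
                                       stringsAsFactors = FALSE)))
  }
  breakdown <- unique(sig[, c("snp_id", "iteration", "method")])
  breakdown <- breakdown[order(breakdown$snp_id, breakdown$iteration,
                               breakdown$method), , drop = FALSE]
  rownames(breakdown) <- NULL
  tab <- table(breakdown$snp_id)
  counts <- data.frame(snp_id = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$snp_id), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, breakdown = breakdown)
}

#' Confidence score of a SNP's cross-iteration appearance count
#'
#' `score = count / (n_methods * n_iterations)`, the fraction of all
#' intermediate models (across every iteration) in which the SNP was called.
#' A score above `threshold` (default 0.5) marks the SNP as a likely true
#' positive. With 4 methods and 4 iterations, a count of 13 scores 0.8125
#' and the maximum count of 16 scores 1.
#'
#' @param count appearance count(s), `0 <= count <= n_methods * n_iterations`.
#' @param n_methods number of ensemble methods (default 4).
#' @param n_iterations number of pipeline iterations (default 4).
#' @param threshold true-positive-candidate threshold (default 0.5,
#'   strict inequality).
#' @return A data frame (`count`, `score`, `is_true_positive_candidate`),
#'   one row per input count.
#' @export
confidence <- function(count, n_methods = 4, n_iterations = 4,
                       threshold = 0.5) {
  stopifnot(n_methods >= 1, n_iterations >= 1)
  maxc <- n_methods * n_iterations
  if (any(count < 0) || any(count > maxc))
    stop("appearance count must lie in 0..", maxc, call. = FALSE)
  score <- count / maxc
  data.frame(count = count, score = score,
             is_true_positive_candidate = score > threshold)
}
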