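#' All-relevant SNP selection via shadow features
#'
#' Shadow-feature (Boruta-style) all-relevant selection on a candidate SNP
#' set. Each run duplicates every still-active column, permutes the
#' duplicates (the "shadow" features — preserving each column's marginal
#' distribution while destroying any association with the phenotype), fits a
#' regression forest on real + shadow columns, and converts permutation
#' importances to Z-scores against the shadow importance distribution. A real
#' SNP scores a "hit" when its Z-score beats the maximum shadow Z-score.
#' After each run, two-sided binomial tests on the accumulated hit counts
#' (null hit probability 1/2), step-down Bonferroni corrected across the
#' still-undecided SNPs, promote SNPs to `confirmed` or demote them to
#' `rejected`; rejected SNPs are dropped from subsequent runs. SNPs still
#' undecided when the run budget is exhausted are `tentative`.
#'
#' Only `confirmed` SNPs count as selection votes downstream; tentative ones
#' are reported but do not vote.
#'
#' @param x candidate predictor matrix (typically the RF top-k SNPs plus any
#'   covariates).
#' @param y numeric response.
#' @param max_runs maximum number of shadow runs (default 100).
#' @param alpha significance level of the binomial decision tests
#'   (default 0.01).
#' @param ntree trees per internal forest (default 500).
#' @param seed integer seed; statuses are reproducible given the seed.
#' @param mtry_fraction per-split candidate fraction for the internal forests.
#' @return A list of class `boruta_result`: `status` (named character,
#'   `confirmed`/`tentative`/`rejected`, one per input column), `hits`
#'   (named integer hit counts), `runs_active` (runs each SNP participated
#'   in), `mean_z` (mean Z-score over a SNP's active runs), `runs_used`.
#' @export
run_boruta <- function(x, y, max_runs = 100, alpha = 0.01, ntree = 500,
                       seed = 1, mtry_fraction = 1/3) {
  x <- as.matrix(x)
  stopifnot(max_runs >= 1, alpha > 0, alpha < 1, nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  vars <- colnames(x)
  status <- stats::setNames(rep("tentative", length(vars)), vars)
  hits <- stats::setNames(integer(length(vars)), vars)
  runs_active <- stats::setNames(integer(length(vars)), vars)
  z_sum <- stats::setNames(numeric(length(vars)), vars)
  seeds <- matrix(derive_seeds(seed, 2 * max_runs), ncol = 2)

  runs_used <- 0L
  for (run in seq_len(max_runs)) {
    active <- vars[status != "rejected"]
    if (!any(status[active] == "tentative")) break
    runs_used <- run

    xa <- x[, active, drop = FALSE]
    set.seed(seeds[run, 1])
    shadows <- apply(xa, 2, sample)
    # keep enough shadows for a stable null importance distribution
    while (ncol(shadows) < 5)
      shadows <- cbind(shadows, apply(xa, 2, sample)[, 1, drop = FALSE])
    colnames(shadows) <- paste0("shadow_", seq_len(ncol(shadows)))
    design <- cbind(xa, shadows)

    fit <- fit_rf(design, y, ntree = ntree, seed = seeds[run, 2],
                  mtry_fraction = mtry_fraction)
    imp <- fit$importance
    sh <- imp[startsWith(names(imp), "shadow_")]
    sh_sd <- stats::sd(sh)
    if (!is.finite(sh_sd) || sh_sd == 0) sh_sd <- .Machine$double.eps
    z <- (imp[active] - mean(sh)) / sh_sd
    z_max_shadow <- max((sh - mean(sh)) / sh_sd)

    hit <- z > z_max_shadow
    hits[active] <- hits[active] + as.integer(hit)
    runs_active[active] <- runs_active[active] + 1L
    z_sum[active] <- z_sum[active] + z

    undecided <- vars[status == "tentative"]
    if (length(undecided) > 0) {
      r <- runs_active[undecided]
      h <- hits[undecided]
      p_up <- stats::pbinom(h - 1, r, 0.5, lower.tail = FALSE)   # P(H >= h)
      p_down <- stats::pbinom(h, r, 0.5)                         # P(H <= h)
      conf <- undecided[stats::p.adjust(p_up, "holm") < alpha]
      rej <- undecided[stats::p.adjust(p_down, "holm") < alpha]
      rej <- setdiff(rej, conf)
      status[conf] <- "confirmed"
      status[rej] <- "rejected"
    }
  }
  mean_z <- ifelse(runs_active > 0, z_sum / runs_active, NA_real_)
  structure(list(status = status, hits = hits, runs_active = runs_active,
                 mean_z = mean_z, runs_used = runs_used),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf("boruta_result: %d confirmed, %d tentative, %d rejected (%d runs)\n",
              tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]],
              x$runs_used))
  invisible(x)
}

boruta_calls <- function(result, iteration = NA_integer_) {
  snp <- names(result$status)
  make_calls("boruta", snp, result$mean_z[snp],
             result$status[snp] == "confirmed", iteration)
}
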