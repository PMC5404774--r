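# All ensemble regressions share the additive linear model
#   y = b0 + X b + e,  e ~ N(0, sigma^2),
# with X the numeric 1/2/3 genotype codes (covariate columns, when supplied,
# are appended to X and treated identically).

new_regression_fit <- function(method, intercept, coefficients, se, pvalues,
                               rss, df_residual, n, r2, model_pvalue,
                               lambda = NA_real_, edf = NA_real_) {
  structure(list(method = method, intercept = intercept,
                 coefficients = coefficients, se = se, pvalues = pvalues,
                 rss = rss, df_residual = df_residual, n = n, r2 = r2,
                 model_pvalue = model_pvalue, lambda = lambda, edf = edf),
            class = "regression_fit")
}

make_calls <- function(method, snp_id, statistic, significant,
                       iteration = NA_integer_) {
  data.frame(method = rep_len(method, length(snp_id)),
             snp_id = as.character(snp_id),
             statistic = as.numeric(statistic),
             significant = as.logical(significant),
             iteration = rep_len(as.integer(iteration), length(snp_id)),
             stringsAsFactors = FALSE)
}

empty_calls <- function() make_calls(character(0), character(0), numeric(0), logical(0))

#' Ordinary least squares fit
#'
#' Solves the normal equations (with intercept) by QR decomposition and
#' returns coefficients, standard errors and two-sided Wald p-values. With
#' zero predictor columns the fit is intercept-only, which anchors nested
#' partial F-tests.
#'
#' @param x numeric predictor matrix (may have 0 columns).
#' @param y numeric response.
#' @return A `regression_fit`.
#' @export
ols_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(x) == n || ncol(x) == 0)
  if (ncol(x) > 0 && is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  xmat <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(xmat)
  if (qrx$rank < ncol(xmat))
    stop("design matrix is rank deficient (singular); cannot fit OLS", call. = FALSE)
  coefs <- qr.coef(qrx, y)
  fitted <- qr.fitted(qrx, y)
  rss <- sum((y - fitted)^2)
  df_res <- n - ncol(xmat)
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- names(coefs)
  slopes <- coefs[-1]
  slope_se <- se[-1]
  pvals <- if (length(slopes) > 0) wald_test(slopes, slope_se, df_res) else numeric(0)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - rss / ss_tot else NA_real_
  model_p <- NA_real_
  if (ncol(x) > 0 && ss_tot > 0 && rss > 0) {
    fstat <- ((ss_tot - rss) / ncol(x)) / (rss / df_res)
    model_p <- stats::pf(fstat, ncol(x), df_res, lower.tail = FALSE)
  }
  new_regression_fit("ols", unname(coefs[1]), slopes, slope_se, pvals,
                     rss, df_res, n, r2, model_p)
}

#' Two-sided Wald test of a regression coefficient
#'
#' Tests `beta = 0` via `t = beta/se` against a t reference distribution with
#' `df` residual degrees of freedom. Vectorised over coefficients.
#'
#' @param beta coefficient estimate(s).
#' @param se standard error(s), strictly positive.
#' @param df residual degrees of freedom (may be non-integer for
#'   shrinkage fits with effective degrees of freedom).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
wald_test <- function(beta, se, df) {
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  stopifnot(df > 0)
  2 * stats::pt(-abs(beta / se), df = df)
}

#' Partial F-test between nested linear models
#'
#' Tests whether the extra predictors of the larger model significantly
#' reduce the residual sum of squares:
#' `F = ((RSS_small - RSS_large)/d) / (RSS_large/df_large)` with `d` the
#' number of added predictors, against `F(d, df_large)`.
#'
#' @param fit_small,fit_large nested `regression_fit`s (the small model's
#'   predictors must be a subset of the large model's).
#' @return Upper-tail p-value.
#' @export
partial_f_test <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "regression_fit"),
            inherits(fit_large, "regression_fit"))
  small_vars <- names(fit_small$coefficients)
  large_vars <- names(fit_large$coefficients)
  if (!all(small_vars %in% large_vars))
    stop("models are not nested: small model has predictors absent from the large model",
         call. = FALSE)
  d <- length(large_vars) - length(small_vars)
  if (d == 0) return(1)  # identical models: F = 0
  num <- (fit_small$rss - fit_large$rss) / d
  if (fit_large$rss <= 0) return(if (num <= 0) 1 else 0)
  fstat <- max(num, 0) / (fit_large$rss / fit_large$df_residual)
  stats::pf(fstat, d, fit_large$df_residual, lower.tail = FALSE)
}

#' Forward stepwise regression with Wald significance calls
#'
#' Starts from the intercept-only null model and greedily adds, one at a
#' time, the candidate SNP giving the largest fit improvement (largest
#' partial F), as long as its entry test passes `entry_alpha`. Reported
#' per-SNP p-values come from Wald tests on the final selected model; calls
#' are flagged significant at `cutoff`.
#'
#' @param x candidate predictor matrix.
#' @param y numeric response.
#' @param entry_alpha partial-F-to-enter threshold (default 0.05).
#' @param cutoff significance cut-off for calls (default 0.01).
#' @param iteration iteration index recorded on the calls.
#' @return A list: `fit` (a `regression_fit` on the selected SNPs, or the
#'   intercept-only fit), `calls` (one row per selected SNP), `selected`.
#' @export
stepwise_forward <- function(x, y, entry_alpha = 0.05, cutoff = 0.01,
                             iteration = NA_integer_) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(ncol(x) >= 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  n <- length(y)
  selected <- character(0)
  candidates <- colnames(x)
  cur_rss <- sum((y - mean(y))^2)
  repeat {
    if (length(candidates) == 0 || cur_rss <= 1e-12) break
    q <- length(selected) + 2L           # intercept + selected + candidate
    df_res <- n - q
    if (df_res < 1) break
    best <- NULL
    for (cand in candidates) {
      xmat <- cbind(1, x[, c(selected, cand), drop = FALSE])
      qrx <- qr(xmat)
      if (qrx$rank < ncol(xmat)) next    # collinear with current model
      rss <- sum(qr.resid(qrx, y)^2)
      fstat <- (cur_rss - rss) / (rss / df_res)
      if (is.null(best) || fstat > best$fstat)
        best <- list(cand = cand, rss = rss, fstat = fstat)
    }
    if (is.null(best)) break
    p_enter <- stats::pf(best$fstat, 1, df_res, lower.tail = FALSE)
    if (!is.finite(p_enter) || p_enter > entry_alpha) break
    selected <- c(selected, best$cand)
    candidates <- setdiff(candidates, best$cand)
    cur_rss <- best$rss
  }
  if (length(selected) == 0) {
    fit <- ols_fit(x[, integer(0), drop = FALSE], y)
    fit$method <- "stepwise"
    return(list(fit = fit, calls = empty_calls(), selected = character(0)))
  }
  fit <- ols_fit(x[, selected, drop = FALSE], y)
  fit$method <- "stepwise"
  calls <- make_calls("stepwise", selected, fit$pvalues[selected],
                      fit$pvalues[selected] <= cutoff, iteration)
  list(fit = fit, calls = calls, selected = selected)
}

#' Ridge regression with automatic lambda and Wald calls
#'
#' Fits the L2-penalised normal equations
#' `beta = (X'X + lambda I)^(-1) X'y` on centred predictors (intercept left
#' unpenalised). The shrinkage weight is chosen automatically by minimising
#' generalised cross-validation (GCV) error over a logarithmic grid — a
#' deterministic automatic selector. At `lambda = 0` the fit equals OLS; as
#' `lambda -> Inf` all slopes shrink to 0 and the prediction tends to the
#' response mean.
#'
#' Approximate per-SNP inference uses the sandwich covariance
#' `Var(beta) = sigma^2 (X'X+lambda I)^(-1) X'X (X'X+lambda I)^(-1)` with
#' `sigma^2 = RSS/(n - edf - 1)` and `edf` the effective degrees of freedom
#' `tr(X (X'X+lambda I)^(-1) X')`.
#'
#' @param x predictor matrix (>= 1 column).
#' @param y numeric response.
#' @param lambda fixed shrinkage weight; `NULL` (default) selects by GCV.
#' @param lambda_grid candidate grid for the automatic selector.
#' @param cutoff significance cut-off for calls (default 0.01).
#' @param iteration iteration index recorded on the calls.
#' @return A list: `fit` (a `regression_fit` with `lambda` and `edf` set),
#'   `calls` (one row per SNP), `gcv` (grid of GCV values, `NULL` if lambda
#'   was fixed).
#' @export
ridge_fit <- function(x, y, lambda = NULL,
                      lambda_grid = 10^seq(-4, 6, length.out = 121),
                      cutoff = 0.01, iteration = NA_integer_) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(ncol(x) >= 1, nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  n <- length(y)
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  sv <- svd(xc)
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  ss_tot <- sum(yc^2)

  ridge_at <- function(lam) {
    shrink <- d / (d^2 + lam)
    if (lam == 0 && any(d < max(d) * 1e-10))
      stop("design matrix is rank deficient; lambda = 0 ridge is singular",
           call. = FALSE)
    beta <- sv$v %*% (shrink * uty)
    fitted_c <- sv$u %*% ((d * shrink) * uty)
    rss <- sum((yc - fitted_c)^2)
    edf <- sum(d^2 / (d^2 + lam))
    list(beta = as.numeric(beta), rss = rss, edf = edf)
  }

  gcv <- NULL
  if (is.null(lambda)) {
    gcv <- vapply(lambda_grid, function(lam) {
      r <- ridge_at(lam)
      n * r$rss / (n - 1 - r$edf)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv)]
  }
  r <- ridge_at(lambda)
  beta <- stats::setNames(r$beta, colnames(x))
  intercept <- ym - sum(xm * beta)
  df_res <- n - r$edf - 1
  if (df_res < 1) df_res <- 1
  sigma2 <- r$rss / df_res
  # sandwich covariance via the SVD: A X'X A = V diag(d^2/(d^2+lam)^2) V'
  var_diag <- rowSums(sweep(sv$v^2, 2, d^2 / (d^2 + lambda)^2, `*`)) * sigma2
  se <- stats::setNames(sqrt(pmax(var_diag, .Machine$double.eps)), colnames(x))
  pvals <- wald_test(beta, se, df_res)
  r2 <- if (ss_tot > 0) 1 - r$rss / ss_tot else NA_real_
  model_p <- NA_real_
  if (ss_tot > 0 && r$rss > 0 && r$edf > 0) {
    fstat <- ((ss_tot - r$rss) / r$edf) / sigma2
    model_p <- stats::pf(fstat, r$edf, df_res, lower.tail = FALSE)
  }
  fit <- new_regression_fit("ridge", intercept, beta, se, pvals, r$rss,
                            df_res, n, r2, model_p, lambda = lambda,
                            edf = r$edf)
  calls <- make_calls("ridge", colnames(x), pvals, pvals <= cutoff, iteration)
  list(fit = fit, calls = calls, gcv = gcv)
}

#' Lasso with cross-validated lambda and sequential partial F-tests
#'
#' Fits the L1-penalised model by coordinate descent (glmnet, gaussian
#' family) at the smallest-error lambda from k-fold cross-validation. SNPs
#' with nonzero coefficients are then tested in decreasing `|beta|` order by
#' partial F-test, each against the model of previously accepted (significant
#' at `cutoff`) SNPs; this converts the sparse coefficient set into per-SNP
#' p-values comparable with the other ensemble methods.
#'
#' @param x predictor matrix (>= 2 columns for the cross-validated path).
#' @param y numeric response.
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param lambda fixed penalty; `NULL` (default) selects by cross-validation.
#' @param cutoff significance cut-off for calls (default 0.01).
#' @param standardize,intercept passed to glmnet.
#' @param iteration iteration index recorded on the calls.
#' @return A list: `fit` (a `regression_fit`; coefficients are the lasso
#'   estimates at the chosen lambda, inference fields from an OLS refit on
#'   the nonzero set when full rank), `calls` (one row per nonzero SNP with
#'   its partial-F p-value), `nonzero`, `lambda`.
#' @export
lasso_fit <- function(x, y, n_folds = 10, seed = 1, lambda = NULL,
                      cutoff = 0.01, standardize = TRUE, intercept = TRUE,
                      iteration = NA_integer_) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), ncol(x) >= 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (is.null(lambda)) {
    stopifnot(n_folds >= 2)
    set.seed(seed)
    cv <- glmnet::cv.glmnet(x, y, family = "gaussian", nfolds = n_folds,
                            standardize = standardize, intercept = intercept)
    lambda <- cv$lambda.min
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  } else {
    gf <- glmnet::glmnet(x, y, family = "gaussian", lambda = lambda,
                         standardize = standardize, intercept = intercept,
                         thresh = 1e-12)
    cf <- as.matrix(stats::coef(gf, s = lambda))
  }
  b0 <- cf[1, 1]
  slopes <- stats::setNames(cf[-1, 1], rownames(cf)[-1])
  nonzero <- names(slopes)[slopes != 0]
  nonzero <- nonzero[order(-abs(slopes[nonzero]))]

  accepted <- character(0)
  pvals <- stats::setNames(rep(NA_real_, length(nonzero)), nonzero)
  for (snp in nonzero) {
    small <- try(ols_fit(x[, accepted, drop = FALSE], y), silent = TRUE)
    large <- try(ols_fit(x[, c(accepted, snp), drop = FALSE], y), silent = TRUE)
    if (inherits(small, "try-error") || inherits(large, "try-error")) {
      pvals[snp] <- 1    # collinear with already-accepted SNPs: no added fit
      next
    }
    pvals[snp] <- partial_f_test(small, large)
    if (pvals[snp] <= cutoff) accepted <- c(accepted, snp)
  }

  rss <- sum((y - (b0 + as.numeric(x %*% slopes)))^2)
  r2 <- NA_real_; model_p <- NA_real_
  if (length(nonzero) > 0) {
    refit <- try(ols_fit(x[, nonzero, drop = FALSE], y), silent = TRUE)
    if (!inherits(refit, "try-error")) {
      r2 <- refit$r2; model_p <- refit$model_pvalue
    }
  }
  fit <- new_regression_fit("lasso", b0, slopes,
                            se = stats::setNames(rep(NA_real_, length(slopes)),
                                                 names(slopes)),
                            pvalues = pvals, rss = rss,
                            df_residual = length(y) - length(nonzero) - 1,
                            n = length(y), r2 = r2, model_pvalue = model_p,
                            lambda = lambda)
  calls <- if (length(nonzero) > 0)
    make_calls("lasso", nonzero, pvals[nonzero], pvals[nonzero] <= cutoff, iteration)
  else empty_calls()
  list(fit = fit, calls = calls, nonzero = nonzero, lambda = lambda)
}
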