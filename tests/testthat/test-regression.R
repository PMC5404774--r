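test_that("OLS matches the normal-equations solve and lm on a 50x5 fixture", {
  x <- random_design(50, 5, seed = 51)
  set.seed(52)
  y <- x %*% c(1, -0.5, 0, 2, 0.3) + rnorm(50)
  fit <- ols_fit(x, y)

  xmat <- cbind(1, x)
  brute <- solve(t(xmat) %*% xmat, t(xmat) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), c(brute),
               tolerance = 1e-8)

  lmfit <- lm(y ~ x)
  sm <- summary(lmfit)
  expect_equal(unname(fit$se), unname(sm$coefficients[-1, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$pvalues), unname(sm$coefficients[-1, 4]), tolerance = 1e-10)
  expect_equal(fit$r2, sm$r.squared, tolerance = 1e-10)

  # exact fit: zero residual variance, coefficient recovered exactly
  y2 <- 2 * x[, 1]
  fit2 <- ols_fit(x[, 1, drop = FALSE], y2)
  expect_equal(unname(fit2$coefficients), 2, tolerance = 1e-12)
  expect_lt(fit2$rss, 1e-20)

  expect_error(ols_fit(cbind(x, x[, 1]), y), "rank deficient")
})

test_that("the Wald test matches the textbook coefficient t-test and its limits", {
  expect_equal(wald_test(0, 1, 20), 1)
  expect_lt(wald_test(100, 1, 20), 1e-12)
  expect_error(wald_test(1, 0, 20), "positive")

  x <- random_design(50, 3, seed = 53)
  set.seed(54)
  y <- x %*% c(0.5, 0, -1) + rnorm(50)
  fit <- ols_fit(x, y)
  sm <- summary(lm(y ~ x))
  expect_equal(unname(wald_test(fit$coefficients, fit$se, fit$df_residual)),
               unname(sm$coefficients[-1, 4]), tolerance = 1e-10)
})

test_that("the partial F-test matches anova() and behaves at its boundaries", {
  x <- random_design(50, 4, seed = 55)
  set.seed(56)
  y <- x %*% c(1, 0.5, 0, 0) + rnorm(50)
  small <- ols_fit(x[, 1:2], y)
  large <- ols_fit(x, y)
  oracle <- anova(lm(y ~ x[, 1:2]), lm(y ~ x))[2, "Pr(>F)"]
  expect_equal(partial_f_test(small, large), oracle, tolerance = 1e-10)

  expect_equal(partial_f_test(small, small), 1)
  expect_error(partial_f_test(large, small), "not nested")
})

test_that("the partial F-test p-value is null-uniform and powered against real effects", {
  set.seed(57)
  pvals <- replicate(200, {
    x <- matrix(rnorm(60 * 3), 60, 3); colnames(x) <- c("a", "b", "noise")
    y <- x[, 1] + rnorm(60)
    partial_f_test(ols_fit(x[, 1:2], y), ols_fit(x, y))
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # beta/sigma = 1 at n = 460: essentially certain detection
  d <- simulate_with_effects(
    simulation_spec(460, 5, maf = 0.3, causal = 3, beta = 1, noise_sd = 1,
                    seed = 58))
  x <- unclass(d$genotypes)
  p <- partial_f_test(ols_fit(x[, c(1, 2)], d$phenotype),
                      ols_fit(x[, c(1, 2, 3)], d$phenotype))
  expect_lt(p, 0.001)
})

test_that("forward stepwise enters the dominant SNP first and stops when nothing improves", {
  x <- random_design(120, 10, seed = 61)
  set.seed(62)
  y <- 3 * x[, 7] + rnorm(120, 0, 0.5)
  sw <- stepwise_forward(x, y)
  expect_identical(sw$selected[1], "X7")
  expect_true(all(sw$calls$significant == (sw$calls$statistic <= 0.01)))

  # oracle: X7 has the largest first-step F among all single-SNP models
  first_f <- apply(x, 2, function(col) summary(lm(y ~ col))$fstatistic[1])
  expect_identical(names(which.max(first_f)), "X7")

  # constant response: no SNP can enter
  expect_length(stepwise_forward(x, rep(1.5, 120))$selected, 0)

  # duplicated causal column: exactly one of the pair enters
  xdup <- cbind(x, X7dup = x[, 7])
  swd <- stepwise_forward(xdup, y)
  expect_equal(sum(c("X7", "X7dup") %in% swd$selected), 1)
})

test_that("ridge at lambda 0 equals OLS and shrinks correctly on orthonormal designs", {
  x <- random_design(60, 6, seed = 63)
  set.seed(64)
  y <- x %*% c(1, -1, 0.5, 0, 0, 2) + rnorm(60)
  r0 <- ridge_fit(x, y, lambda = 0)
  ols <- ols_fit(x, y)
  expect_equal(r0$fit$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(r0$fit$intercept, ols$intercept, tolerance = 1e-8)

  q <- orthonormal_design(60, 6, seed = 65)
  set.seed(66)
  yq <- q %*% c(3, -2, 1, 0, 0.5, 0) + rnorm(60, 0, 0.2)
  lam <- 0.8
  rq <- ridge_fit(q, yq, lambda = lam)
  oq <- ols_fit(q, yq)
  expect_equal(rq$fit$coefficients, oq$coefficients / (1 + lam),
               tolerance = 1e-8)

  # lambda -> Inf: slopes vanish, prediction collapses to the response mean
  rinf <- ridge_fit(x, y, lambda = 1e12)
  expect_true(all(abs(rinf$fit$coefficients) < 1e-6))
  expect_equal(rinf$fit$intercept, mean(y), tolerance = 1e-4)
})

test_that("automatic ridge lambda selection is deterministic and spans the grid", {
  x <- random_design(80, 10, seed = 67)
  set.seed(68)
  y <- x %*% c(rep(0.5, 3), rep(0, 7)) + rnorm(80)
  r1 <- ridge_fit(x, y)
  r2 <- ridge_fit(x, y)
  expect_identical(r1$fit$lambda, r2$fit$lambda)
  expect_true(r1$fit$lambda %in% 10^seq(-4, 6, length.out = 121))
  expect_length(r1$gcv, 121)
})

test_that("lasso obeys the L1 threshold and soft-thresholding closed forms", {
  q <- orthonormal_design(60, 8, seed = 71)
  set.seed(72)
  y <- q %*% c(3, -2, 1.5, rep(0, 5)) + rnorm(60, 0, 0.1)
  n <- nrow(q)

  # above the data-dependent maximum penalty every coefficient is zero
  lam_max <- max(abs(crossprod(q, y - mean(y)))) / n
  lbig <- lasso_fit(q, y, lambda = 10 * lam_max)
  expect_true(all(lbig$fit$coefficients == 0))

  # orthonormal design: coefficients equal soft-thresholded OLS values
  lam <- 0.02
  lf <- lasso_fit(q, y, lambda = lam, standardize = FALSE, intercept = FALSE)
  b <- drop(crossprod(q, y))
  st <- sign(b) * pmax(abs(b) - n * lam, 0)
  expect_equal(unname(lf$fit$coefficients), unname(st), tolerance = 1e-8)

  # monotone shrinkage along increasing lambda
  lams <- c(0.005, 0.02, 0.05)
  paths <- sapply(lams, function(l)
    abs(lasso_fit(q, y, lambda = l, standardize = FALSE,
                  intercept = FALSE)$fit$coefficients))
  expect_true(all(diff(t(paths)) <= 1e-8))
})

test_that("cross-validated lasso recovers planted causal SNPs", {
  hits <- 0L
  for (rep in 1:20) {
    d <- simulate_with_effects(
      simulation_spec(200, 30, maf = 0.3, causal = c(4, 15, 22),
                      beta = c(0.8, 0.8, 0.8), noise_sd = 1, seed = 100 + rep))
    lf <- lasso_fit(unclass(d$genotypes), d$phenotype, seed = rep)
    if (all(c("X4", "X15", "X22") %in% lf$nonzero)) hits <- hits + 1L
  }
  expect_gte(hits, 18)
})

test_that("significance flags always agree with the 0.01 cut-off (idempotent filter)", {
  d <- simulate_with_effects(
    simulation_spec(150, 12, maf = 0.3, causal = 5, beta = 1, noise_sd = 1,
                    seed = 73))
  x <- unclass(d$genotypes); y <- d$phenotype
  calls <- rbind(stepwise_forward(x, y, iteration = 1)$calls,
                 ridge_fit(x, y, iteration = 1)$calls,
                 lasso_fit(x, y, seed = 1, iteration = 1)$calls)
  expect_true(all(calls$significant == (calls$statistic <= 0.01)))
})
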