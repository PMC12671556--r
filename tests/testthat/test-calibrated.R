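# The calibrated-loss machinery: truncation, objectives, two-level
# cross-fitted fits and the resulting nuisance predictions.

test_that("linear-predictor truncation caps at twice the positivity constant", {
  expect_identical(truncate_linpred(0), 0)
  expect_equal(truncate_linpred(10, M = 2.2), 4.4)
  expect_equal(truncate_linpred(-10, M = 2.2), -4.4)
  expect_equal(truncate_linpred(-1, M = 2.2), -1)  # identity inside the cap
  expect_equal(plogis(2.2), 0.900, tolerance = 5e-4)  # M = 2.2 <-> [0.1, 0.9]
})

test_that("calibrated objectives: gradients, bounds, convexity, reductions", {
  set.seed(11)
  n <- 200; p <- 3
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  A <- rbinom(n, 1, plogis(X[, 2]))
  y <- rbinom(n, 1, plogis(0.5 * X[, 2] - 0.3 * X[, 3]))
  beta_i <- c(0.2, 0.5, -0.1, 0.3)
  alpha_i <- c(-0.1, 0.4, 0.2, 0)
  for (arm in c(1, 0)) {
    a0 <- rnorm(p + 1, sd = 0.3)
    # analytic gradient of the propensity loss vs central differences
    s <- if (arm == 1) -1 else 1
    gw <- smmal:::.gdot(truncate_linpred(drop(X %*% beta_i), 2.2))
    g_an <- colMeans(X * (gw * ((arm - A) +
                                  (A == arm) * s * exp(s * drop(X %*% a0)))))
    g_num <- num_grad(function(a)
      calib_ps_objective(a, X, A, beta_i, arm), a0)
    expect_equal(g_an, g_num, tolerance = 1e-6, ignore_attr = TRUE)
    # weight boundedness of both losses
    expect_true(all(gw >= smmal:::.gdot(4.4) - 1e-12 & gw <= 0.25))
    w_or <- exp(truncate_linpred(s * drop(X %*% (alpha_i * 50)), 2.2))
    expect_true(all(w_or >= exp(-4.4) - 1e-12 & w_or <= exp(4.4) + 1e-12))
    # convexity along random segments (midpoint inequality)
    for (f in list(function(v) calib_ps_objective(v, X, A, beta_i, arm),
                   function(v) calib_or_objective(v, X[A == arm, ],
                                                  y[A == arm], alpha_i,
                                                  arm))) {
      v1 <- rnorm(p + 1); v2 <- rnorm(p + 1)
      expect_lte(f((v1 + v2) / 2), (f(v1) + f(v2)) / 2 + 1e-10)
    }
  }
  # a zero initial propensity gives unit weights: plain logistic loss
  b <- rnorm(p + 1, sd = 0.2)
  eta <- drop(X[A == 1, ] %*% b)
  expect_equal(calib_or_objective(b, X[A == 1, ], y[A == 1],
                                  rep(0, p + 1), 1),
               mean(log1p(exp(eta)) - y[A == 1] * eta))
})

test_that("a single-arm calibrated propensity problem needs its penalty", {
  set.seed(12)
  n <- 100
  X <- cbind(1, rnorm(n), rnorm(n))
  A <- rep(1L, n)  # degenerate: loss mean(exp(-alpha'X)) is unbounded below
  gw <- rep(0.25, n)
  fit <- smmal:::.prox_solve(X, A, rep(1 / n, n), gw, 1L, 1L, lambda = 0.05,
                             pen = c(0, 1, 1), coef0 = rep(0, 3),
                             maxit = 2e4, tol = 1e-6, standardize = FALSE)
  expect_true(all(is.finite(fit$coef)))
  expect_true(fit$converged)
})

test_that("imputation and initial fits honor their training contracts", {
  sim <- hd_sim(N = 900, n_expected = 450, p = 12, seed = 13)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 3, seed = 2, check_pairs = TRUE)
  imp <- fit_imputation(co, folds, cv_folds = 4, seed = 3,
                        lambda_scope = "shared")
  expect_length(imp$xi, 3)
  expect_length(imp$xi[[1]], ncol(co$x) + ncol(co$s) + 1L)
  # flexible imputation: restricting the design to the surrogates works
  imp_s <- fit_imputation(co, folds, cv_folds = 4, seed = 3,
                          design_cols = c(13L, 14L))
  expect_length(imp_s$xi[[1]], 3L)
  init <- fit_initial(co, folds, cv_folds = 4, seed = 4,
                      lambda_scope = "shared")
  expect_setequal(names(init$alpha), c("1.2", "1.3", "2.3"))
  # initial fits depend only on the unordered excluded pair
  expect_identical(smmal:::.pair_key(3, 1), "1.3")
})

test_that("calibrated fits recover a correct sparse propensity model", {
  sim <- hd_sim(N = 1500, n_expected = 500, p = 50, seed = 17)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 3, seed = 5, check_pairs = TRUE)
  init <- fit_initial(co, folds, cv_folds = 4, seed = 6,
                      lambda_scope = "shared")
  cal <- fit_calibrated(co, folds, init, cv_folds = 4, seed = 7)
  alpha_star <- c(0, 0.5, 0.25, 0.125, rep(0, 47))
  # tolerance frozen from pilot runs of this configuration: the penalized
  # fits shrink the weak signals, leaving an l2 error well below the
  # null-model distance ||alpha*|| yet bounded away from zero
  err <- sapply(cal$alpha1, function(a) sqrt(sum((a - alpha_star)^2)))
  expect_lt(mean(err), 0.5)
  err0 <- sapply(cal$alpha0, function(a) sqrt(sum((a - alpha_star)^2)))
  expect_lt(mean(err0), 0.5)
  # calibration weights stayed within the truncation bounds
  expect_gte(cal$or_weight_range[1], exp(-4.4) - 1e-12)
  expect_lte(cal$or_weight_range[2], exp(4.4) + 1e-12)
  imp <- fit_imputation(co, folds, cv_folds = 4, seed = 8,
                        lambda_scope = "shared")
  pr <- predict_nuisances_hd(co, folds, imp, cal)
  expect_true(all(pr$pi1 >= plogis(-4.4) & pr$pi1 <= plogis(4.4)))
  expect_true(all(pr$pi0 >= plogis(-4.4) & pr$pi0 <= plogis(4.4)))
  # separate per-arm calibrations: the two propensities need not sum to 1
  expect_gt(max(abs(pr$pi1 + pr$pi0 - 1)), 1e-6)
  expect_equal(pr$Pi0, 1 - pr$Pi1)
})

test_that("the DR estimate is first-order insensitive to outcome-model error", {
  sim <- hd_sim(N = 1200, n_expected = 500, p = 20, seed = 19)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 3, seed = 3, check_pairs = TRUE)
  pr <- fit_nuisances_hd(co, folds, cv_folds = 4, seed = 4,
                         lambda_scope = "shared")
  Xd <- smmal:::design_x(co)
  set.seed(21)
  d <- rnorm(ncol(Xd)); d <- d / sqrt(sum(d^2))
  delta_at <- function(eps) {
    p2 <- pr
    shift <- eps * drop(Xd %*% d)
    p2$mu1 <- plogis(qlogis(pr$mu1) + shift)
    p2$mu0 <- plogis(qlogis(pr$mu0) + shift)
    smmal_estimate(co, p2)$delta
  }
  eps <- 0.05
  slope <- (delta_at(eps) - delta_at(-eps)) / (2 * eps)
  expect_lt(abs(slope), 0.05)
})
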