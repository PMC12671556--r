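test_that("the complete-data influence value vanishes and is linear in y", {
  expect_equal(phi_cmp(y = 0.7, a = 1, pi1 = 0.4, pi0 = 0.6,
                       mu1 = 0.7, mu0 = 0.2, delta = 0.5), 0)
  # slope in y for a treated subject is 1/pi1
  v1 <- phi_cmp(1, 1, 0.4, 0.6, 0.7, 0.2, 0.5)
  v0 <- phi_cmp(0, 1, 0.4, 0.6, 0.7, 0.2, 0.5)
  expect_equal(v1 - v0, 1 / 0.4)
})

test_that("unlabeled subjects contribute only the imputation plug-in line", {
  sim <- lowd_sim(N = 500, n_expected = 100, seed = 23)
  folds <- assign_folds(500, 4, seed = 1)
  pr <- oracle_preds(sim, folds)
  v <- influence_values(sim$cohort, pr, rho = 0.2)
  plug <- pr$mu1 + pr$Pi1 / pr$pi1 * (pr$m1 - pr$mu1) -
    pr$mu0 - pr$Pi0 / pr$pi0 * (pr$m0 - pr$mu0)
  un <- sim$cohort$r == 0L
  expect_identical(v[un], plug[un])
  expect_false(isTRUE(all.equal(v[!un], plug[!un])))
})

test_that("with full labels the estimator reduces exactly to complete-data AIPW", {
  # the imputation terms cancel algebraically when R = 1 and rho = 1
  sim <- lowd_sim(N = 400, n_expected = 399, seed = 29)
  co <- sim$cohort
  co$r <- rep(1L, co$N)
  co$a <- sim$truth$A_full
  co$y <- sim$truth$Y_full
  co$rho_hat <- 1
  folds <- assign_folds(co$N, 4, seed = 2)
  pr <- oracle_preds(sim, folds)
  v <- influence_values(co, pr, rho = 1)
  phi <- phi_cmp(co$y, co$a, pr$pi1, pr$pi0, pr$mu1, pr$mu0, 0)
  expect_lt(max(abs(v - phi)), 1e-12)
  est <- smmal_estimate(co, pr, rho = 1)
  expect_equal(est$delta, mean(phi), tolerance = 1e-13)
})

test_that("oracle-nuisance influence values are centered at the true ATE", {
  sim <- lowd_sim(N = 1e5, n_expected = 5000, seed = 31)
  folds <- assign_folds(1e5, 5, seed = 3)
  pr <- oracle_preds(sim, folds)
  v <- influence_values(sim$cohort, pr)
  expect_lt(abs(mean(v) - sim$truth$delta_star), 3 * sd(v) / sqrt(1e5))
  est <- smmal_estimate(sim$cohort, pr)
  expect_equal(est$delta, mean(v))
  expect_true(est$ci_low <= est$delta && est$delta <= est$ci_high)
  # variance bookkeeping: Eq-style plug-in recomputed directly
  expect_equal(est$V, est$rho_hat / 1e5 * sum((v - mean(v))^2))
  # the total uncertainty dominates the unlabeled (plug-in) component
  plug <- pr$mu1 + pr$Pi1 / pr$pi1 * (pr$m1 - pr$mu1) -
    pr$mu0 - pr$Pi0 / pr$pi0 * (pr$m0 - pr$mu0)
  expect_gte(est$V, est$rho_hat * var(plug) * 0.99)
})

test_that("the supervised benchmark is the reweighted labeled-subset AIPW", {
  sim <- lowd_sim(N = 2000, n_expected = 400, seed = 37)
  co <- sim$cohort
  folds <- assign_folds(2000, 4, seed = 4)
  pr <- oracle_preds(sim, folds)
  est <- supervised_estimate(co, pr)
  lab <- which(co$r == 1L)
  aipw <- mean(phi_cmp(co$y[lab], co$a[lab], pr$pi1[lab], pr$pi0[lab],
                       pr$mu1[lab], pr$mu0[lab], 0))
  # with rho_hat = n/N the two agree exactly: (1/N)(1/rho_hat) = 1/n
  expect_equal(est$delta, aipw, tolerance = 1e-12)
})

test_that("dichotomization matches prevalence and perfect surrogates recover AIPW", {
  sim <- lowd_sim(N = 1500, n_expected = 400, seed = 41)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 4, seed = 5)
  # prevalence matching of the thresholding rule
  prev <- mean(co$y[co$r == 1L])
  y_t <- smmal:::.dichotomize(co$s[, 2], prev)
  expect_lt(abs(mean(y_t) - prev), 1 / co$N + 1e-12)
  # perfect surrogates: cohort built so labeled prevalence equals the full
  # prevalence exactly, making the dichotomization the identity
  set.seed(41)
  N <- 800
  a_full <- rep(c(1L, 0L), N / 2)
  y_full <- rbinom(N, 1, 0.4)
  x <- matrix(runif(N), ncol = 1, dimnames = list(NULL, "X1"))
  co2 <- smmal:::.new_cohort(x, cbind(S_A = as.numeric(a_full),
                                      S_Y = as.numeric(y_full)),
                             a_full, y_full, rep(1L, N))
  folds2 <- assign_folds_checked(co2, 4, seed = 7)
  ul <- unsupervised_estimate(co2, folds2, cv_folds = 4, seed = 6)
  ref <- smmal:::.aipw_complete(x, a_full, y_full, folds2, cv_folds = 4,
                                seed = 6)
  expect_equal(ul$delta, ref$delta, tolerance = 1e-12)
  expect_error(unsupervised_estimate(
    within.list(co, s <- cbind(S_A = rep(0.5, co$N), S_Y = rep(0.5, co$N))),
    folds), "degenerate")
})

test_that("the ensemble weight is optimal, bounded and degenerates safely", {
  sim <- lowd_sim(N = 4000, n_expected = 600, seed = 43)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 4, seed = 6)
  pr <- oracle_preds(sim, folds)
  sm <- smmal_estimate(co, pr)
  sl <- supervised_estimate(co, pr)
  en <- ensemble_estimate(sm, sl)
  expect_true(en$b >= 0 && en$b <= 1)
  expect_lte(en$V, min(sm$V, sl$V) * 1.05)
  expect_true(en$ci_low <= en$delta && en$delta <= en$ci_high)
  # identical influence vectors: fall back to the SMMAL estimate
  expect_warning(same <- ensemble_estimate(sm, sm), "degenerate")
  expect_identical(same$delta, sm$delta)
})

test_that("crude comparators compute arm-mean differences", {
  sim <- lowd_sim(N = 1000, n_expected = 300, seed = 47)
  co <- sim$cohort
  cs <- crude_estimate(co, "sl")
  lab <- which(co$r == 1L)
  expect_equal(cs$delta, mean(co$y[lab][co$a[lab] == 1]) -
                 mean(co$y[lab][co$a[lab] == 0]))
  cu <- crude_estimate(co, "ul")
  expect_identical(cu$n, co$N)
})
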