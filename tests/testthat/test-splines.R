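test_that("tensor B-spline basis: dimensions, partition of unity, clamping", {
  x <- runif(50)
  B <- bspline_basis(x, degrees = 4, order = 1)
  expect_equal(ncol(B), 5)  # d + order columns in one dimension
  expect_equal(rowSums(B), rep(1, 50))
  # degree 1, order 1: the two hat functions {1 - t, t}
  B1 <- bspline_basis(x, 1, 1, boundary = list(lo = 0, hi = 1))
  expect_equal(B1[, 1], 1 - x)
  expect_equal(B1[, 2], x)
  # higher order and several dimensions keep the partition of unity
  X2 <- matrix(runif(80), ncol = 2)
  B2 <- bspline_basis(X2, degrees = c(3, 2), order = 2)
  expect_equal(ncol(B2), (3 + 2) * (2 + 2))
  expect_equal(rowSums(B2), rep(1, 40))
  # extrapolation beyond the boundary is clamped to it
  Bout <- bspline_basis(c(-5, 7), 3, 1, boundary = list(lo = 0, hi = 1))
  Bin <- bspline_basis(c(0, 1), 3, 1, boundary = list(lo = 0, hi = 1))
  expect_equal(Bout, Bin, ignore_attr = TRUE)
  expect_error(bspline_basis(c(1, NA), 2), "non-finite")
})

test_that("fast order-1 engine agrees with a maximum-likelihood oracle", {
  set.seed(5)
  n <- 600
  x <- runif(n)
  p <- plogis(2 * sin(3 * x))
  y <- rbinom(n, 1, p)
  fit <- spline_logit(x, y, degree = 4)
  B <- bspline_basis(x, 4, 1, boundary = list(lo = min(x), hi = max(x)))
  oracle <- glm.fit(B, y, family = binomial())
  expect_equal(predict(fit, x), oracle$fitted.values, tolerance = 1e-4,
               ignore_attr = TRUE)
  # two-dimensional tensor: compare against the dense in-R IRLS path
  X2 <- cbind(x, runif(n))
  y2 <- rbinom(n, 1, plogis(1.5 * X2[, 1] - X2[, 2]))
  fit2 <- spline_logit(X2, y2, degree = 2)
  B2 <- bspline_basis(X2, 2, 1, boundary = list(lo = apply(X2, 2, min),
                                                hi = apply(X2, 2, max)))
  ref <- plogis(drop(B2 %*% smmal:::.irls_dense(B2, y2)))
  expect_equal(predict(fit2, X2), ref, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("degree selection: candidate set, null and signal behavior", {
  set.seed(6)
  n <- 500
  x <- runif(n)
  # candidate set {1, ..., floor(sqrt(n))} in one dimension
  d_null <- select_degree_cv(x, rbinom(n, 1, 0.5), seed = 2)
  expect_length(attr(d_null, "entropy"), 22)
  expect_lte(d_null, 3)  # null signal: complexity near the minimum
  n2 <- 3000
  x2 <- runif(n2)
  y2 <- rbinom(n2, 1, plogis(2 * sin(6 * x2)))  # genuinely curved signal
  d_sig <- select_degree_cv(x2, y2, seed = 3)
  expect_gt(d_sig, 1)
})

test_that("cross-fitted spline nuisances: clipping, purity, degenerate arm", {
  sim <- lowd_sim(N = 1200, n_expected = 300, seed = 8)
  co <- sim$cohort
  folds <- assign_folds_checked(co, 4, seed = 2)
  pr <- fit_nuisances_spline(co, folds, seed = 3, cv_folds = 5)
  expect_true(all(pr$pi1 >= plogis(-2.2) & pr$pi1 <= plogis(2.2)))
  expect_equal(pr$pi0, 1 - pr$pi1)
  expect_true(all(is.finite(c(pr$mu1, pr$mu0, pr$Pi1, pr$m1, pr$m0))))
  # out-of-fold purity: perturbing a labeled row in fold 1 leaves fold-1
  # subjects' predictions untouched and changes some other fold's
  i <- which(co$r == 1L & folds$fold_of == 1L)[1]
  co2 <- co
  co2$y[i] <- 1 - co2$y[i]
  pr2 <- fit_nuisances_spline(co2, folds, seed = 3, cv_folds = 5)
  in1 <- folds$fold_of == 1L
  expect_identical(pr$mu1[in1], pr2$mu1[in1])
  expect_identical(pr$pi1[in1], pr2$pi1[in1])
  expect_false(identical(pr$mu1[!in1], pr2$mu1[!in1]) &&
                 identical(pr$mu0[!in1], pr2$mu0[!in1]))
  # a constant-outcome arm saturates to the clipped upper bound
  co3 <- co
  co3$y[co3$r == 1L & co3$a == 1L] <- 1
  pr3 <- fit_nuisances_spline(co3, folds, seed = 3, cv_folds = 5)
  expect_true(all(pr3$mu1 > 0.99))
})

test_that("nuisance errors shrink as the labeled set grows", {
  mses <- sapply(c(250, 2000), function(n) {
    sim <- lowd_sim(N = 4000, n_expected = n, seed = 31)
    folds <- assign_folds_checked(sim$cohort, 5, seed = 2)
    pr <- fit_nuisances_spline(sim$cohort, folds, seed = 4, cv_folds = 5)
    nuisance_mse(pr, sim$truth)
  })
  expect_true(all(mses[, 2] < mses[, 1]))
  # and at a large labeled set the propensity error is small in the
  # max-over-arms root-mean-square sense
  expect_lt(mses["pi", 2], 0.05)
  expect_lt(mses["mu", 2], 0.08)
})
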