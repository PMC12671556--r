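test_that("mixture Beta surrogate has the right moments, symmetry and domain", {
  set.seed(1)
  u <- 0.4; alpha <- 2.5; n <- 4e4
  s1 <- gen_surrogate(rep(1, n), u, alpha)
  expect_true(all(s1 > 0 & s1 < 1))
  # Beta(a, 1) mean a/(a+1)
  expect_equal(mean(s1), (alpha + u) / (alpha + u + 1), tolerance = 0.01)
  # Beta(1, b) is 1 - Beta(b, 1) in law
  s0 <- gen_surrogate(rep(0, n), u, alpha)
  qq <- seq(0.1, 0.9, by = 0.2)
  expect_equal(unname(quantile(s0, qq)),
               unname(1 - quantile(s1, rev(qq))), tolerance = 0.02)
  expect_error(gen_surrogate(1, 0.5, -1), "positive")
  expect_error(gen_surrogate(1, 1.2, 1), "strictly")
  expect_error(gen_surrogate(2, 0.5, 1), "binary")
})

test_that("MCAR labels hit the target rate and reject degenerate rates", {
  expect_error(mcar_labels(10, 0), "strictly")
  expect_error(mcar_labels(10, 1), "strictly")
  set.seed(2)
  r <- mcar_labels(10000, 0.05)
  expect_lt(abs(mean(r) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("low-d generator: smooth model truth, masking, reproducibility", {
  sim <- lowd_sim(N = 5000, n_expected = 250, seed = 11)
  co <- sim$cohort; tr <- sim$truth
  x <- co$x[, 1]
  # adopted grouping: pi*(1, x) = 1 - 1.2/(3 - x^2); at x = 0 this is 0.6
  expect_equal(tr$pi_star, 1 - 1.2 / (3 - x^2))
  expect_equal(smmal:::.lowd_pi1(0, "ratio_sq"), 0.6)
  expect_equal(tr$mu0_star, 1 - 1.2 / (3 - (1 - x)^2))
  expect_true(all(tr$pi_star > 0 & tr$pi_star < 1))
  expect_true(all(tr$mu0_star > 0 & tr$mu0_star < 1))
  expect_identical(tr$delta_star, 0)
  # masking: treatment/outcome present iff labeled; truth keeps latents
  expect_true(all(is.na(co$a[co$r == 0])))
  expect_true(all(!is.na(co$a[co$r == 1])))
  expect_true(all(!is.na(tr$A_full)))
  expect_identical(co$a[co$r == 1], tr$A_full[co$r == 1])
  # label count concentrates at the expected rate
  expect_lt(abs(sum(co$r) - 250), 4 * sqrt(5000 * 0.05 * 0.95))
  # bitwise reproducibility
  sim2 <- lowd_sim(N = 5000, n_expected = 250, seed = 11)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$truth, sim2$truth)
  # the alternative grouping also respects positivity and a zero ATE
  alt <- lowd_sim(N = 5000, n_expected = 250, seed = 11,
                  formula_reading = "sq_ratio")
  expect_true(all(alt$truth$pi_star > 0 & alt$truth$pi_star < 1))
  expect_identical(alt$truth$delta_star, 0)
  expect_identical(alt$cohort$meta$formula_reading, "sq_ratio")
})

test_that("low-d imputation truths are coherent posteriors", {
  sim <- lowd_sim(N = 20000, n_expected = 1000, seed = 3)
  tr <- sim$truth; co <- sim$cohort
  expect_true(all(tr$Pi1_star > 0 & tr$Pi1_star < 1))
  # E[A | bins of Pi*] tracks Pi* (posterior calibration)
  bins <- cut(tr$Pi1_star, quantile(tr$Pi1_star, 0:5 / 5),
              include.lowest = TRUE)
  obs <- tapply(tr$A_full, bins, mean)
  exp_ <- tapply(tr$Pi1_star, bins, mean)
  expect_lt(max(abs(obs - exp_)), 0.03)
  m_obs <- tapply(tr$Y_full[tr$A_full == 1], bins[tr$A_full == 1], mean)
  m_exp <- tapply(tr$m1_star[tr$A_full == 1], bins[tr$A_full == 1], mean)
  expect_lt(max(abs(m_obs - m_exp)), 0.05)
})

test_that("high-d generator: AR(1) structure, logistic models, masking", {
  sim <- simulate_cohort(sim_config("hd_linear_linear", N = 1e5,
                                    n_expected = 5000, p = 6, seed = 5),
                         truth_ate = list(delta = NA_real_, se = NA_real_))
  X <- sim$cohort$x
  # stationary AR(1) variance 0.5625 / (1 - 0.25) = 0.75
  expect_equal(var(X[, 6]), 0.75, tolerance = 0.02)
  expect_equal(cor(X[, 5], X[, 6]), 0.5 * sqrt(var(X[, 5]) / var(X[, 6])),
               tolerance = 0.02)
  # model values at X = 0 and at the unit directions (signal strengths)
  z <- matrix(0, 1, 3)
  mu <- smmal:::.hd_or(z, FALSE)
  expect_equal(mu$mu1, plogis(0.1))
  expect_equal(mu$mu0, plogis(-0.1))
  expect_equal(mu$mu1 - mu$mu0, 0.04996, tolerance = 1e-4)
  expect_equal(smmal:::.hd_ps(diag(3), FALSE), plogis(c(0.5, 0.25, 0.125)))
  # interaction reading: linear index times the second-order factor
  xr <- matrix(c(1, -0.5, 0.25), 1, 3)
  lin <- 0.5 * 1 + 0.25 * -0.5 + 0.125 * 0.25
  fac <- 1 + 0.0625 * 1 + 0.125 * -0.5 - 0.5 * 0.25
  expect_equal(smmal:::.hd_ps(xr, TRUE), plogis(lin * fac))
  expect_error(sim_config("hd_linear_linear", p = 2), "X1..X3")
  expect_true(all(is.na(sim$cohort$y[sim$cohort$r == 0])))
})

test_that("high-d ATE oracle is reproducible and tracks the outcome gap", {
  o1 <- hd_true_ate("hd_linear_linear", n_mc = 2e5, seed = 9)
  o2 <- hd_true_ate("hd_linear_linear", n_mc = 2e5, seed = 9)
  expect_identical(o1, o2)
  expect_gt(o1$delta, 0.04)
  expect_lt(o1$delta, 0.06)
  expect_gt(o1$se, 0)
})

test_that("surrogate AUC matches its calibration and the closed form", {
  auc80 <- surrogate_auc("lowd_smooth", 1.39, "A", n_mc = 2e5, seed = 1)
  expect_equal(auc80, 0.80, tolerance = 0.012)
  auc95 <- surrogate_auc("lowd_smooth", 2.54, "A", n_mc = 2e5, seed = 1)
  expect_equal(auc95, 0.95, tolerance = 0.012)
  # AUC rises with the shape offset toward 1
  aucP <- surrogate_auc("lowd_smooth", 5.49, "A", n_mc = 2e5, seed = 1)
  expect_gt(aucP, auc95)
  expect_gt(aucP, 0.99)
  # conditional closed form P(Beta(a1,1) > Beta(1,a0)) = 1 - a1 B(a1, a0+1)
  cf <- smmal:::.surrogate_auc_closed_form("lowd_smooth", 2.54, "A",
                                           n_mc = 2e5, seed = 1)
  expect_equal(auc95, cf, tolerance = 0.006)
  expect_error(surrogate_auc("lowd_smooth", 2.54, "A", n_mc = 100), "1e4")
})

test_that("cohort CSV round-trip preserves data and masking", {
  sim <- lowd_sim(N = 300, n_expected = 60, seed = 21)
  f <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, f, truth = sim$truth, truth_file = ft)
  back <- read_cohort(f)
  expect_equal(back$x, sim$cohort$x, ignore_attr = TRUE)
  expect_equal(back$s, sim$cohort$s, ignore_attr = TRUE)
  expect_identical(back$r, sim$cohort$r)
  expect_identical(back$a, sim$cohort$a)
  expect_true(all(is.na(back$y[back$r == 0])))
  hdr <- readLines(ft, n = 1)
  expect_match(hdr, "delta_star=0")
  unlink(c(f, ft))
})
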