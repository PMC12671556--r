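# Shared fixtures: all data are generated in code at test time.

lowd_sim <- function(N = 2000, n_expected = 300, seed = 7, alpha_A = 2.54,
                     alpha_Y = 2.57, ...) {
  simulate_cohort(sim_config("lowd_smooth", N = N, n_expected = n_expected,
                             alpha_A = alpha_A, alpha_Y = alpha_Y,
                             seed = seed, ...))
}

hd_sim <- function(N = 1500, n_expected = 400, p = 20, seed = 7,
                   scenario = "hd_linear_linear") {
  simulate_cohort(sim_config(scenario, N = N, n_expected = n_expected,
                             p = p, seed = seed),
                  truth_ate = list(delta = NA_real_, se = NA_real_))
}

# nuisance predictions filled with the generator's truth (only available
# for the low-dimensional design, where the imputation truth is closed
# form)
oracle_preds <- function(sim, folds) {
  tr <- sim$truth
  structure(list(pi1 = tr$pi_star, pi0 = 1 - tr$pi_star,
                 mu1 = tr$mu1_star, mu0 = tr$mu0_star,
                 Pi1 = tr$Pi1_star, Pi0 = 1 - tr$Pi1_star,
                 m1 = tr$m1_star, m0 = tr$m0_star,
                 fold_of = folds$fold_of, K = folds$K, M = Inf,
                 pi_bounds = c(0, 1), nuisance = "oracle"),
            class = "nuisance_preds")
}

# numerical gradient of a scalar function, central differences
num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
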