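# Synthetic cohort generator: semi-supervised cohorts with mixture-Beta
# surrogates, MCAR labels, and known nuisance truth for recovery tests.

# Independent RNG substream per stochastic component so that changing one
# generator knob perturbs only its own stream.
.substream <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% 2147483629L)
}
.STREAM <- c(x = 11L, a = 22L, y = 33L, s_a = 44L, s_y = 55L, r = 66L,
             truth = 77L)

#' Simulation configuration
#'
#' Describes one of the four study designs of the simulation suite: a
#' one-dimensional smooth-model design (`lowd_smooth`) and three
#' high-dimensional logistic designs on AR(1)-correlated Gaussian
#' confounders (`hd_linear_linear`, `hd_psinteraction_orlinear`,
#' `hd_pslinear_orinteraction`).
#'
#' @param scenario one of `"lowd_smooth"`, `"hd_linear_linear"`,
#'   `"hd_psinteraction_orlinear"`, `"hd_pslinear_orinteraction"`.
#' @param N total number of subjects.
#' @param n_expected expected number of labeled subjects; the labeling
#'   rate is `rho = n_expected / N`.
#' @param alpha_A,alpha_Y positive Beta shape offsets controlling how well
#'   the treatment/outcome surrogate discriminates its latent label; see
#'   [surrogate_alpha()] for calibrations to marginal AUC values.
#' @param p confounder dimension; forced to 1 for `lowd_smooth`, default
#'   500 for the high-dimensional designs.
#' @param seed integer seed; identical configurations are bitwise
#'   reproducible.
#' @param formula_reading grouping convention for the smooth low-d model:
#'   `"ratio_sq"` (default) reads the propensity as
#'   \eqn{1 - 1.2/(3 - X^2)}, `"sq_ratio"` as \eqn{1 - 1.2/(3 - X)^2}.
#'   Both keep probabilities inside (0,1) and both give a true ATE of 0.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("lowd_smooth", "hd_linear_linear",
                                    "hd_psinteraction_orlinear",
                                    "hd_pslinear_orinteraction"),
                       N = 10000L, n_expected = 500L,
                       alpha_A = 2.54, alpha_Y = 2.57,
                       p = NULL, seed = 1L,
                       formula_reading = c("ratio_sq", "sq_ratio")) {
  scenario <- match.arg(scenario)
  formula_reading <- match.arg(formula_reading)
  N <- as.integer(N); n_expected <- as.integer(n_expected)
  if (N <= 0L || n_expected <= 0L || n_expected >= N)
    stop("need 0 < n_expected < N")
  if (alpha_A <= 0 || alpha_Y <= 0)
    stop("alpha_A and alpha_Y must be positive")
  if (scenario == "lowd_smooth") {
    p <- 1L
  } else {
    p <- if (is.null(p)) 500L else as.integer(p)
    if (p < 3L) stop("high-dimensional designs reference X1..X3; need p >= 3")
  }
  structure(list(scenario = scenario, N = N, n_expected = n_expected,
                 rho = n_expected / N, alpha_A = alpha_A, alpha_Y = alpha_Y,
                 p = p, seed = as.integer(seed),
                 formula_reading = formula_reading),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation design:", x$scenario, "\n")
  cat(sprintf("  N = %d, expected labels = %d (rho = %.4g)\n",
              x$N, x$n_expected, x$rho))
  cat(sprintf("  alpha_A = %.3g, alpha_Y = %.3g, p = %d, seed = %d\n",
              x$alpha_A, x$alpha_Y, x$p, x$seed))
  if (x$scenario == "lowd_smooth")
    cat("  smooth-model reading:", x$formula_reading, "\n")
  invisible(x)
}

#' Surrogate quality calibrations
#'
#' Beta shape offsets calibrated per design so that the marginal AUC of the
#' surrogate for its latent label hits a requested value.  The calibration
#' differs slightly between designs because the marginal label prevalence
#' differs.
#'
#' @param setting simulation design name as in [sim_config()].
#' @param auc one of 0.80, 0.90, 0.95, 0.99, 0.999 (also accepted as
#'   `"ok"`, `"reasonable"`, `"good"`, `"great"`, `"perfect"`).
#' @param which `"A"` for the treatment surrogate, `"Y"` for the outcome
#'   surrogate.
#' @return the alpha shape offset.
#' @export
surrogate_alpha <- function(setting, auc, which = c("A", "Y")) {
  which <- match.arg(which)
  lev <- c("0.8" = 1L, "0.9" = 2L, "0.95" = 3L, "0.99" = 4L, "0.999" = 5L,
           ok = 1L, reasonable = 2L, good = 3L, great = 4L, perfect = 5L)
  key <- as.character(auc)
  if (!key %in% names(lev)) stop("unknown AUC level: ", auc)
  j <- lev[[key]]
  tab <- list(
    lowd_smooth = list(A = c(1.39, 1.99, 2.54, 3.86, 5.49),
                       Y = c(1.39, 1.96, 2.57, 3.80, 5.70)),
    hd_linear_linear = list(A = c(1.36, 1.99, 2.54, 3.80, 5.64),
                            Y = c(1.33, 1.96, 2.51, 3.89, 5.55)),
    hd_psinteraction_orlinear = list(A = c(1.36, 1.96, 2.54, 3.80, 5.55),
                                     Y = c(1.39, 1.93, 2.54, 3.74, 5.52)),
    hd_pslinear_orinteraction = list(A = c(1.36, 1.96, 2.54, 3.80, 5.55),
                                     Y = c(1.39, 1.93, 2.54, 3.74, 5.52)))
  if (!setting %in% names(tab)) stop("unknown setting: ", setting)
  tab[[setting]][[which]][j]
}

#' Draw one mixture-Beta surrogate
#'
#' A surrogate for a binary latent `value` mimicking the bounded score of a
#' phenotyping algorithm: `Beta(alpha + u, 1)` when the latent is 1 and
#' `Beta(1, alpha + u)` when it is 0, where `u` in (0,1) is a covariate
#' level that shifts the score distribution.
#'
#' @param value binary latent label(s).
#' @param u covariate level(s) in (0,1).
#' @param alpha positive shape offset; larger values separate the two
#'   mixture components more and raise the surrogate's AUC.
#' @return numeric draw(s) in (0,1); vectorized over `value` and `u`.
#' @export
gen_surrogate <- function(value, u, alpha) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0,1)")
  if (any(!value %in% c(0, 1))) stop("value must be binary")
  n <- max(length(value), length(u))
  value <- rep_len(value, n); u <- rep_len(u, n)
  sh <- alpha + u
  rbeta(n, shape1 = ifelse(value == 1, sh, 1),
        shape2 = ifelse(value == 1, 1, sh))
}

#' Missing-completely-at-random label indicators
#'
#' @param N cohort size.
#' @param rho labeling probability, strictly inside (0,1).
#' @return integer 0/1 vector of length `N`, iid Bernoulli(`rho`).
#' @export
mcar_labels <- function(N, rho) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly in (0,1)")
  rbinom(N, 1L, rho)
}

# --- low-dimensional smooth truth -----------------------------------------

.lowd_pi1 <- function(x, reading) {
  if (reading == "ratio_sq") 1 - 1.2 / (3 - x^2) else 1 - 1.2 / (3 - x)^2
}
.lowd_mu0 <- function(x, reading) .lowd_pi1(1 - x, reading)

# Beta mixture component densities, shape offset ab = alpha + u
.dsurr1 <- function(s, ab) ab * s^(ab - 1)        # latent = 1
.dsurr0 <- function(s, ab) ab * (1 - s)^(ab - 1)  # latent = 0

# Exact posterior imputation truths for the low-d design:
#   m*(a, W)  = P(Y = 1 | A = a, X, S_Y)   (S_A drops out given A)
#   Pi*(1, W) = P(A = 1 | X, S_A, S_Y)
.lowd_imputation_truth <- function(x, s_a, s_y, alpha_A, alpha_Y, reading) {
  pi1 <- .lowd_pi1(x, reading)
  mu1 <- pi1
  mu0 <- .lowd_mu0(x, reading)
  aby <- alpha_Y + x; aba <- alpha_A + x
  fy1 <- .dsurr1(s_y, aby); fy0 <- .dsurr0(s_y, aby)
  m1 <- mu1 * fy1 / (mu1 * fy1 + (1 - mu1) * fy0)
  m0 <- mu0 * fy1 / (mu0 * fy1 + (1 - mu0) * fy0)
  lik1 <- .dsurr1(s_a, aba) * pi1 * (mu1 * fy1 + (1 - mu1) * fy0)
  lik0 <- .dsurr0(s_a, aba) * (1 - pi1) * (mu0 * fy1 + (1 - mu0) * fy0)
  list(Pi1 = lik1 / (lik1 + lik0), m1 = m1, m0 = m0)
}

.new_cohort <- function(x, s, a, y, r, meta = list()) {
  a <- as.integer(a); y <- as.numeric(y); r <- as.integer(r)
  a[r == 0L] <- NA_integer_
  y[r == 0L] <- NA_real_
  structure(list(x = x, s = s, a = a, y = y, r = r,
                 N = nrow(x), p = ncol(x), q = ncol(s),
                 rho_hat = mean(r), meta = meta),
            class = "ssl_cohort")
}

#' @export
print.ssl_cohort <- function(x, ...) {
  cat(sprintf(
    "Semi-supervised cohort: N = %d, labeled n = %d (rho_hat = %.4g)\n",
    x$N, sum(x$r), x$rho_hat))
  cat(sprintf("  %d confounder(s), %d surrogate(s)\n", x$p, x$q))
  if (!is.null(x$meta$scenario)) cat("  generated from:", x$meta$scenario, "\n")
  invisible(x)
}

.new_truth <- function(delta, delta_se, pi1, mu1, mu0, a_full, y_full,
                       scenario, extra = list()) {
  structure(c(list(delta_star = delta, delta_se = delta_se,
                   pi_star = pi1, mu1_star = mu1, mu0_star = mu0,
                   A_full = as.integer(a_full), Y_full = as.numeric(y_full),
                   scenario = scenario), extra),
            class = "sim_truth")
}

#' Generate the low-dimensional smooth cohort
#'
#' One uniform confounder; the propensity and treated-arm outcome model
#' share the same smooth curve and the control-arm model is its mirror
#' image in `X`, so the true ATE is exactly zero by symmetry.
#'
#' @param config a [sim_config()] with `scenario = "lowd_smooth"`.
#' @return list with elements `cohort` (an `ssl_cohort`) and `truth`
#'   (a `sim_truth` carrying the per-subject true nuisance values, the
#'   latent treatment/outcome before masking, and closed-form imputation
#'   truths).
#' @export
gen_lowd <- function(config) {
  if (!inherits(config, "sim_config") || config$scenario != "lowd_smooth")
    stop("config must be a sim_config with scenario 'lowd_smooth'")
  N <- config$N; rd <- config$formula_reading
  .substream(config$seed, .STREAM["x"])
  x <- runif(N)
  pi1 <- .lowd_pi1(x, rd)
  mu1 <- pi1
  mu0 <- .lowd_mu0(x, rd)
  .substream(config$seed, .STREAM["a"])
  a <- rbinom(N, 1L, pi1)
  .substream(config$seed, .STREAM["y"])
  y <- rbinom(N, 1L, ifelse(a == 1L, mu1, mu0))
  .substream(config$seed, .STREAM["s_a"])
  s_a <- gen_surrogate(a, x, config$alpha_A)
  .substream(config$seed, .STREAM["s_y"])
  s_y <- gen_surrogate(y, x, config$alpha_Y)
  .substream(config$seed, .STREAM["r"])
  r <- mcar_labels(N, config$rho)
  xm <- matrix(x, ncol = 1, dimnames = list(NULL, "X1"))
  sm <- cbind(S_A = s_a, S_Y = s_y)
  imp <- .lowd_imputation_truth(x, s_a, s_y, config$alpha_A, config$alpha_Y, rd)
  cohort <- .new_cohort(xm, sm, a, y, r,
                        meta = list(scenario = config$scenario,
                                    formula_reading = rd,
                                    seed = config$seed))
  truth <- .new_truth(0, 0, pi1, mu1, mu0, a, y, config$scenario,
                      extra = list(Pi1_star = imp$Pi1, m1_star = imp$m1,
                                   m0_star = imp$m0))
  list(cohort = cohort, truth = truth)
}

# linear indices and nuisance curves for the high-dimensional designs
.hd_ps <- function(X, interaction) {
  l <- 0.5 * X[, 1] + 0.25 * X[, 2] + 0.125 * X[, 3]
  if (interaction)
    l <- l * (1 + 0.0625 * X[, 1] + 0.125 * X[, 2] - 0.5 * X[, 3])
  plogis(l)
}
.hd_or <- function(X, interaction) {
  l1 <- 0.1 + 0.25 * X[, 1] + 0.125 * X[, 2] + 0.0625 * X[, 3]
  l0 <- -l1
  if (interaction) {
    f <- 1 + 0.0625 * X[, 1] + 0.125 * X[, 2] - 0.5 * X[, 3]
    l1 <- l1 * f; l0 <- l0 * f
  }
  list(mu1 = plogis(l1), mu0 = plogis(l0))
}

.hd_draw_x <- function(N, p) {
  X <- matrix(rnorm(N * p), N, p)
  for (j in seq_len(p)[-1]) X[, j] <- 0.5 * X[, j - 1] + 0.75 * X[, j]
  colnames(X) <- paste0("X", seq_len(p))
  X
}

#' Monte-Carlo oracle for the true ATE of a high-dimensional design
#'
#' The outcome models only involve the first three confounders, so the
#' oracle integrates \eqn{\mu^*(1,X) - \mu^*(0,X)} over a fresh draw of
#' those coordinates.
#'
#' @param scenario a high-dimensional scenario name.
#' @param n_mc Monte-Carlo size (default 1e6).
#' @param seed RNG seed for the fresh draw.
#' @return list with `delta` and its Monte-Carlo standard error `se`.
#' @export
hd_true_ate <- function(scenario, n_mc = 1e6, seed = 1L) {
  or_int <- scenario == "hd_pslinear_orinteraction"
  if (!scenario %in% c("hd_linear_linear", "hd_psinteraction_orlinear",
                       "hd_pslinear_orinteraction"))
    stop("not a high-dimensional scenario: ", scenario)
  .substream(seed, .STREAM["truth"])
  X <- .hd_draw_x(n_mc, 3L)
  mu <- .hd_or(X, or_int)
  d <- mu$mu1 - mu$mu0
  list(delta = mean(d), se = sd(d) / sqrt(n_mc))
}

#' Generate a high-dimensional logistic cohort
#'
#' AR(1)-correlated Gaussian confounders (`X1 = U1`,
#' `Xj = 0.5 X_{j-1} + 0.75 Uj`) with logistic propensity and outcome
#' models on the first three coordinates, using signal strengths
#' 0.5 / 0.25 / 0.125 / 0.0625.  The interaction variants multiply the
#' linear index by a second-order factor, creating model mis-specification
#' for linear-logistic working models.
#'
#' @param config a [sim_config()] with a high-dimensional scenario.
#' @param truth_ate optional precomputed result of [hd_true_ate()] (saves
#'   the Monte-Carlo integration when simulating many replicates).
#' @return list with `cohort` and `truth` as in [gen_lowd()].
#' @export
gen_hd <- function(config, truth_ate = NULL) {
  if (!inherits(config, "sim_config") ||
      !startsWith(config$scenario, "hd_"))
    stop("config must be a sim_config with a high-dimensional scenario")
  N <- config$N; p <- config$p
  ps_int <- config$scenario == "hd_psinteraction_orlinear"
  or_int <- config$scenario == "hd_pslinear_orinteraction"
  .substream(config$seed, .STREAM["x"])
  X <- .hd_draw_x(N, p)
  pi1 <- .hd_ps(X, ps_int)
  mu <- .hd_or(X, or_int)
  .substream(config$seed, .STREAM["a"])
  a <- rbinom(N, 1L, pi1)
  .substream(config$seed, .STREAM["y"])
  y <- rbinom(N, 1L, ifelse(a == 1L, mu$mu1, mu$mu0))
  u <- pnorm(X[, 1])
  .substream(config$seed, .STREAM["s_a"])
  s_a <- gen_surrogate(a, u, config$alpha_A)
  .substream(config$seed, .STREAM["s_y"])
  s_y <- gen_surrogate(y, u, config$alpha_Y)
  .substream(config$seed, .STREAM["r"])
  r <- mcar_labels(N, config$rho)
  if (is.null(truth_ate))
    truth_ate <- hd_true_ate(config$scenario, seed = config$seed)
  cohort <- .new_cohort(X, cbind(S_A = s_a, S_Y = s_y), a, y, r,
                        meta = list(scenario = config$scenario,
                                    seed = config$seed))
  truth <- .new_truth(truth_ate$delta, truth_ate$se, pi1, mu$mu1, mu$mu0,
                      a, y, config$scenario)
  list(cohort = cohort, truth = truth)
}

#' Simulate a cohort from any configured design
#'
#' @param config a [sim_config()].
#' @param truth_ate optional precomputed ATE oracle for the
#'   high-dimensional designs.
#' @return list with `cohort` and `truth`.
#' @export
simulate_cohort <- function(config, truth_ate = NULL) {
  if (config$scenario == "lowd_smooth") gen_lowd(config)
  else gen_hd(config, truth_ate = truth_ate)
}

.auc_rank <- function(score, label) {
  n1 <- as.numeric(sum(label == 1)); n0 <- as.numeric(sum(label == 0))
  if (n1 == 0 || n0 == 0) stop("need both classes for an AUC")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Marginal surrogate AUC under a simulation design
#'
#' Monte-Carlo estimate of the AUC of the surrogate as a classifier of its
#' latent label, under the joint law of (latent label, covariate level)
#' implied by the design.
#'
#' @param scenario design name as in [sim_config()].
#' @param alpha Beta shape offset of the surrogate.
#' @param which `"A"` or `"Y"`.
#' @param n_mc Monte-Carlo cohort size (at least 1e4).
#' @param seed RNG seed.
#' @return estimated AUC in (0,1).
#' @export
surrogate_auc <- function(scenario, alpha, which = c("A", "Y"),
                          n_mc = 1e6, seed = 1L) {
  which <- match.arg(which)
  if (n_mc < 1e4) stop("n_mc must be at least 1e4")
  if (alpha <= 0) stop("alpha must be positive")
  d <- .surrogate_latents(scenario, n_mc, seed)
  lab <- if (which == "A") d$a else d$y
  set.seed(seed + 101L)
  s <- gen_surrogate(lab, d$u, alpha)
  .auc_rank(s, lab)
}

# latent labels and the surrogate covariate level u for a design
.surrogate_latents <- function(scenario, n_mc, seed) {
  set.seed(seed)
  if (scenario == "lowd_smooth") {
    x <- runif(n_mc)
    pi1 <- .lowd_pi1(x, "ratio_sq")
    a <- rbinom(n_mc, 1L, pi1)
    y <- rbinom(n_mc, 1L, ifelse(a == 1L, pi1, .lowd_mu0(x, "ratio_sq")))
    list(u = x, a = a, y = y)
  } else {
    ps_int <- scenario == "hd_psinteraction_orlinear"
    or_int <- scenario == "hd_pslinear_orinteraction"
    X <- .hd_draw_x(n_mc, 3L)
    pi1 <- .hd_ps(X, ps_int)
    mu <- .hd_or(X, or_int)
    a <- rbinom(n_mc, 1L, pi1)
    y <- rbinom(n_mc, 1L, ifelse(a == 1L, mu$mu1, mu$mu0))
    list(u = pnorm(X[, 1]), a = a, y = y)
  }
}

# Closed-form check of the same AUC: conditionally on covariate levels
# (u1, u0) of a positive/negative pair, P(S+ > S-) = 1 - a1 B(a1, a0 + 1)
# with a1 = alpha + u1, a0 = alpha + u0; average over label-conditional
# covariate draws.  Used as an independent oracle in tests.
.surrogate_auc_closed_form <- function(scenario, alpha, which, n_mc, seed) {
  d <- .surrogate_latents(scenario, n_mc, seed)
  lab <- if (which == "A") d$a else d$y
  u1 <- d$u[lab == 1]; u0 <- d$u[lab == 0]
  set.seed(seed + 202L)
  m <- min(2e5, as.numeric(length(u1)) * as.numeric(length(u0)))
  a1 <- alpha + sample(u1, m, replace = TRUE)
  a0 <- alpha + sample(u0, m, replace = TRUE)
  mean(1 - a1 * beta(a1, a0 + 1))
}

#' Write a simulated cohort (and optional truth) to CSV
#'
#' Columns `id,R,A,Y,S_A,S_Y,X1..Xp`, with empty cells for the masked
#' treatment/outcome of unlabeled subjects.  The truth file carries a
#' leading comment line with the true ATE and its Monte-Carlo SE.
#'
#' @param cohort an `ssl_cohort`.
#' @param file path for the cohort CSV.
#' @param truth optional `sim_truth`.
#' @param truth_file path for the truth CSV when `truth` is given.
#' @export
write_cohort <- function(cohort, file, truth = NULL, truth_file = NULL) {
  df <- data.frame(id = seq_len(cohort$N), R = cohort$r,
                   A = cohort$a, Y = cohort$y)
  df <- cbind(df, as.data.frame(cohort$s), as.data.frame(cohort$x))
  write.csv(df, file, row.names = FALSE, na = "")
  if (!is.null(truth)) {
    if (is.null(truth_file)) stop("truth_file required when truth is given")
    con <- file(truth_file, "w")
    on.exit(close(con))
    writeLines(sprintf("# delta_star=%.17g delta_se=%.17g",
                       truth$delta_star, truth$delta_se), con)
    tdf <- data.frame(id = seq_len(cohort$N), pi_star = truth$pi_star,
                      mu1_star = truth$mu1_star, mu0_star = truth$mu0_star,
                      A_full = truth$A_full, Y_full = truth$Y_full)
    write.csv(tdf, con, row.names = FALSE)
  }
  invisible(file)
}

#' Read a cohort CSV written by [write_cohort()] (or matching its layout)
#'
#' @param file path to the CSV.
#' @param roles optional named list remapping column roles, with entries
#'   `r`, `a`, `y`, `s` (character vector), `x` (character vector).
#' @return an `ssl_cohort`.
#' @export
read_cohort <- function(file, roles = NULL) {
  df <- read.csv(file)
  if (is.null(roles)) {
    xcols <- grep("^X[0-9]+$", names(df), value = TRUE)
    scols <- intersect(c("S_A", "S_Y"), names(df))
    roles <- list(r = "R", a = "A", y = "Y", s = scols, x = xcols)
  }
  x <- as.matrix(df[roles$x]); s <- as.matrix(df[roles$s])
  .new_cohort(x, s, df[[roles$a]], df[[roles$y]], df[[roles$r]],
              meta = list(source = file))
}
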