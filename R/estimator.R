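# Influence-function assembly and the family of ATE estimators: SMMAL,
# the supervised cross-fitted DML benchmark, the unsupervised
# dichotomized-surrogate benchmark, crude means, and the optimal linear
# ensemble.

#' Complete-data efficient influence value
#'
#' The augmented inverse-probability-weighting (AIPW) influence function
#' for the ATE with fully observed treatment and outcome:
#' \deqn{\mu(1,X) - \mu(0,X) + \frac{I(A=1)(Y - \mu(1,X))}{\pi(1,X)}
#'   - \frac{I(A=0)(Y - \mu(0,X))}{\pi(0,X)} - \Delta.}
#'
#' @param y outcome, `a` treatment (vectors).
#' @param a treatment indicator.
#' @param pi1,pi0,mu1,mu0 nuisance values per subject.
#' @param delta centering value (the ATE).
#' @return influence values.
#' @export
phi_cmp <- function(y, a, pi1, pi0, mu1, mu0, delta) {
  mu1 - mu0 + (a == 1) * (y - mu1) / pi1 - (a == 0) * (y - mu0) / pi0 - delta
}

#' Semi-supervised influence values
#'
#' Per-subject estimated influence values whose cohort average is the
#' SMMAL point estimate.  The first (imputation-augmented plug-in) block
#' is evaluated for everyone; labeled subjects add the inverse-probability
#' corrections scaled by `1/rho`.  Masked treatment/outcome of unlabeled
#' subjects are never touched.
#'
#' @param cohort an `ssl_cohort`.
#' @param preds a `nuisance_preds` object for the same cohort.
#' @param rho labeling proportion used in the weighting (usually the
#'   empirical `cohort$rho_hat`).
#' @return numeric vector of length `N`.
#' @export
influence_values <- function(cohort, preds, rho = cohort$rho_hat) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  if (is.null(preds$Pi1))
    stop("nuisance predictions lack the imputation models")
  v <- preds$mu1 + preds$Pi1 / preds$pi1 * (preds$m1 - preds$mu1) -
    preds$mu0 - preds$Pi0 / preds$pi0 * (preds$m0 - preds$mu0)
  lab <- which(cohort$r == 1L)
  a <- cohort$a[lab]; y <- cohort$y[lab]
  if (anyNA(a) || anyNA(y))
    stop("labeled subject with missing treatment or outcome")
  p1 <- preds$pi1[lab]; p0 <- preds$pi0[lab]
  m1 <- preds$mu1[lab]; m0 <- preds$mu0[lab]
  v[lab] <- v[lab] +
    ((a == 1) * y - (a == 1) * m1) / (rho * p1) -
    ((a == 0) * y - (a == 0) * m0) / (rho * p0) -
    (preds$Pi1[lab] * preds$m1[lab] - preds$Pi1[lab] * m1) / (rho * p1) +
    (preds$Pi0[lab] * preds$m0[lab] - preds$Pi0[lab] * m0) / (rho * p0)
  v
}

.new_estimate <- function(method, delta, V, n, N, rho_hat, K, level,
                          influence = NULL, extra = list()) {
  se <- sqrt(V / n)
  z <- qnorm(1 - (1 - level) / 2)
  structure(c(list(method = method, delta = delta, V = V, se = se,
                   ci_low = delta - z * se, ci_high = delta + z * se,
                   level = level, n = n, N = N, rho_hat = rho_hat, K = K,
                   influence = influence), extra),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE estimate (%s): %.5f  [%s%% CI %.5f, %.5f]\n",
              x$method, x$delta, format(100 * x$level), x$ci_low, x$ci_high))
  cat(sprintf("  se = %.5f on n = %d labels (N = %d, rho_hat = %.4g)\n",
              x$se, x$n, x$N, x$rho_hat))
  invisible(x)
}

#' SMMAL estimate of the average treatment effect
#'
#' Averages the estimated semi-supervised influence values over the whole
#' cohort; the variance of the root-n-scaled error is estimated by
#' `rho_hat` times the empirical variance of the influence values over
#' all `N` subjects, capturing the uncertainty from both the labeled and
#' the (large but finite) unlabeled data.
#'
#' @param cohort an `ssl_cohort`.
#' @param preds a `nuisance_preds` with imputation models.
#' @param level confidence level (default 0.95).
#' @param rho labeling proportion; defaults to the empirical `rho_hat`,
#'   override only for a known design sampling fraction.
#' @param method label stored on the estimate (`"smmal"`; the
#'   high-dimensional route conventionally reports `"smmal_dr"`).
#' @return an `ate_estimate`; `delta` equals the mean influence value.
#' @export
smmal_estimate <- function(cohort, preds, level = 0.95,
                           rho = cohort$rho_hat, method = "smmal") {
  n <- sum(cohort$r)
  if (n == 0L) stop("no labeled subjects")
  v <- influence_values(cohort, preds, rho)
  delta <- mean(v)
  V <- rho / cohort$N * sum((v - delta)^2)
  .new_estimate(method, delta, V, n, cohort$N, cohort$rho_hat, preds$K,
                level, influence = v)
}

#' Supervised cross-fitted DML benchmark
#'
#' The labeled-subset AIPW estimator with the same cross-fitted propensity
#' and outcome models, reweighted by `1/rho_hat` so that it averages over
#' the whole cohort index.  Uses no surrogate information.
#'
#' @inheritParams smmal_estimate
#' @return an `ate_estimate` with influence values
#'   `(R/rho)(phi_cmp + delta)`.
#' @export
supervised_estimate <- function(cohort, preds, level = 0.95,
                                rho = cohort$rho_hat) {
  n <- sum(cohort$r)
  if (n == 0L) stop("no labeled subjects")
  v <- numeric(cohort$N)
  lab <- which(cohort$r == 1L)
  a <- cohort$a[lab]; y <- cohort$y[lab]
  v[lab] <- (phi_cmp(y, a, preds$pi1[lab], preds$pi0[lab],
                     preds$mu1[lab], preds$mu0[lab], 0)) / rho
  delta <- mean(v)
  V <- rho / cohort$N * sum((v - delta)^2)
  .new_estimate("sl_dml", delta, V, n, cohort$N, cohort$rho_hat, preds$K,
                level, influence = v)
}

# complete-data cross-fitted AIPW on (y, a, x): the engine behind the
# unsupervised benchmark and the exact-reduction identity
.aipw_complete <- function(x, a, y, folds, level = 0.95, M = 2.2,
                           cv_folds = 10L, max_degree = NULL, seed = 1L,
                           degree_scope = "per_fold") {
  x <- as.matrix(x)
  cohort <- .new_cohort(x, matrix(0, nrow(x), 0), a, y,
                        rep(1L, nrow(x)))
  preds <- fit_nuisances_spline(cohort, folds, M = M, cv_folds = cv_folds,
                                max_degree = max_degree, seed = seed,
                                include_imputation = FALSE,
                                degree_scope = degree_scope)
  v <- phi_cmp(y, a, preds$pi1, preds$pi0, preds$mu1, preds$mu0, 0)
  delta <- mean(v)
  V <- mean((v - delta)^2)
  list(delta = delta, V = V, influence = v, preds = preds)
}

#' Unsupervised benchmark from dichotomized surrogates
#'
#' Thresholds each surrogate at the sample quantile matching the labeled
#' prevalence of its target, then treats the dichotomized values as if
#' they were the true treatment and outcome in a complete-data
#' cross-fitted AIPW analysis of all `N` subjects.  Ignoring the
#' surrogate error this way is generally biased; the estimator exists as
#' the cautionary benchmark.
#'
#' @param cohort an `ssl_cohort`.
#' @param folds a `fold_assignment`.
#' @param level confidence level.
#' @param cv_folds,max_degree,seed,degree_scope passed to the spline
#'   nuisance fits on the dichotomized data.
#' @return an `ate_estimate` (with `n = N`, as every subject carries
#'   pseudo-labels).
#' @export
unsupervised_estimate <- function(cohort, folds, level = 0.95,
                                  cv_folds = 10L, max_degree = NULL,
                                  seed = 1L, degree_scope = "per_fold") {
  lab <- which(cohort$r == 1L)
  if (!length(lab)) stop("labeled subset is empty")
  if (cohort$q < 2L) stop("need treatment and outcome surrogates")
  s_a <- cohort$s[, 1]; s_y <- cohort$s[, 2]
  if (sd(s_a) == 0 || sd(s_y) == 0) stop("degenerate (constant) surrogate")
  n <- length(lab)
  a_tilde <- .dichotomize(s_a, mean(cohort$a[lab]))
  y_tilde <- .dichotomize(s_y, mean(cohort$y[lab]))
  fit <- .aipw_complete(cohort$x, a_tilde, y_tilde, folds, level,
                        cv_folds = cv_folds, max_degree = max_degree,
                        seed = seed, degree_scope = degree_scope)
  .new_estimate("ul", fit$delta, fit$V, cohort$N, cohort$N, 1, folds$K,
                level, influence = fit$influence)
}

# threshold at the order statistic matching a target prevalence
.dichotomize <- function(s, prev) {
  k <- round(length(s) * prev)
  if (k <= 0L) return(rep(0L, length(s)))
  if (k >= length(s)) return(rep(1L, length(s)))
  thr <- sort(s, decreasing = TRUE)[k]
  as.integer(s >= thr)
}

#' Optimal linear ensemble of the SMMAL and supervised estimates
#'
#' Combines the two estimates as
#' `delta_smmal + b (delta_sl - delta_smmal)` with the variance-minimizing
#' weight estimated from the empirical variances and covariance of the
#' two influence vectors.  When the denominator is numerically
#' non-positive (e.g. identical influence vectors) the weight falls back
#' to 0 with a warning, returning the SMMAL estimate unchanged.
#'
#' @param smmal an `ate_estimate` from [smmal_estimate()].
#' @param sl an `ate_estimate` from [supervised_estimate()] on the same
#'   cohort.
#' @param level confidence level.
#' @return an `ate_estimate` with the combining weight in `$b`.
#' @export
ensemble_estimate <- function(smmal, sl, level = 0.95) {
  if (is.null(smmal$influence) || is.null(sl$influence) ||
      length(smmal$influence) != length(sl$influence))
    stop("both estimates must carry influence vectors on the same cohort")
  v_ssl <- var(smmal$influence)
  v_sl <- var(sl$influence)
  cv <- cov(smmal$influence, sl$influence)
  den <- v_ssl + v_sl - 2 * cv
  if (!is.finite(den) || den <= 1e-12 * max(v_ssl, v_sl, 1e-300)) {
    warning("degenerate ensemble denominator; returning the SMMAL estimate")
    b <- 0
  } else {
    b <- (v_ssl - cv) / den
  }
  delta <- smmal$delta + b * (sl$delta - smmal$delta)
  comb <- (1 - b) * smmal$influence + b * sl$influence
  V <- smmal$rho_hat / smmal$N * sum((comb - mean(comb))^2)
  .new_estimate("ensemble", delta, V, smmal$n, smmal$N, smmal$rho_hat,
                smmal$K, level, influence = comb, extra = list(b = b))
}

#' Crude (unadjusted) difference-in-means comparators
#'
#' `type = "sl"`: difference of labeled-set arm means.  `type = "ul"`:
#' difference of arm means after dichotomizing both surrogates over all
#' `N` subjects.
#'
#' @param cohort an `ssl_cohort`.
#' @param type `"sl"` or `"ul"`.
#' @param level confidence level.
#' @return an `ate_estimate` (two-sample variance).
#' @export
crude_estimate <- function(cohort, type = c("sl", "ul"), level = 0.95) {
  type <- match.arg(type)
  if (type == "sl") {
    lab <- which(cohort$r == 1L)
    a <- cohort$a[lab]; y <- cohort$y[lab]
    n <- length(lab)
  } else {
    lab <- which(cohort$r == 1L)
    a <- .dichotomize(cohort$s[, 1], mean(cohort$a[lab]))
    y <- .dichotomize(cohort$s[, 2], mean(cohort$y[lab]))
    n <- cohort$N
  }
  n1 <- sum(a == 1); n0 <- sum(a == 0)
  if (n1 == 0 || n0 == 0) stop("a treatment arm is empty")
  delta <- mean(y[a == 1]) - mean(y[a == 0])
  V <- n * (var(y[a == 1]) / n1 + var(y[a == 0]) / n0)
  .new_estimate(paste0("crude_", type), delta, V, n, cohort$N,
                cohort$rho_hat, NA_integer_, level)
}
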