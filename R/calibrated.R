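# Doubly robust nuisance estimation for high-dimensional confounders:
# lasso imputation and initial fits, linear-predictor truncation, and the
# calibrated propensity/outcome losses minimized under two-level
# cross-fitting.

#' Truncate a linear predictor at twice the positivity constant
#'
#' \eqn{\tau(x) = sign(x) \min(|x|, 2M)}.  Applied to initial-fit linear
#' predictors it bounds the calibration weights in
#' \eqn{[e^{-2M}, e^{2M}]}, which is what removes the sparsity
#' requirement on a mis-specified initial model.
#'
#' @param x numeric linear predictor(s).
#' @param M positivity constant (default 2.2, matching a probability range
#'   of about \[0.1, 0.9\]).
#' @return truncated value(s).
#' @export
truncate_linpred <- function(x, M = 2.2) {
  cap <- 2 * M
  sign(x) * pmin(abs(x), cap)
}

# design matrices with leading intercept column
design_x <- function(cohort) cbind(`(Intercept)` = 1, cohort$x)
design_w <- function(cohort) cbind(`(Intercept)` = 1, cohort$x, cohort$s)

#' Calibrated propensity-score loss
#'
#' The convex loss whose first-order condition makes the ATE estimator
#' Neyman-orthogonal to errors in the outcome model:
#' \deqn{\ell_{\alpha,a} = \dot g(\tau(X'\beta)) \{ (a - A) \alpha'X +
#'   I(A = a) e^{(-1)^a \alpha'X} \}.}
#' The derivative weight multiplies the whole bracket: with this grouping
#' the true propensity coefficients solve the population calibration
#' equation for any initial outcome fit, and the equation coincides with
#' the first-order condition that removes the estimator's sensitivity to
#' the outcome model.
#'
#' @param alpha coefficient vector (length `ncol(design)`).
#' @param design design matrix with leading intercept (labeled rows).
#' @param a_obs observed treatment for the same rows.
#' @param beta_init initial outcome-model coefficients for arm `arm`.
#' @param arm target treatment arm (0 or 1).
#' @param M positivity constant for the truncation.
#' @return mean loss over the rows.
#' @export
calib_ps_objective <- function(alpha, design, a_obs, beta_init, arm,
                               M = 2.2) {
  gw <- .gdot(truncate_linpred(drop(design %*% beta_init), M))
  eta <- drop(design %*% alpha)
  s <- if (arm == 1) -1 else 1
  mean(gw * ((arm - a_obs) * eta +
               (a_obs == arm) * exp(pmin(pmax(s * eta, -30), 30))))
}

#' Calibrated outcome-regression loss
#'
#' Weighted logistic loss with exponential-tilt weights from the truncated
#' initial propensity fit:
#' \deqn{\ell_{\beta,a} = e^{\tau((-1)^a \alpha'X)} \ell(Y, \beta'X).}
#' The truncation keeps every weight inside \eqn{[e^{-2M}, e^{2M}]}.
#'
#' @param beta coefficient vector.
#' @param design design matrix (labeled rows of arm `arm`).
#' @param y_obs observed outcomes for those rows.
#' @param alpha_init initial propensity coefficients.
#' @param arm treatment arm.
#' @param M positivity constant.
#' @return mean loss over the rows.
#' @export
calib_or_objective <- function(beta, design, y_obs, alpha_init, arm,
                               M = 2.2) {
  s <- if (arm == 1) -1 else 1
  w <- exp(truncate_linpred(s * drop(design %*% alpha_init), M))
  eta <- drop(design %*% beta)
  e <- pmin(pmax(eta, -30), 30)
  mean(w * (log1p(exp(e)) - y_obs * eta))
}

# glmnet fit returning the full coefficient vector (intercept first);
# lambda = "cv" selects by K-fold deviance
.glmnet_coef <- function(x, y, weights = NULL, lambda, cv_folds = 10L,
                         seed = 1L) {
  if (length(unique(y)) < 2L) {
    p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    return(list(coef = c(qlogis(p0), rep(0, ncol(x))), lambda = NA_real_))
  }
  if (identical(lambda, "cv")) {
    set.seed(as.integer(seed))
    foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", weights = weights,
                            foldid = foldid, nlambda = 50L)
    lam <- cv$lambda.min
    return(list(coef = as.vector(coef(cv, s = "lambda.min")), lambda = lam))
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", weights = weights,
                        lambda = lambda * c(8, 4, 2, 1))
  list(coef = as.vector(coef(fit, s = lambda)), lambda = lambda)
}

#' Lasso imputation models on confounders and surrogates
#'
#' For each fold, fits on the out-of-fold labeled rows the treatment
#' imputation `Pi(1, W)` (logistic lasso of `A` on `W`) and the
#' arm-specific outcome imputations `m(a, W)`.  The imputation models need
#' not be correctly specified for valid inference, so the design may be
#' restricted (e.g. to the surrogate columns alone) via `design_cols`.
#'
#' @param cohort an `ssl_cohort`.
#' @param folds a `fold_assignment`.
#' @param lambda `"cv"` (per-fit cross-validated penalty) or a fixed
#'   value.
#' @param cv_folds folds for the penalty cross-validation.
#' @param seed RNG seed.
#' @param design_cols optional integer columns of `W = (X, S)` to restrict
#'   the imputation design to (e.g. only the surrogates).
#' @param lambda_scope `"per_fold"` reselects the penalty for every fold;
#'   `"shared"` selects once on the first fold's training set and reuses
#'   it.
#' @return list with per-fold coefficient vectors `xi`, `zeta1`, `zeta0`
#'   (intercept first) and the columns used.
#' @export
fit_imputation <- function(cohort, folds, lambda = "cv", cv_folds = 10L,
                           seed = 1L, design_cols = NULL,
                           lambda_scope = c("per_fold", "shared")) {
  lambda_scope <- match.arg(lambda_scope)
  Wfull <- cbind(cohort$x, cohort$s)
  if (is.null(design_cols)) design_cols <- seq_len(ncol(Wfull))
  W <- Wfull[, design_cols, drop = FALSE]
  out <- list(xi = vector("list", folds$K), zeta1 = vector("list", folds$K),
              zeta0 = vector("list", folds$K), design_cols = design_cols)
  shared <- list(xi = lambda, zeta1 = lambda, zeta0 = lambda)
  for (k in seq_len(folds$K)) {
    oof <- out_of_fold(folds, k)
    lab <- oof[cohort$r[oof] == 1L]
    a <- cohort$a[lab]; y <- cohort$y[lab]
    sets <- list(xi = list(rows = seq_along(lab), yy = a),
                 zeta1 = list(rows = which(a == 1L), yy = y[a == 1L]),
                 zeta0 = list(rows = which(a == 0L), yy = y[a == 0L]))
    for (m in names(sets)) {
      rows <- lab[sets[[m]]$rows]
      fit <- .glmnet_coef(W[rows, , drop = FALSE], sets[[m]]$yy,
                          lambda = shared[[m]], cv_folds = cv_folds,
                          seed = seed + 7L * k + match(m, names(sets)))
      if (lambda_scope == "shared" && identical(shared[[m]], "cv"))
        shared[[m]] <- fit$lambda
      out[[m]][[k]] <- fit$coef
    }
  }
  out
}

# unordered-pair key: initial fits depend only on the excluded fold set
.pair_key <- function(k1, k2) paste(sort(c(k1, k2)), collapse = ".")

#' Initial lasso propensity and outcome fits for every fold pair
#'
#' For each unordered fold pair, fits on the labeled rows outside both
#' folds: the initial propensity (logistic lasso of `A` on `X`) and the
#' arm-specific initial outcome models.  These feed the calibrated losses
#' through the truncation, so their accuracy requirements are mild.
#'
#' @inheritParams fit_imputation
#' @return list with named elements `alpha[[key]]`, `beta1[[key]]`,
#'   `beta0[[key]]` keyed by `"k1.k2"` with `k1 < k2`.
#' @export
fit_initial <- function(cohort, folds, lambda = "cv", cv_folds = 10L,
                        seed = 1L, lambda_scope = c("per_fold", "shared")) {
  lambda_scope <- match.arg(lambda_scope)
  X <- cohort$x
  out <- list(alpha = list(), beta1 = list(), beta0 = list())
  shared <- list(alpha = lambda, beta1 = lambda, beta0 = lambda)
  for (k1 in seq_len(folds$K - 1L)) for (k2 in (k1 + 1L):folds$K) {
    idx <- out_of_two(folds, k1, k2)
    lab <- idx[cohort$r[idx] == 1L]
    a <- cohort$a[lab]; y <- cohort$y[lab]
    key <- .pair_key(k1, k2)
    sets <- list(alpha = list(rows = seq_along(lab), yy = a),
                 beta1 = list(rows = which(a == 1L), yy = y[a == 1L]),
                 beta0 = list(rows = which(a == 0L), yy = y[a == 0L]))
    for (m in names(sets)) {
      rows <- lab[sets[[m]]$rows]
      fit <- .glmnet_coef(X[rows, , drop = FALSE], sets[[m]]$yy,
                          lambda = shared[[m]], cv_folds = cv_folds,
                          seed = seed + 13L * k1 + 29L * k2 +
                            match(m, names(sets)))
      if (lambda_scope == "shared" && identical(shared[[m]], "cv"))
        shared[[m]] <- fit$lambda
      out[[m]][[key]] <- fit$coef
    }
  }
  out
}

# assemble the two-level cross-fitted rows feeding the calibrated fit for
# target fold k1: labeled rows of each other fold k2, each carrying
# initial-fit values from the fit that excluded both k1 and k2
.calib_rows <- function(cohort, folds, initials, k1, arm, M) {
  Xd <- design_x(cohort)
  rows <- integer(0); gw <- numeric(0); orw <- numeric(0)
  s <- if (arm == 1) -1 else 1
  for (k2 in setdiff(seq_len(folds$K), k1)) {
    idx <- which(folds$fold_of == k2 & cohort$r == 1L)
    if (!length(idx)) next
    key <- .pair_key(k1, k2)
    beta_i <- initials[[if (arm == 1) "beta1" else "beta0"]][[key]]
    alpha_i <- initials$alpha[[key]]
    eta_b <- drop(Xd[idx, , drop = FALSE] %*% beta_i)
    eta_a <- drop(Xd[idx, , drop = FALSE] %*% alpha_i)
    rows <- c(rows, idx)
    gw <- c(gw, .gdot(truncate_linpred(eta_b, M)))
    orw <- c(orw, exp(truncate_linpred(s * eta_a, M)))
  }
  list(rows = rows, gw = gw, orw = orw)
}

#' Calibrated propensity and outcome fits with two-level cross-fitting
#'
#' For each target fold `k1` and arm, minimizes the aggregated calibrated
#' losses over the labeled rows of every other fold `k2`, with
#' initial-fit weights taken from the fit trained outside both `k1` and
#' `k2`.  The propensity loss is normalized by the total number of labels;
#' the outcome loss by the number of labeled arm rows actually summed
#' over.
#'
#' @inheritParams fit_imputation
#' @param initials result of [fit_initial()].
#' @param M positivity constant; calibration weights stay inside
#'   `[exp(-2M), exp(2M)]`.
#' @param tol KKT tolerance for the final fits.
#' @param lambda_scope `"shared"` (default) cross-validates the calibrated
#'   penalty once per (loss, arm) on the first target fold and reuses it;
#'   `"per_fold"` reselects for every target fold.
#' @return list with per-fold coefficient vectors `alpha1`, `alpha0`,
#'   `beta1`, `beta0`, the observed outcome-weight range `or_weight_range`,
#'   and KKT residuals.
#' @export
fit_calibrated <- function(cohort, folds, initials, M = 2.2, lambda = "cv",
                           cv_folds = 5L, seed = 1L, tol = 1e-6,
                           lambda_scope = c("shared", "per_fold")) {
  lambda_scope <- match.arg(lambda_scope)
  Xd <- design_x(cohort)
  n_lab <- sum(cohort$r)
  K <- folds$K
  out <- list(alpha1 = vector("list", K), alpha0 = vector("list", K),
              beta1 = vector("list", K), beta0 = vector("list", K))
  kkt <- c()
  wrange <- c(Inf, -Inf)
  lam_ps <- list(`1` = lambda, `0` = lambda)
  lam_or <- list(`1` = lambda, `0` = lambda)
  for (k1 in seq_len(K)) for (arm in c(1L, 0L)) {
    cr <- .calib_rows(cohort, folds, initials, k1, arm, M)
    Xr <- Xd[cr$rows, , drop = FALSE]
    Ar <- cohort$a[cr$rows]
    Yr <- cohort$y[cr$rows]
    akey <- as.character(arm)
    # --- calibrated propensity (exponential tilt), normalized by n ---
    cw_ps <- rep(1 / n_lab, length(cr$rows))
    if (identical(lam_ps[[akey]], "cv")) {
      lam_ps[[akey]] <- as.numeric(
        cv_lambda(Xr, Ar, loss_kind = "calib_ps", gw = cr$gw, arm = arm,
                  folds = cv_folds, seed = seed + 401L + arm,
                  nlambda = 50L))
    }
    # cv_lambda normalizes its loss by the row count; rescale the selected
    # penalty to this fit's 1/n normalization
    lam_ps_use <- lam_ps[[akey]] * length(cr$rows) / n_lab
    pen <- c(0, rep(1, ncol(Xd) - 1L))
    fps <- .prox_solve(Xr, Ar, cw_ps, cr$gw, 1L, arm, lam_ps_use, pen,
                       rep(0, ncol(Xd)), 5e4, tol, TRUE)
    if (!fps$converged)
      stop(sprintf("calibrated PS fit (fold %d, arm %d) did not converge: %s",
                   k1, arm, sprintf("KKT residual %.3g", fps$kkt)))
    out[[paste0("alpha", arm)]][[k1]] <- fps$coef
    kkt <- c(kkt, fps$kkt)
    # --- calibrated outcome: weighted logistic lasso ---
    sel <- Ar == arm
    worm <- cr$orw[sel]
    wrange <- c(min(wrange[1], min(worm)), max(wrange[2], max(worm)))
    if (identical(lam_or[[akey]], "cv")) {
      lam_or[[akey]] <- as.numeric(
        cv_lambda(Xr[sel, , drop = FALSE], Yr[sel], weights = worm,
                  loss_kind = "logistic", folds = cv_folds,
                  seed = seed + 907L + arm, nlambda = 50L))
    }
    n_or <- sum(sel)
    cw_or <- worm / n_or
    lam_or_use <- lam_or[[akey]] * sum(worm) / n_or  # see PS rescaling note
    for_ <- .prox_solve(Xr[sel, , drop = FALSE], Yr[sel], cw_or,
                        numeric(n_or), 0L, 0L, lam_or_use, pen,
                        rep(0, ncol(Xd)), 5e4, tol, TRUE)
    if (!for_$converged)
      stop(sprintf("calibrated OR fit (fold %d, arm %d) did not converge: %s",
                   k1, arm, sprintf("KKT residual %.3g", for_$kkt)))
    out[[paste0("beta", arm)]][[k1]] <- for_$coef
    kkt <- c(kkt, for_$kkt)
    if (lambda_scope == "per_fold") {
      lam_ps[[akey]] <- lambda
      lam_or[[akey]] <- lambda
    }
  }
  out$or_weight_range <- wrange
  out$kkt <- kkt
  out$lambda_ps <- lam_ps
  out$lambda_or <- lam_or
  out
}

#' Assemble high-dimensional nuisance predictions
#'
#' Evaluates the calibrated and imputation fits per the construction:
#' propensities use the truncated linear predictor
#' (`pi(1) = g(tau(X'alpha1))`, `pi(0) = g(tau(-X'alpha0))`, each arm with
#' its own calibration so the two need not sum to one), outcome
#' regressions `mu(a) = g(X'beta_a)`, and imputations
#' `Pi(1) = g(W'xi)` with the arm-0 value taken as the complement, and
#' `m(a) = g(W'zeta_a)`.
#'
#' @param cohort an `ssl_cohort`.
#' @param folds a `fold_assignment`.
#' @param imput result of [fit_imputation()].
#' @param calib result of [fit_calibrated()].
#' @param M positivity constant.
#' @return a `nuisance_preds` object.
#' @export
predict_nuisances_hd <- function(cohort, folds, imput, calib, M = 2.2) {
  N <- cohort$N
  Xd <- design_x(cohort)
  Wd <- cbind(1, cbind(cohort$x, cohort$s)[, imput$design_cols, drop = FALSE])
  out <- list(pi1 = rep(NA_real_, N), pi0 = rep(NA_real_, N),
              mu1 = rep(NA_real_, N), mu0 = rep(NA_real_, N),
              Pi1 = rep(NA_real_, N), m1 = rep(NA_real_, N),
              m0 = rep(NA_real_, N))
  for (k in seq_len(folds$K)) {
    idx <- which(folds$fold_of == k)
    Xk <- Xd[idx, , drop = FALSE]; Wk <- Wd[idx, , drop = FALSE]
    out$pi1[idx] <- plogis(truncate_linpred(drop(Xk %*% calib$alpha1[[k]]), M))
    out$pi0[idx] <- plogis(truncate_linpred(-drop(Xk %*% calib$alpha0[[k]]), M))
    out$mu1[idx] <- plogis(drop(Xk %*% calib$beta1[[k]]))
    out$mu0[idx] <- plogis(drop(Xk %*% calib$beta0[[k]]))
    out$Pi1[idx] <- plogis(drop(Wk %*% imput$xi[[k]]))
    out$m1[idx] <- plogis(drop(Wk %*% imput$zeta1[[k]]))
    out$m0[idx] <- plogis(drop(Wk %*% imput$zeta0[[k]]))
  }
  out$Pi0 <- 1 - out$Pi1
  structure(c(out, list(fold_of = folds$fold_of, K = folds$K, M = M,
                        pi_bounds = c(plogis(-2 * M), plogis(2 * M)),
                        or_weight_range = calib$or_weight_range,
                        nuisance = "hd_calibrated")),
            class = "nuisance_preds")
}

#' Full high-dimensional nuisance pipeline
#'
#' Runs [fit_imputation()], [fit_initial()], [fit_calibrated()] and
#' [predict_nuisances_hd()] in sequence.
#'
#' @inheritParams fit_imputation
#' @param M positivity constant.
#' @param cv_folds folds for penalty cross-validation.
#' @param lambda_scope penalty-selection reuse policy passed to the
#'   component fitters (`"shared"` trades per-fold reselection for speed).
#' @param imputation_cols optional design restriction for the imputation
#'   models.
#' @return a `nuisance_preds` object.
#' @export
fit_nuisances_hd <- function(cohort, folds, M = 2.2, lambda = "cv",
                             cv_folds = 10L, seed = 1L,
                             lambda_scope = c("per_fold", "shared"),
                             imputation_cols = NULL) {
  lambda_scope <- match.arg(lambda_scope)
  imput <- fit_imputation(cohort, folds, lambda = lambda,
                          cv_folds = cv_folds, seed = seed,
                          design_cols = imputation_cols,
                          lambda_scope = lambda_scope)
  init <- fit_initial(cohort, folds, lambda = lambda, cv_folds = cv_folds,
                      seed = seed + 1000L, lambda_scope = lambda_scope)
  calib <- fit_calibrated(cohort, folds, init, M = M, lambda = lambda,
                          cv_folds = min(cv_folds, 5L), seed = seed + 2000L,
                          lambda_scope = if (lambda_scope == "shared")
                            "shared" else "per_fold")
  predict_nuisances_hd(cohort, folds, imput, calib, M = M)
}
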