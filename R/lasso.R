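# L1-penalized M-estimation used by the high-dimensional nuisance route.
# The package ships its own FISTA proximal-gradient solver with KKT
# certification; it handles both the weighted logistic loss and the
# exponential-tilt calibrated propensity loss, which is not a GLM family
# available in standard lasso software.

.gdot <- function(x) {
  p <- plogis(x)
  p * (1 - p)
}

# standardize penalized columns to unit sd, solve, then map back
.prox_solve <- function(design, y, cw, gw, kind, arm, lambda, pen, coef0,
                        maxit, tol, standardize) {
  scales <- rep(1, ncol(design))
  if (standardize) {
    s <- apply(design, 2, sd)
    scales <- ifelse(pen > 0 & s > 0, s, 1)
    design <- sweep(design, 2, scales, "/")
    coef0 <- coef0 * scales
  }
  fit <- cpp_prox_lasso(design, as.numeric(y), cw, gw, as.integer(kind),
                        as.integer(arm), lambda, pen, coef0,
                        as.integer(maxit), tol)
  fit$coef <- drop(fit$coef) / scales
  fit$coef_std <- drop(fit$coef) * scales
  fit
}

#' L1-penalized (weighted) logistic regression
#'
#' Minimizes the normalized weighted logistic loss
#' \eqn{\sum_i w_i \ell(y_i, x_i'\theta) / \sum_i w_i + \lambda \|\theta_{-1}\|_1}
#' by proximal gradient descent with backtracking, certifying the KKT
#' conditions of the returned solution.  The first (intercept) column of
#' the design is unpenalized.
#'
#' @param design numeric matrix whose first column is the constant 1.
#' @param y binary response.
#' @param weights nonnegative observation weights (default 1).
#' @param lambda nonnegative penalty.
#' @param standardize scale penalized columns to unit standard deviation
#'   internally (coefficients are reported on the original scale).
#' @param maxit,tol solver budget and KKT tolerance.
#' @param coef0 optional warm start.
#' @param on_fail `"error"` (default) stops on non-convergence, reporting
#'   the final KKT residual; `"warn"` downgrades to a warning.
#' @return object of class `coef_fit` with elements `coef`, `lambda`,
#'   `loss_kind`, `support_size` (non-intercept non-zeros), `kkt`,
#'   `converged`, `iter`.
#' @export
logistic_lasso <- function(design, y, weights = NULL, lambda,
                           standardize = TRUE, maxit = 5e4, tol = 1e-6,
                           coef0 = NULL, on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  n <- nrow(design)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero")
  cw <- weights / sw
  pen <- c(0, rep(1, ncol(design) - 1L))
  if (is.null(coef0)) coef0 <- rep(0, ncol(design))
  fit <- .prox_solve(design, y, cw, numeric(n), 0L, 0L, lambda, pen, coef0,
                     maxit, tol, standardize)
  if (!fit$converged) {
    msg <- sprintf("lasso solver did not converge: KKT residual %.3g > %.3g",
                   fit$kkt, tol)
    if (on_fail == "error") stop(msg) else warning(msg)
  }
  structure(list(coef = fit$coef, lambda = lambda, loss_kind = "logistic",
                 arm = "pooled",
                 support_size = sum(fit$coef[-1] != 0),
                 kkt = fit$kkt, converged = fit$converged, iter = fit$iter),
            class = "coef_fit")
}

#' @export
print.coef_fit <- function(x, ...) {
  cat(sprintf("L1-penalized fit (%s loss, arm %s): lambda = %.4g, %d of %d\n",
              x$loss_kind, as.character(x$arm), x$lambda, x$support_size,
              length(x$coef) - 1L))
  cat(sprintf("  covariates in support; KKT residual %.2e after %d iters\n",
              x$kkt, x$iter))
  invisible(x)
}

# largest penalty with an all-zero penalized block, from the gradient at
# the intercept-only optimum (closed form for both supported losses)
.lambda_max <- function(design, y, cw, gw, kind, arm, standardize) {
  scales <- rep(1, ncol(design))
  if (standardize) {
    s <- apply(design, 2, sd)
    scales <- ifelse(s > 0, s, 1)
    scales[1] <- 1
  }
  Xs <- sweep(design, 2, scales, "/")
  if (kind == 0L) {
    p0 <- sum(cw * y) / sum(cw)
    p0 <- min(max(p0, 1e-6), 1 - 1e-6)
    g <- drop(crossprod(Xs, cw * (p0 - y)))
  } else {
    s_sign <- if (arm == 1L) -1 else 1
    ia <- as.numeric(y == arm)
    # intercept solving mean[gw (a - A)] + s e^{s b0} mean[gw I(A=a)] = 0
    num <- sum(cw * gw * abs(arm - y))
    den <- sum(cw * gw * ia)
    e0 <- if (den > 0) num / den else 1
    g <- drop(crossprod(Xs, cw * gw * ((arm - y) + ia * s_sign * e0)))
  }
  max(abs(g[-1]), 1e-8)
}

# warm-started solution path over a decreasing penalty grid
.lasso_path <- function(design, y, cw, gw, kind, arm, grid, standardize,
                        maxit = 800, tol = 1e-4) {
  pen <- c(0, rep(1, ncol(design) - 1L))
  coefs <- matrix(0, ncol(design), length(grid))
  b <- rep(0, ncol(design))
  for (j in seq_along(grid)) {
    fit <- .prox_solve(design, y, cw, gw, kind, arm, grid[j], pen, b,
                       maxit, tol, standardize)
    b <- fit$coef
    coefs[, j] <- b
    if (any(!is.finite(b)) || max(abs(b)) > 1e5) {
      coefs[, j] <- sign(coefs[, j]) * 1e5  # flag divergence, keep finite
      b <- rep(0, length(b))                # clean warm start
    }
  }
  coefs
}

.oof_loss <- function(design, y, cw, gw, kind, arm, coefs) {
  eta <- design %*% coefs  # n x nlambda
  if (kind == 0L) {
    e <- pmin(pmax(eta, -30), 30)
    colSums(cw * (log1p(exp(e)) - y * eta))
  } else {
    s_sign <- if (arm == 1L) -1 else 1
    ia <- as.numeric(y == arm)
    colSums(cw * gw * ((arm - y) * eta +
                         ia * exp(pmin(pmax(s_sign * eta, -30), 30))))
  }
}

#' Cross-validated penalty selection
#'
#' Selects the penalty minimizing mean out-of-fold loss of the same loss
#' kind as the fit it will be used for; ties break toward the larger
#' penalty.  The default grid is 50 log-spaced values descending from the
#' smallest penalty that zeroes the whole penalized block, a grid whose
#' center tracks the `sqrt(log(p)/n)` scale of the theory.
#'
#' @param design design matrix with leading intercept column.
#' @param y binary response (the treatment indicator for the calibrated
#'   propensity loss).
#' @param weights observation weights (logistic loss) .
#' @param loss_kind `"logistic"` (also covers the weighted calibrated
#'   outcome loss) or `"calib_ps"`.
#' @param gw derivative weights \eqn{\dot g(\tau(x'\beta))} for the
#'   calibrated propensity loss.
#' @param arm treatment arm for the calibrated propensity loss.
#' @param folds number of cross-validation folds.
#' @param seed RNG seed for the fold split.
#' @param nlambda,lambda_min_ratio grid size and ratio of smallest to
#'   largest penalty.
#' @param grid optional explicit descending penalty grid (at least 50
#'   values recommended).
#' @param standardize standardize penalized columns internally.
#' @return the selected penalty (an element of the grid), with the grid
#'   and mean out-of-fold losses attached as attributes.
#' @export
cv_lambda <- function(design, y, weights = NULL,
                      loss_kind = c("logistic", "calib_ps"),
                      gw = NULL, arm = 1L, folds = 10L, seed = 1L,
                      nlambda = 50L, lambda_min_ratio = NULL,
                      grid = NULL, standardize = TRUE) {
  loss_kind <- match.arg(loss_kind)
  kind <- if (loss_kind == "logistic") 0L else 1L
  n <- nrow(design)
  if (is.null(weights)) weights <- rep(1, n)
  cw <- weights / sum(weights)
  if (is.null(gw)) gw <- numeric(n)
  if (kind == 0L && length(unique(y)) < 2L) {
    warning("degenerate response (single class); returning lambda_max")
    lmax <- .lambda_max(design, y, cw, gw, kind, arm, standardize)
    return(lmax)
  }
  if (is.null(grid)) {
    # the calibrated loss needs a floor: below roughly lambda_max/10 its
    # exponential term can make the finite-sample objective unbounded
    if (is.null(lambda_min_ratio))
      lambda_min_ratio <- if (kind == 0L) 0.02 else 0.1
    lmax <- .lambda_max(design, y, cw, gw, kind, arm, standardize)
    grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
  }
  grid <- sort(grid, decreasing = TRUE)
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(folds), n))
  loss <- matrix(0, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    cw_tr <- weights[tr] / sum(weights[tr])
    coefs <- .lasso_path(design[tr, , drop = FALSE], y[tr], cw_tr, gw[tr],
                         kind, arm, grid, standardize)
    cw_te <- weights[!tr] / sum(weights[!tr])
    loss[f, ] <- .oof_loss(design[!tr, , drop = FALSE], y[!tr], cw_te,
                           gw[!tr], kind, arm, coefs)
  }
  mloss <- colMeans(loss)
  sel <- grid[which.min(mloss)]  # descending grid: first min = largest
  attr(sel, "grid") <- grid
  attr(sel, "cv_loss") <- mloss
  sel
}
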