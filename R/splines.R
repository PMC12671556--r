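# Low-dimensional nuisance estimation: tensor-product B-spline logistic
# regressions with cross-validated degree selection and positivity clipping.
#
# The order-1 (piecewise linear) tensor basis has at most 2 active functions
# per dimension at any point, which a compiled fast path exploits; the
# general-order path builds the dense basis in R.  Both paths use equally
# spaced interior knots on the training range, and extrapolation beyond the
# range is clamped to the boundary.

#' Tensor-product B-spline design matrix
#'
#' Equally spaced interior knots on the per-dimension boundary interval;
#' inputs outside the boundary are clamped to it.  For `order = 1`
#' (piecewise linear) and a single dimension with `degrees = d`, the basis
#' has `d + 1` hat functions forming a partition of unity.
#'
#' @param values numeric vector or matrix (rows = observations).
#' @param degrees integer degrees per dimension (recycled); dimension of
#'   the basis is `prod(degrees + order)`.
#' @param order spline order; 1 = piecewise linear.
#' @param boundary optional list with vectors `lo`, `hi` per dimension;
#'   defaults to the column ranges of `values`.
#' @return design matrix with attributes `degrees`, `order`, `boundary`.
#' @export
bspline_basis <- function(values, degrees, order = 1L, boundary = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (any(!is.finite(values))) stop("non-finite values in spline input")
  D <- ncol(values)
  degrees <- rep_len(as.integer(degrees), D)
  if (any(degrees < 1L)) stop("degrees must be at least 1")
  order <- as.integer(order)
  if (is.null(boundary))
    boundary <- list(lo = apply(values, 2, min), hi = apply(values, 2, max))
  M <- matrix(1, nrow(values), 1)
  for (d in seq_len(D)) {
    lo <- boundary$lo[d]; hi <- boundary$hi[d]
    if (hi <= lo) hi <- lo + 1  # degenerate column: constant basis
    x <- pmin(pmax(values[, d], lo), hi)
    inner <- if (degrees[d] > 1L)
      lo + seq_len(degrees[d] - 1L) / degrees[d] * (hi - lo) else numeric(0)
    knots <- c(rep(lo, order + 1L), inner, rep(hi, order + 1L))
    B <- splines::splineDesign(knots, x, ord = order + 1L)
    M <- M[, rep(seq_len(ncol(M)), each = ncol(B)), drop = FALSE] *
      B[, rep(seq_len(ncol(B)), times = ncol(M)), drop = FALSE]
  }
  attr(M, "degrees") <- degrees
  attr(M, "order") <- order
  attr(M, "boundary") <- boundary
  M
}

# dense ridge-stabilized IRLS, used by the general-order path and as an
# in-R reference for the compiled order-1 engine
.irls_dense <- function(B, y, ridge = 1e-6, maxit = 25L) {
  coefs <- rep(0, ncol(B))
  eta <- drop(B %*% coefs)
  for (it in seq_len(maxit)) {
    p <- plogis(pmin(pmax(eta, -30), 30))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y - p) / w
    G <- crossprod(B, B * w)
    diag(G) <- diag(G) + ridge * nrow(B) + 1e-10
    new <- drop(solve(G, crossprod(B, w * z)))
    delta <- max(abs(new - coefs))
    coefs <- new
    eta <- drop(B %*% coefs)
    if (delta < 1e-8) break
  }
  coefs
}

#' Fit a tensor-product spline logistic regression
#'
#' @param x numeric matrix of covariates (rows = observations).
#' @param y binary response.
#' @param degree common spline degree across dimensions.
#' @param order spline order (1 = piecewise linear, the default used
#'   throughout the package).
#' @param ridge small ridge added to the normal equations; keeps fits
#'   defined under empty cells or separation.
#' @return object of class `spline_logit_fit`.
#' @export
spline_logit <- function(x, y, degree, order = 1L, ridge = 1e-6) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (order == 1L) {
    fit <- cpp_spline_fit(x, as.numeric(y), as.integer(degree), lo, hi,
                          ridge, 25L)
    coefs <- drop(fit$coef)
    engine <- "fast"
  } else {
    B <- bspline_basis(x, degree, order, boundary = list(lo = lo, hi = hi))
    coefs <- .irls_dense(B, as.numeric(y), ridge)
    engine <- "dense"
  }
  structure(list(coef = coefs, degree = as.integer(degree),
                 order = as.integer(order), lo = lo, hi = hi,
                 dim = ncol(x), engine = engine),
            class = "spline_logit_fit")
}

#' @param object a `spline_logit_fit`.
#' @param newx covariate matrix to predict at (clamped to the training
#'   range).
#' @param ... unused.
#' @return predicted probabilities.
#' @rdname spline_logit
#' @export
predict.spline_logit_fit <- function(object, newx, ...) {
  if (is.vector(newx)) newx <- matrix(newx, ncol = 1)
  storage.mode(newx) <- "double"
  if (object$engine == "fast") {
    drop(cpp_spline_predict(newx, object$coef, object$degree,
                            object$lo, object$hi))
  } else {
    B <- bspline_basis(newx, object$degree, object$order,
                       boundary = list(lo = object$lo, hi = object$hi))
    plogis(pmin(pmax(drop(B %*% object$coef), -30), 30))
  }
}

#' Cross-validated spline degree selection
#'
#' Picks the common per-dimension degree minimizing mean out-of-fold
#' binomial entropy (negative log-likelihood); ties break toward the
#' smaller degree.
#'
#' @param features covariate matrix.
#' @param y binary response.
#' @param max_degree largest candidate degree.  Defaults to
#'   `floor(sqrt(nrow))` in one dimension; in higher dimensions the
#'   candidates are additionally capped so the tensor basis has at most
#'   `max(8, nrow/3)` columns.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed RNG seed for the fold split.
#' @param order spline order.
#' @param ridge ridge stabilizer passed to the fits.
#' @return the selected integer degree, with the per-degree entropies
#'   attached as attribute `"entropy"`.
#' @export
select_degree_cv <- function(features, y, max_degree = NULL, cv_folds = 10L,
                             seed = 1L, order = 1L, ridge = 1e-6) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  storage.mode(features) <- "double"
  n <- nrow(features); D <- ncol(features)
  if (length(y) != n) stop("length(y) must match nrow(features)")
  if (is.null(max_degree)) max_degree <- max(1L, floor(sqrt(n)))
  if (D > 1L) {
    cap <- max(8, floor(n / 3))
    dmax_basis <- max(1L, floor(cap^(1 / D)) - order)
    max_degree <- min(max_degree, dmax_basis)
  }
  degrees <- seq_len(max_degree)
  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(cv_folds), n))
  if (order == 1L) {
    # selection only needs approximately converged fits
    ent <- cpp_spline_cv(features, as.numeric(y), as.integer(degrees),
                         as.integer(foldid), as.integer(cv_folds),
                         ridge, 10L)
  } else {
    ent <- vapply(degrees, function(d) {
      tot <- 0; ntot <- 0
      for (f in seq_len(cv_folds)) {
        tr <- foldid != f
        fit <- tryCatch(
          spline_logit(features[tr, , drop = FALSE], y[tr], d, order, ridge),
          error = function(e) NULL)
        if (is.null(fit)) return(Inf)
        p <- pmin(pmax(predict(fit, features[!tr, , drop = FALSE]),
                       1e-9), 1 - 1e-9)
        tot <- tot - sum(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
        ntot <- ntot + sum(!tr == FALSE)
      }
      tot / ntot
    }, numeric(1))
  }
  if (all(!is.finite(ent)))
    stop("all candidate spline fits failed, starting at degree ",
         degrees[1])
  sel <- degrees[which.min(ent)]
  attr(sel, "entropy") <- stats::setNames(ent, degrees)
  sel
}

.clip <- function(p, lo, hi) pmin(pmax(p, lo), hi)

# fit + predict one nuisance model for one fold
.spline_model <- function(feat_tr, y_tr, feat_te, degree, order, ridge) {
  fit <- spline_logit(feat_tr, y_tr, degree, order, ridge)
  predict(fit, feat_te)
}

#' Cross-fitted spline nuisance models for a semi-supervised cohort
#'
#' For every fold `k`, fits on the out-of-fold labeled rows: the propensity
#' `pi(1, X)` (pooled logistic spline of `A` on `X`, complement for arm 0),
#' arm-specific outcome regressions `mu(a, X)`, and the imputation models
#' `Pi(1, W)` and `m(a, W)` on `W = (X, S)`; each subject's predictions
#' come from the fits that excluded their fold.  Spline degrees are chosen
#' by [select_degree_cv()] per fold and model.  Propensity predictions are
#' clipped into the positivity interval `[g(-M), g(M)]`
#' (`[0.1, 0.9]` at the default `M = 2.2`); the remaining probabilities
#' are bounded away from 0/1 only by a numerical epsilon, since validity
#' does not require clipping them.
#'
#' @param cohort an `ssl_cohort`.
#' @param folds a `fold_assignment` for the same cohort.
#' @param M positivity constant; propensity clip bounds are
#'   `plogis(-M)` and `plogis(M)`.
#' @param order spline order (default 1, piecewise linear).
#' @param cv_folds folds for degree selection.
#' @param max_degree optional cap on candidate degrees.
#' @param seed base seed; each (fold, model) gets its own offset so degree
#'   selections use independent splits.
#' @param include_imputation fit the `W`-based imputation models (set
#'   `FALSE` for complete-data workflows that only need `pi` and `mu`).
#' @param degree_scope `"per_fold"` (default) reselects the degree on each
#'   fold's own training set; `"shared"` selects once per model on all
#'   labeled rows, trading a small cross-fitting leak in the tuning
#'   parameter for speed.
#' @return object of class `nuisance_preds` with per-subject vectors
#'   `pi1, pi0, mu1, mu0, Pi1, Pi0, m1, m0`, the fold map, and the clip
#'   bounds used.
#' @export
fit_nuisances_spline <- function(cohort, folds, M = 2.2, order = 1L,
                                 cv_folds = 10L, max_degree = NULL,
                                 seed = 1L, include_imputation = TRUE,
                                 degree_scope = c("per_fold", "shared")) {
  degree_scope <- match.arg(degree_scope)
  N <- cohort$N
  X <- cohort$x
  W <- cbind(cohort$x, cohort$s)
  lab_all <- cohort$r == 1L
  lo_pi <- plogis(-M); hi_pi <- plogis(M)
  eps <- 1e-6
  out <- list(pi1 = rep(NA_real_, N), mu1 = rep(NA_real_, N),
              mu0 = rep(NA_real_, N), Pi1 = rep(NA_real_, N),
              m1 = rep(NA_real_, N), m0 = rep(NA_real_, N))
  degrees_used <- list()
  model_defs <- list(
    pi = list(feat = X, rows = quote(lab), yv = quote(cohort$a)),
    mu1 = list(feat = X, rows = quote(lab1), yv = quote(cohort$y)),
    mu0 = list(feat = X, rows = quote(lab0), yv = quote(cohort$y)),
    Pi = list(feat = W, rows = quote(lab), yv = quote(cohort$a)),
    m1 = list(feat = W, rows = quote(lab1), yv = quote(cohort$y)),
    m0 = list(feat = W, rows = quote(lab0), yv = quote(cohort$y)))
  if (!include_imputation) model_defs <- model_defs[1:3]
  shared_degree <- list()
  if (degree_scope == "shared") {
    lab <- which(lab_all)
    lab1 <- lab[cohort$a[lab] == 1L]; lab0 <- lab[cohort$a[lab] == 0L]
    for (m in names(model_defs)) {
      def <- model_defs[[m]]
      rows <- eval(def$rows)
      yv <- eval(def$yv)[rows]
      shared_degree[[m]] <- select_degree_cv(
        def$feat[rows, , drop = FALSE], yv, max_degree = max_degree,
        cv_folds = cv_folds, seed = seed + match(m, names(model_defs)),
        order = order)
    }
  }
  for (k in seq_len(folds$K)) {
    oof <- out_of_fold(folds, k)
    test <- which(folds$fold_of == k)
    lab <- oof[lab_all[oof]]
    lab1 <- lab[cohort$a[lab] == 1L]
    lab0 <- lab[cohort$a[lab] == 0L]
    if (length(lab1) == 0L || length(lab0) == 0L)
      stop("out-of-fold labeled data for fold ", k,
           " lacks a treatment arm; re-draw the folds")
    for (mi in seq_along(model_defs)) {
      m <- names(model_defs)[mi]
      def <- model_defs[[m]]
      rows <- eval(def$rows)
      yv <- eval(def$yv)[rows]
      feat_tr <- def$feat[rows, , drop = FALSE]
      deg <- if (degree_scope == "shared") shared_degree[[m]] else
        select_degree_cv(feat_tr, yv, max_degree = max_degree,
                         cv_folds = cv_folds,
                         seed = seed + 131L * k + mi, order = order)
      pred <- .spline_model(feat_tr, yv, def$feat[test, , drop = FALSE],
                            deg, order, 1e-6)
      out[[if (m == "pi") "pi1" else if (m == "Pi") "Pi1" else m]][test] <- pred
      degrees_used[[paste0(m, ".k", k)]] <- as.integer(deg)
    }
  }
  out$pi1 <- .clip(out$pi1, lo_pi, hi_pi)
  out$pi0 <- 1 - out$pi1
  out$mu1 <- .clip(out$mu1, eps, 1 - eps)
  out$mu0 <- .clip(out$mu0, eps, 1 - eps)
  if (include_imputation) {
    out$Pi1 <- .clip(out$Pi1, eps, 1 - eps)
    out$Pi0 <- 1 - out$Pi1
    out$m1 <- .clip(out$m1, eps, 1 - eps)
    out$m0 <- .clip(out$m0, eps, 1 - eps)
  } else {
    out$Pi1 <- out$Pi0 <- out$m1 <- out$m0 <- NULL
  }
  structure(c(out, list(fold_of = folds$fold_of, K = folds$K, M = M,
                        pi_bounds = c(lo_pi, hi_pi),
                        degrees = unlist(degrees_used),
                        nuisance = "spline")),
            class = "nuisance_preds")
}

#' @export
print.nuisance_preds <- function(x, ...) {
  cat(sprintf("Cross-fitted nuisance predictions (%s route), N = %d, K = %d\n",
              x$nuisance, length(x$pi1), x$K))
  cat(sprintf("  propensity range [%.4f, %.4f] (clip bounds [%.3f, %.3f])\n",
              min(x$pi1), max(x$pi1), x$pi_bounds[1], x$pi_bounds[2]))
  if (!is.null(x$Pi1)) cat("  imputation models: fitted\n")
  invisible(x)
}
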