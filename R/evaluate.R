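# Replicated simulation harness: bias, empirical SD, mean SE, CI coverage
# and relative efficiency across estimators, with common random numbers
# within each replicate.

#' Run replicated simulations of a design
#'
#' Generates `n_reps` fresh cohorts (seeds `base_seed + 1, ...,
#' base_seed + n_reps`), runs every requested estimator on the same data
#' within each replicate, and aggregates against the design's true ATE.
#' Relative efficiency is the ratio of empirical variances
#' (benchmark over method) across replicates.
#'
#' @param config a [sim_config()]; its `seed` field is overridden per
#'   replicate.
#' @param methods subset of `"smmal"`, `"sl_dml"`, `"ul"`, `"ensemble"`,
#'   `"crude_sl"`, `"crude_ul"`.
#' @param n_reps number of replicates (at least 50 for coverage claims).
#' @param base_seed base RNG seed.
#' @param nuisance `"spline"` (low-dimensional route) or
#'   `"hd_calibrated"`.
#' @param K number of cross-fitting folds.
#' @param level confidence level.
#' @param cv_folds folds for tuning-parameter selection inside the
#'   nuisance fits.
#' @param max_degree optional degree cap for the spline route.
#' @param lambda_scope penalty-selection reuse policy for the
#'   high-dimensional route (`"shared"` recommended at replicate scale).
#' @param degree_scope degree-selection policy for the spline route.
#' @param ul_degree_scope degree policy for the unsupervised benchmark's
#'   complete-data fits (`"shared"` keeps its `N`-sized fits affordable).
#' @param M positivity constant.
#' @return object of class `replicate_summary` with a per-method summary
#'   table, the per-replicate estimates, the ATE oracle used, and a
#'   failure log.
#' @export
run_replicates <- function(config, methods = c("smmal", "sl_dml"),
                           n_reps = 200L, base_seed = 1L,
                           nuisance = c("spline", "hd_calibrated"),
                           K = 10L, level = 0.95, cv_folds = 10L,
                           max_degree = NULL,
                           lambda_scope = "shared",
                           degree_scope = "per_fold",
                           ul_degree_scope = "shared", M = 2.2) {
  nuisance <- match.arg(nuisance)
  methods <- match.arg(methods, c("smmal", "sl_dml", "ul", "ensemble",
                                  "crude_sl", "crude_ul"),
                       several.ok = TRUE)
  if ("ensemble" %in% methods &&
      !all(c("smmal", "sl_dml") %in% methods))
    stop("the ensemble needs both 'smmal' and 'sl_dml'")
  hd <- nuisance == "hd_calibrated"
  truth_ate <- if (config$scenario == "lowd_smooth") list(delta = 0, se = 0)
    else hd_true_ate(config$scenario, seed = base_seed)
  need_preds <- any(c("smmal", "sl_dml", "ensemble") %in% methods)
  rows <- list()
  failures <- list()
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- base_seed + r
      sim <- simulate_cohort(cfg, truth_ate = truth_ate)
      cohort <- sim$cohort
      folds <- assign_folds_checked(cohort, K,
                                    seed = base_seed + 100000L + r,
                                    check_pairs = hd)
      ests <- list()
      if (need_preds) {
        preds <- if (hd)
          fit_nuisances_hd(cohort, folds, M = M, cv_folds = cv_folds,
                           seed = base_seed + r,
                           lambda_scope = lambda_scope)
        else
          fit_nuisances_spline(cohort, folds, M = M, cv_folds = cv_folds,
                               max_degree = max_degree,
                               seed = base_seed + r,
                               degree_scope = degree_scope)
        if ("smmal" %in% methods)
          ests$smmal <- smmal_estimate(cohort, preds, level,
                                       method = if (hd) "smmal_dr"
                                       else "smmal")
        if ("sl_dml" %in% methods)
          ests$sl_dml <- supervised_estimate(cohort, preds, level)
        if ("ensemble" %in% methods)
          ests$ensemble <- ensemble_estimate(ests$smmal, ests$sl_dml, level)
      }
      if ("ul" %in% methods)
        ests$ul <- unsupervised_estimate(cohort, folds, level,
                                         cv_folds = cv_folds,
                                         max_degree = max_degree,
                                         seed = base_seed + 5000L + r,
                                         degree_scope = ul_degree_scope)
      if ("crude_sl" %in% methods)
        ests$crude_sl <- crude_estimate(cohort, "sl", level)
      if ("crude_ul" %in% methods)
        ests$crude_ul <- crude_estimate(cohort, "ul", level)
      do.call(rbind, lapply(names(ests), function(m) {
        e <- ests[[m]]
        data.frame(rep = r, method = m, delta = e$delta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high)
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps)) stop("every replicate failed")
  delta_star <- truth_ate$delta
  reps$covered <- reps$ci_low <= delta_star & delta_star <= reps$ci_high
  summ <- do.call(rbind, lapply(split(reps, reps$method), function(d) {
    data.frame(method = d$method[1], n_reps = nrow(d),
               bias = mean(d$delta) - delta_star, sd = sd(d$delta),
               mean_se = mean(d$se), coverage = mean(d$covered))
  }))
  vars <- tapply(reps$delta, reps$method, var)
  re_vs <- lapply(rownames(summ), function(m)
    vars[setdiff(names(vars), m)] / vars[[m]])
  names(re_vs) <- rownames(summ)
  structure(list(summary = summ, reps = reps, re_vs = re_vs,
                 delta_star = delta_star, delta_se = truth_ate$se,
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL,
                 meta = list(scenario = config$scenario, N = config$N,
                             n_expected = config$n_expected,
                             alpha_A = config$alpha_A,
                             alpha_Y = config$alpha_Y, p = config$p,
                             n_reps = n_reps, base_seed = base_seed,
                             nuisance = nuisance, K = K,
                             cv_folds = cv_folds,
                             lambda_scope = lambda_scope,
                             degree_scope = degree_scope)),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicated simulation: %s, %d replicates, true ATE %.5f\n",
              x$meta$scenario, x$meta$n_reps, x$delta_star))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$failures))
    cat(sprintf("  (%d replicate(s) failed)\n", nrow(x$failures)))
  invisible(x)
}

#' Relative efficiency between two methods in a replicate summary
#'
#' @param x a `replicate_summary`.
#' @param method proposal method name.
#' @param benchmark benchmark method name.
#' @return `Var(benchmark) / Var(method)` across replicates.
#' @export
relative_efficiency <- function(x, method = "smmal", benchmark = "sl_dml") {
  re <- x$re_vs[[method]]
  if (is.null(re) || !benchmark %in% names(re))
    stop("methods not found in the summary")
  unname(re[benchmark])
}

#' Root-mean-square nuisance error against the simulated truth
#'
#' The max-over-arms root-mean-square model distance
#' \eqn{\|\hat h - h^*\|_2 = \max_a \sqrt{E(\hat h(a,\cdot) -
#' h^*(a,\cdot))^2}} for each nuisance model.  Imputation truths are only
#' available when the generator supplies them (closed form in the
#' low-dimensional design); otherwise those entries are `NA`.
#'
#' @param preds a `nuisance_preds`.
#' @param truth a `sim_truth` from the same replicate.
#' @return named vector with entries `pi`, `mu`, `Pi`, `m`.
#' @export
nuisance_mse <- function(preds, truth) {
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  out <- c(pi = max(rmse(preds$pi1, truth$pi_star),
                    rmse(preds$pi0, 1 - truth$pi_star)),
           mu = max(rmse(preds$mu1, truth$mu1_star),
                    rmse(preds$mu0, truth$mu0_star)),
           Pi = NA_real_, m = NA_real_)
  if (!is.null(truth$Pi1_star) && !is.null(preds$Pi1))
    out["Pi"] <- max(rmse(preds$Pi1, truth$Pi1_star),
                     rmse(preds$Pi0, 1 - truth$Pi1_star))
  if (!is.null(truth$m1_star) && !is.null(preds$m1))
    out["m"] <- max(rmse(preds$m1, truth$m1_star),
                    rmse(preds$m0, truth$m0_star))
  out
}

#' Surrogate-quality grid of replicated simulations
#'
#' Runs [run_replicates()] on every combination of the supplied surrogate
#' calibrations and returns a long table of relative efficiency (versus
#' the supervised benchmark) and coverage per cell, suitable for heat-map
#' rendering.
#'
#' @param alpha_grid_A,alpha_grid_Y Beta shape offsets for the two
#'   surrogates (e.g. the per-design calibrated values from
#'   [surrogate_alpha()]).
#' @param scenario design name.
#' @param n_reps replicates per cell.
#' @param seed base seed (each cell gets a distinct offset).
#' @param N,n_expected,p cohort dimensions.
#' @param methods estimators to run; relative efficiency is reported
#'   against `"sl_dml"` when present.
#' @param ... further arguments to [run_replicates()].
#' @return data frame with columns `alpha_A`, `alpha_Y`, `method`, `re`,
#'   `coverage`, `bias`, `sd`, `n_reps`.
#' @export
heatmap_grid <- function(alpha_grid_A, alpha_grid_Y, scenario,
                         n_reps = 100L, seed = 1L, N = 10000L,
                         n_expected = 500L, p = NULL,
                         methods = c("smmal", "sl_dml"), ...) {
  out <- list()
  cell <- 0L
  for (aA in alpha_grid_A) for (aY in alpha_grid_Y) {
    cell <- cell + 1L
    cfg <- sim_config(scenario, N = N, n_expected = n_expected,
                      alpha_A = aA, alpha_Y = aY, p = p, seed = 1L)
    rs <- run_replicates(cfg, methods = methods, n_reps = n_reps,
                         base_seed = seed + 100000L * cell, ...)
    s <- rs$summary
    re <- vapply(s$method, function(m) {
      if (m != "sl_dml" && "sl_dml" %in% s$method)
        relative_efficiency(rs, m, "sl_dml") else NA_real_
    }, numeric(1))
    out[[cell]] <- data.frame(alpha_A = aA, alpha_Y = aY,
                              method = s$method, re = re,
                              coverage = s$coverage, bias = s$bias,
                              sd = s$sd, n_reps = s$n_reps)
  }
  do.call(rbind, out)
}
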