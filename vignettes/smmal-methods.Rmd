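---
title: "Semi-supervised ATE estimation with surrogate-assisted influence functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised ATE estimation with surrogate-assisted influence functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electronic-health-record cohorts routinely contain, for every one of $N$
subjects, a vector of potential confounders $X$ and error-prone proxies
("surrogates") $S$ for the treatment actually received and for the clinical
response — diagnosis codes, medication codes, NLP-derived scores.  The exact
treatment $A \in \{0,1\}$ and outcome $Y$ are only ascertained by manual
chart review on a small random subset, flagged by $R \in \{0,1\}$, with
labeling fraction $\rho = E(R)$ small (hundreds of labels against tens of
thousands of records).  Because the surrogates were generated *from* the
true $A$ and $Y$, treating them as the truth biases any downstream causal
contrast, while discarding the unlabeled majority wastes most of the data.

The package estimates the average treatment effect
$$\Delta^* = E\{Y(1) - Y(0)\} = E\{\mu^*(1,X) - \mu^*(0,X)\},
\qquad \mu^*(a,X) = E(Y \mid A=a, X),$$
under (i) consistency, (ii) positivity of the propensity
$\pi^*(a,X) = P(A=a\mid X)$, (iii) ignorability of $A$ given $X$, and (iv) a
missing-completely-at-random labeling mechanism
$R \perp (Y, A, X, S)$.  MCAR holds by design whenever the chart-review
subset is drawn at random, which is the sampling scheme the package
assumes; the label count $n = \sum_i R_i$ is then Binomial$(N, \rho)$ and
$\hat\rho = n/N$ is plugged in wherever $\rho$ appears.

## The estimator

Four nuisance models enter: the propensity $\pi(a,X)$ and outcome
regression $\mu(a,X)$ on confounders, and the *imputation models*
$\Pi(a,W) = P(A=a\mid W)$ and $m(a,W) = E(Y \mid A=a, W)$ on
$W = (X^\top, S^\top)^\top$.  The imputation models carry the surrogate
information to the unlabeled subjects; they do **not** need to be correctly
specified for valid inference — mis-specifying them costs efficiency, never
validity.

Starting from the complete-data AIPW influence function
$$\varphi_{\mathrm{cmp}} = \mu(1,X) - \mu(0,X)
 + \frac{I(A=1)\{Y-\mu(1,X)\}}{\pi(1,X)}
 - \frac{I(A=0)\{Y-\mu(0,X)\}}{\pi(0,X)} - \Delta,$$
the semi-supervised influence function is obtained by projecting onto the
always-observed $W$ and re-weighting the labeled residual by $R/\rho$:
$$\varphi_{\mathrm{SSL}} = E(\varphi_{\mathrm{cmp}}\mid W)
 + \frac{R}{\rho}\{\varphi_{\mathrm{cmp}} - E(\varphi_{\mathrm{cmp}}\mid W)\}.$$
`influence_values()` evaluates the resulting per-subject values
$\widehat{\mathcal V}_i$ with cross-fitted nuisance estimates; the point
estimate is their cohort mean, and the variance of the $\sqrt n$-scaled
error is estimated by $\hat V = (\hat\rho / N)\sum_i (\widehat{\mathcal
V}_i - \hat\Delta)^2$, i.e. $\hat\rho$ times the empirical variance over
*all* $N$ subjects.  Averaging over everyone (not just the labeled rows)
captures the uncertainty contributed by the large-but-finite unlabeled set;
confidence intervals are $\hat\Delta \pm z_{\alpha/2}\sqrt{\hat V / n}$.
When every subject is labeled ($R \equiv 1$, $\rho = 1$) the imputation
terms cancel algebraically and the estimator reduces *exactly* to
cross-fitted complete-data AIPW; the test suite asserts this identity to
$10^{-12}$.

All nuisance fits are cross-fitted: the cohort (labeled and unlabeled rows
together, since $R$ is exchangeable under MCAR) is split into $K$ folds
(`assign_folds()`, default $K=10$), and subject $i$'s predictions come from
fits that never saw fold$(i)$.  A fold whose out-of-fold labeled subset
lacks one treatment arm would make the arm-specific regressions
unfittable; `assign_folds_checked()` re-draws such degenerate partitions
up to 20 times with incremented seeds before failing — a stated convention,
since the procedure itself is silent on this corner case.

## Low-dimensional route: tensor-product spline logistic regressions

With a handful of continuous confounders the four models are fitted by
logistic regression on tensor products of order-1 (piecewise-linear)
B-spline bases with equally spaced interior knots on the training range
(`fit_nuisances_spline()`).  The per-dimension degree is selected by
10-fold cross-validated out-of-fold entropy among $1,\dots,\lfloor\sqrt
n\rfloor$ candidates, ties toward the smaller degree; for the
multi-dimensional $W$-models the candidates are additionally capped so the
tensor basis has at most $\max(8, n/3)$ columns — with three dimensions and
$\approx 450$ training rows that admits up to $5^3 = 125$ basis functions,
which is already saturated relative to the sample.  Selection is done per
(fold, model) with its own seeded split, so no subject's prediction
depends on its own row even through the tuning parameter.

Positivity is enforced by clipping the *propensity* predictions into
$[g(-M), g(M)]$ with $g$ the logistic link and $M = 2.2$ by default (the
conventional $[0.1, 0.9]$ window).  The outcome and imputation
probabilities are clipped only at a numerical epsilon ($10^{-6}$): the
validity conditions bound $1/\hat\pi$ but merely require the other three
models to be bounded, which probabilities are automatically.  Clipping
$\hat\Pi$ or $\hat m$ into $[0.1, 0.9]$ would deliberately destroy the
imputation models exactly when the surrogates are most informative, so the
package does not do it.  We clip fitted probabilities rather than linear
predictors; under a monotone link the two are equivalent.

Degenerate inputs behave predictably: a constant-outcome arm saturates to
the clipped bound (a small ridge, $10^{-6} n$, keeps every normal-equation
solve defined under separation or empty spline cells), and extrapolation
beyond the training range is clamped to the boundary knots.

## High-dimensional route: calibrated lasso with two-level cross-fitting

With $p$ comparable to or exceeding $n$, all models are logistic-linear
and fitted with $\ell_1$ penalties (intercepts never penalized).  The
imputation fits (`fit_imputation()`) and the *initial* propensity/outcome
fits (`fit_initial()`) are plain cross-validated logistic lassos, run
through glmnet.  The initial fits exist per unordered fold pair
$(k_1,k_2)$, trained on the labeled rows outside both folds — with
$K = 10$ that is 80% of the data, the advantage of two-level cross-fitting
over sample splitting.

The final propensity and outcome fits minimize *calibrated* losses
(`fit_calibrated()`), constructed so that their first-order conditions
zero out the derivative of the ATE estimator with respect to the other
model (Neyman orthogonality), which is what converts consistency of one
model into valid inference when the other is wrong.  Writing
$\tau(x) = \mathrm{sign}(x)\min(|x|, 2M)$ for truncation at twice the
positivity constant:

* calibrated propensity, arm $a$:
  $\dot g\{\tau(X^\top\beta_{\mathrm{init}})\}\,
  \{(a - A)\,\alpha^\top X + I(A=a)\, e^{(-1)^a \alpha^\top X}\}$.
  The derivative weight $\dot g(\cdot)$ multiplies the whole bracket; with
  this grouping the true coefficients solve the population calibration
  equation for *any* initial outcome fit (substituting
  $g(t)e^{-t} = 1-g(t)$ makes the gradient vanish identically), and the
  equation is precisely the orthogonality condition of the estimator.  The
  weight-on-the-linear-term-only variant fails both properties — we
  verified the failure analytically and numerically before settling on
  this form.
* calibrated outcome, arm $a$:
  $\exp\{\tau((-1)^a X^\top\alpha_{\mathrm{init}})\}\,\ell(Y, \beta^\top
  X)$ with $\ell$ the logistic loss — a weighted logistic lasso whose
  weights the truncation confines to $[e^{-2M}, e^{2M}]$ no matter how bad
  the initial fit is.  This is what removes any sparsity requirement on a
  mis-specified initial model.

For target fold $k_1$ the calibrated objectives aggregate the labeled rows
of every other fold $k_2$, each row weighted through the initial fit
trained outside **both** $k_1$ and $k_2$; the propensity loss is
normalized by the total label count $n$ and the outcome loss by the number
of arm rows actually summed over.  Predictions are
$\hat\pi(1,X)=g\{\tau(X^\top\hat\alpha_1)\}$,
$\hat\pi(0,X)=g\{\tau(-X^\top\hat\alpha_0)\}$ (separate per-arm
calibrations, so the two need not sum to one),
$\hat\mu(a,X)=g(X^\top\hat\beta_a)$, $\hat\Pi(1,W)=g(W^\top\hat\xi)$ with
the arm-0 value taken as the complement, and
$\hat m(a,W)=g(W^\top\hat\zeta_a)$.

### Solver and tuning

The calibrated propensity loss is convex but not a GLM family, so the
package ships a FISTA proximal-gradient solver with backtracking line
search and adaptive restart (`src/prox_lasso.cpp`), used for that loss and
for the exported `logistic_lasso()`; solutions are certified by their KKT
residual (default tolerance $10^{-6}$, budget $5\times10^4$ iterations,
non-convergence is an error carrying the residual).  Exponent arguments
are clamped at $\pm 30$ with a diagnostic counter; the truncation makes
the clamp unreachable for initial-fit arguments, but trial iterates can
transiently exceed it.  Below roughly a tenth of $\lambda_{\max}$ the
finite-sample calibrated objective can be unbounded (only the labeled
arm's exponential term restrains the linear one), so cross-validation
grids for that loss stop at $\lambda_{\max}/10$, divergent path solves are
flagged and restarted cold, and their out-of-fold loss naturally rejects
such penalties.  `cv_lambda()` selects penalties by out-of-fold loss *of
the same loss kind* on 50 log-spaced values descending from
$\lambda_{\max}$ (ties toward the larger penalty); the selected value is
rescaled to the normalization of the fit it is used in.  Covariates are
standardized inside the solvers and coefficients returned on the original
scale.

## Benchmarks

* `supervised_estimate()` — cross-fitted AIPW on the labeled subset alone
  (the supervised double-machine-learning benchmark), sharing the same
  $\hat\pi,\hat\mu$.
* `unsupervised_estimate()` — dichotomizes each surrogate at the sample
  quantile matching the labeled prevalence of its target and runs
  complete-data AIPW on all $N$ as if the dichotomized values were true;
  it exists to demonstrate the bias and under-coverage of treating
  surrogates as labels.
* `crude_estimate()` — unadjusted arm-mean differences (labeled subset, or
  dichotomized over all $N$).
* `ensemble_estimate()` — the variance-optimal linear combination
  $\hat\Delta_{\mathrm{SMMAL}} + \hat b(\hat\Delta_{\mathrm{SL}} -
  \hat\Delta_{\mathrm{SMMAL}})$ with $\hat b$ from the empirical variances
  and covariance of the two influence vectors, a safety net when the
  imputation quality is in doubt; a numerically non-positive denominator
  falls back to $\hat b = 0$ with a warning.

## The synthetic-data generator

`simulate_cohort()` reproduces the study designs used throughout the
package's own evaluation, with one named RNG substream per component
($X, A, Y, S_A, S_Y, R$) so that changing one knob perturbs only its
stream, and bitwise reproducibility under a fixed seed.

**Low-dimensional smooth design.**  $X \sim U(0,1)$;
$\pi^*(1,X) = \mu^*(1,X) = 1 - 1.2/(3 - X^2)$ and
$\mu^*(0,X) = 1 - 1.2/(3 - (1-X)^2)$.  This expression admits more than
one grouping when written without parentheses; the left-to-right reading
$0.6 - X^2$ exits $[0,1]$ and violates positivity, so it cannot be
meant.  The adopted grouping is the default, the alternative grouping
$1 - 1.2/(3-X)^2$ (also positive, also symmetric) is available via
`formula_reading = "sq_ratio"`, and the choice is stamped into the cohort
metadata.  Under either reading the control curve is the treated curve
evaluated at $1-X$, so by the symmetry of $U(0,1)$ the true ATE is exactly
0 — which is what coverage is assessed against.  The closed-form
posteriors $P(A=1\mid X,S_A,S_Y)$ and $P(Y=1\mid A,X,S_Y)$ are attached to
the truth object, giving exact references for the imputation-model error
diagnostics $\max_a \{E(\hat h(a,W) - h^*(a,W))^2\}^{1/2}$
(`nuisance_mse()`).

**High-dimensional designs.**  $X$ is AR(1) Gaussian
($X_1 = U_1$, $X_j = 0.5X_{j-1} + 0.75U_j$; stationary variance $0.75$),
default $p = 500$, with logistic models on $X_1..X_3$ at signal strengths
$0.5/0.25/0.125/0.0625$.  The interaction variants multiply the linear
index by $(1 + 0.0625X_1 + 0.125X_2 - 0.5X_3)$ — read as a product, the
only reading consistent with "second-order interactions" — while the
working models stay linear, creating the mis-specified-propensity and
mis-specified-outcome scenarios.  The true ATE has no closed form and is
attached by a $10^6$-draw Monte-Carlo oracle together with its standard
error; recovery tests use $\max(3\,\mathrm{SE}, 0.002)$ as their
tolerance.

**Surrogates.**  $S = \mathrm{Beta}(\alpha + u, 1)$ under a positive
latent and $\mathrm{Beta}(1, \alpha + u)$ under a negative one, with
$u = X$ (low-d) or $u = \Phi(X_1)$ (high-d), both marginally uniform so
the same $\alpha \mapsto$ AUC calibration applies; `surrogate_alpha()` maps
the five calibrated accuracy levels (AUC 0.80–0.999) to their per-design
$\alpha$ values, taken verbatim per design even where they differ slightly
(each design's marginal prevalence differs, so the calibration is
per-design).  `surrogate_auc()` recomputes any calibration by rank-based
Monte Carlo, and the tests cross-check it against the conditional closed
form $P\{\mathrm{Beta}(a_1,1) > \mathrm{Beta}(1,a_0)\} = 1 - a_1
B(a_1, a_0+1)$ averaged over covariate draws.

What the generator does *not* emulate: real EHR feature engineering
(code counts, collider-prone utilization features), informative labeling
(MAR or worse), continuous or censored outcomes, and surrogates whose
dependence on $(A, Y)$ is more complex than a one-parameter location
shift.  Passing tests therefore demonstrate correctness of the estimator
under its stated assumptions, not robustness to their failure.

## Evaluation harness and problem sizes

`run_replicates()` regenerates a fresh cohort per replicate (common random
numbers across estimators within a replicate, so relative-efficiency
ratios are stable at modest replicate counts), aggregates bias, empirical
SD, mean SE, coverage, and relative efficiency as the ratio of empirical
variances, and logs failed replicates rather than dying.
`heatmap_grid()` sweeps the surrogate-quality grid (5 × 5 calibrated
levels in the full design).

The package's own evaluation uses desk-scale sizes, chosen once: 200
replicates for the low-dimensional design at $N = 10^4$, $n = 500$,
$K = 10$; 100 replicates for each high-dimensional mis-specification
scenario at $p = 100$, $K = 5$ with penalty selection shared across folds
within a replicate (the full $p = 500$, $K = 10$, 1000-replicate sweep is
cluster-scale).  The unsupervised benchmark, whose complete-data fits see
all $N$ rows, shares its spline degrees across folds and caps candidates
at 22 for the same reason.  These scopes trade a small amount of per-fold
adaptivity for replicate throughput and are stamped into each summary's
metadata.

## Known limitations

* MCAR only; extending to labeling that depends on $W$ would require
  modeling the labeling propensity and recalibrating all five models.
* Binary (or bounded, via the logistic working model) outcomes in the
  high-dimensional route; continuous-outcome calibration would need a
  different link and loss.
* The efficiency gain degrades gracefully to none as surrogates become
  uninformative, but no attempt is made to *select* informative surrogate
  subsets; `fit_imputation(design_cols = ...)` merely lets the user
  restrict the imputation design by hand.
* The ensemble weight is estimated from the same data as the estimates it
  combines; its optimality is first-order and in-sample.
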