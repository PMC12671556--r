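# K-fold partitioning of the whole cohort (labeled and unlabeled together)
# and the ordered fold-pair structure used by two-level cross-fitting.

#' Balanced random fold assignment
#'
#' Splits all `N` subjects into `K` folds of size differing by at most one,
#' without stratifying on the label indicator: under MCAR the labels are
#' exchangeable, so the whole cohort is split jointly.
#'
#' @param N number of subjects.
#' @param K number of folds, at least 3 (two-level cross-fitting needs a
#'   nonempty out-of-two-folds set).
#' @param seed RNG seed.
#' @return object of class `fold_assignment` with fields `K`, `fold_of`
#'   (length-`N` integer vector in `1..K`) and `seed`.
#' @export
assign_folds <- function(N, K, seed = 1L) {
  N <- as.integer(N); K <- as.integer(K)
  if (K < 3L) stop("K must be at least 3")
  if (K > N) stop("K cannot exceed N")
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(K), N))
  structure(list(K = K, fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Fold assignment: N = %d subjects in K = %d folds (seed %d)\n",
              length(x$fold_of), x$K, x$seed))
  cat("  fold sizes:", paste(tabulate(x$fold_of, x$K), collapse = " "), "\n")
  invisible(x)
}

#' Indices outside one fold
#' @param folds a `fold_assignment`.
#' @param k fold index.
#' @return integer indices of subjects not in fold `k`.
#' @export
out_of_fold <- function(folds, k) which(folds$fold_of != k)

#' Indices outside two folds
#' @param folds a `fold_assignment`.
#' @param k1,k2 distinct fold indices.
#' @return integer indices of subjects in neither fold.
#' @export
out_of_two <- function(folds, k1, k2) {
  if (k1 == k2) stop("k1 and k2 must differ")
  which(folds$fold_of != k1 & folds$fold_of != k2)
}

#' All ordered fold pairs
#'
#' Pair `(k1, k2)` indexes the initial fit trained outside both folds and
#' later applied to fold `k2` rows inside the calibrated fit for target
#' fold `k1`.
#'
#' @param K number of folds.
#' @return two-column integer matrix with `K (K - 1)` rows.
#' @export
fold_pairs <- function(K) {
  if (K < 3L) stop("K must be at least 3")
  g <- expand.grid(k2 = seq_len(K), k1 = seq_len(K))
  g <- g[g$k1 != g$k2, c("k1", "k2")]
  as.matrix(g[order(g$k1, g$k2), , drop = FALSE])
}

# A partition is usable when every training set the pipeline will form
# contains both treatment arms among its labeled rows.
.folds_usable <- function(folds, r, a, check_pairs = FALSE) {
  lab <- r == 1L
  for (k in seq_len(folds$K)) {
    idx <- out_of_fold(folds, k)
    arms <- a[idx][lab[idx]]
    if (length(unique(arms[!is.na(arms)])) < 2L) return(FALSE)
  }
  if (check_pairs) {
    for (k1 in seq_len(folds$K - 1L)) for (k2 in (k1 + 1L):folds$K) {
      idx <- out_of_two(folds, k1, k2)
      arms <- a[idx][lab[idx]]
      if (length(unique(arms[!is.na(arms)])) < 2L) return(FALSE)
    }
  }
  TRUE
}

#' Fold assignment with a retry policy for degenerate partitions
#'
#' A fold whose out-of-fold labeled subset lacks one treatment arm makes
#' the arm-specific outcome models unfittable.  The partition is re-drawn
#' with an incremented seed up to `max_retry` times before failing.
#'
#' @inheritParams assign_folds
#' @param cohort an `ssl_cohort` supplying labels and treatment arms.
#' @param check_pairs also require both arms in every out-of-two-folds
#'   labeled subset (needed by two-level cross-fitting).
#' @param max_retry maximum number of re-draws.
#' @return a usable `fold_assignment`.
#' @export
assign_folds_checked <- function(cohort, K, seed = 1L, check_pairs = FALSE,
                                 max_retry = 20L) {
  for (i in 0:max_retry) {
    folds <- assign_folds(cohort$N, K, seed + i)
    if (.folds_usable(folds, cohort$r, cohort$a, check_pairs)) {
      if (i > 0L)
        folds$retries <- i
      return(folds)
    }
  }
  stop("no usable fold assignment after ", max_retry + 1L,
       " draws: some training set lacks a treatment arm among its ",
       "labeled rows")
}
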