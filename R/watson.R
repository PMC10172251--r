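## Watson's U2 two-sample test for circular data, with a seeded permutation
## p-value. The statistic is rotation-invariant, so it compares angular
## *distributions* regardless of any common reference rotation.

## Internal core: U2 from a pooled sorted layout.
## ord sorts the pooled sample; runs mark tie groups (ECDF differences are
## evaluated after consuming all observations tied at a value, so identical
## samples give exactly 0). labels is logical: TRUE = sample 1.
.watson_u2_core <- function(lab_sorted, run_end, run_len, n1, n2) {
  n <- n1 + n2
  c1 <- cumsum(lab_sorted)
  d <- c1[run_end] / n1 - (run_end - c1[run_end]) / n2
  sd1 <- sum(run_len * d)
  sd2 <- sum(run_len * d^2)
  (n1 * n2 / n^2) * (sd2 - sd1^2 / n)
}

.watson_layout <- function(pooled) {
  ord <- order(pooled)
  v <- pooled[ord]
  run_end <- which(c(v[-1] != v[-length(v)], TRUE))
  run_len <- diff(c(0L, run_end))
  list(ord = ord, run_end = run_end, run_len = run_len)
}

#' Watson's U2 statistic for two circular samples
#'
#' Nonparametric two-sample statistic
#' \eqn{U^2 = \frac{n_1 n_2}{N^2}\left[\sum_k d_k^2 - (\sum_k d_k)^2/N\right]}
#' where \eqn{d_k = F_1(\theta_k) - F_2(\theta_k)} are pooled-ECDF
#' differences, each evaluated after consuming all observations tied at
#' \eqn{\theta_k}, and the sums run over the N pooled observations.
#' Invariant under a common rotation of both samples, which makes it the
#' appropriate comparison for angles measured relative to arbitrary
#' reference directions.
#'
#' @param s1,s2 numeric vectors of angles in degrees, each n >= 2.
#' @return the U2 statistic (>= 0).
#' @references Watson, G. S. (1962) Goodness-of-fit tests on a circle II.
#'   Biometrika 49, 57-63.
#' @export
watson_u2 <- function(s1, s2) {
  s1 <- wrap_angle(s1); s2 <- wrap_angle(s2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2 || n2 < 2)
    stop("each sample needs at least 2 angles", call. = FALSE)
  pooled <- c(s1, s2)
  lay <- .watson_layout(pooled)
  lab <- c(rep(TRUE, n1), rep(FALSE, n2))[lay$ord]
  .watson_u2_core(lab, lay$run_end, lay$run_len, n1, n2)
}

#' Watson's U2 test with permutation p-value
#'
#' Compares two angular samples by Watson's U2 with a p-value from random
#' relabelling of the pooled angles into groups of the original sizes:
#' p = (1 + #\{permuted U2 >= observed\}) / (1 + n_permutations).
#' Deterministic given `seed`.
#'
#' @inheritParams watson_u2
#' @param n_permutations number of relabellings, >= 99.
#' @param seed integer seed for the permutation stream.
#' @return object of class `"watson_test"`: list with `u2`, `p_value`,
#'   `n1`, `n2`, `n_permutations`, `seed`.
#' @examples
#' set.seed(1)
#' watson_u2_test(runif(20, -180, 180), runif(20, -180, 180),
#'                n_permutations = 99, seed = 1)
#' @export
watson_u2_test <- function(s1, s2, n_permutations = 999, seed = 1) {
  if (n_permutations < 99)
    stop("n_permutations must be at least 99", call. = FALSE)
  s1 <- wrap_angle(s1); s2 <- wrap_angle(s2)
  n1 <- length(s1); n2 <- length(s2)
  if (n1 < 2 || n2 < 2)
    stop("each sample needs at least 2 angles", call. = FALSE)
  pooled <- c(s1, s2)
  lay <- .watson_layout(pooled)
  lab0 <- c(rep(TRUE, n1), rep(FALSE, n2))[lay$ord]
  obs <- .watson_u2_core(lab0, lay$run_end, lay$run_len, n1, n2)

  n <- n1 + n2
  ## tie-run layout is a property of the pooled values only, so each
  ## permutation just re-draws which sorted slots belong to sample 1
  count <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      lab <- logical(n)
      lab[sample.int(n, n1)] <- TRUE
      u <- .watson_u2_core(lab, lay$run_end, lay$run_len, n1, n2)
      if (u >= obs - 1e-12) count <- count + 1L
    }
  })
  out <- list(u2 = obs, p_value = (1 + count) / (1 + n_permutations),
              n1 = n1, n2 = n2, n_permutations = n_permutations, seed = seed)
  class(out) <- "watson_test"
  out
}

#' @export
print.watson_test <- function(x, ...) {
  cat("Watson two-sample U2 test (permutation)\n")
  cat(sprintf("  U2 = %.5f, p = %.4g  (n1 = %d, n2 = %d, %d permutations, seed %d)\n",
              x$u2, x$p_value, x$n1, x$n2, x$n_permutations, x$seed))
  invisible(x)
}

## Evaluate a block under a private RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}
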