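# Two-sided bootstrap test for equality of means, plus box-plot summaries.

#' Bootstrap test for equality of two group means
#'
#' Shift bootstrap: the null of equal means is enforced by translating each
#' group to the pooled mean; `B` replicates resample each shifted group
#' with replacement at its own size and the two-sided p-value is the
#' add-one estimator `p = (1 + #{|T*| >= |T_obs|}) / (B + 1)` for
#' `T = mean(A) - mean(B)`. The smallest attainable p-value is therefore
#' `1/(B+1)` and `p` is invariant to swapping the groups.
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return Object of class `"boot_eq_test"` with fields `T_obs`, `B`,
#'   `p_value`, `seed`, `nA`, `nB`, `mean_A`, `mean_B`; `tidy()`/`glance()`
#'   return it as a one-row tibble.
#' @export
boot_mean_eq_test <- function(groupA, groupB, B = 1000, seed) {
  if (length(groupA) == 0 || length(groupB) == 0) abort("empty group")
  stopifnot(B >= 1)
  if (missing(seed)) abort("an explicit seed is required")
  nA <- length(groupA); nB <- length(groupB)
  T_obs <- mean(groupA) - mean(groupB)
  pooled <- mean(c(groupA, groupB))
  A0 <- groupA - mean(groupA) + pooled
  B0 <- groupB - mean(groupB) + pooled
  # draw replicates in a canonical group order so that swapping the groups
  # reproduces the same |T*| stream (exact two-sided symmetry)
  key <- function(v) paste(format(v, digits = 15), collapse = ",")
  canonical <- key(A0) <= key(B0)
  g1 <- if (canonical) A0 else B0
  g2 <- if (canonical) B0 else A0
  Tstar <- withr::with_seed(seed, {
    m1 <- matrix(sample(g1, length(g1) * B, replace = TRUE), nrow = length(g1))
    m2 <- matrix(sample(g2, length(g2) * B, replace = TRUE), nrow = length(g2))
    colMeans(m1) - colMeans(m2)
  })
  p <- (1 + sum(abs(Tstar) >= abs(T_obs))) / (B + 1)
  structure(
    list(T_obs = T_obs, B = B, p_value = p, seed = seed,
         nA = nA, nB = nB, mean_A = mean(groupA), mean_B = mean(groupB)),
    class = "boot_eq_test"
  )
}

#' @export
print.boot_eq_test <- function(x, ...) {
  cat(sprintf(
    "Two-sided bootstrap equality-of-means test (shift bootstrap)\n  mean A = %.4g (n = %d), mean B = %.4g (n = %d)\n  T_obs = %.4g, B = %d, p = %.4g\n",
    x$mean_A, x$nA, x$mean_B, x$nB, x$T_obs, x$B, x$p_value))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.boot_eq_test <- function(x, ...) {
  tibble(T_obs = x$T_obs, p_value = x$p_value, B = x$B,
         nA = x$nA, nB = x$nB, mean_A = x$mean_A, mean_B = x$mean_B,
         seed = x$seed)
}

#' @export
#' @exportS3Method generics::glance
glance.boot_eq_test <- function(x, ...) tidy(x)

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation ([stats::quantile()] type 7); whiskers
#' are the most extreme data points within 1.5 x IQR of the box bounds.
#'
#' @param values Numeric vector (n >= 1).
#' @return One-row tibble: `q25`, `median`, `q75`, `whisker_lo`,
#'   `whisker_hi`, `n`, `n_outliers`.
#' @export
box_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  tibble(q25 = q[1], median = q[2], q75 = q[3],
         whisker_lo = min(inside), whisker_hi = max(inside),
         n = length(values), n_outliers = length(values) - length(inside))
}
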