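#' Cohen's d
#'
#' Standardized mean difference `(mean1 - mean2) / s_pooled`, with the
#' pooled standard deviation using the `n1 + n2 - 2` denominator.
#'
#' @param group1,group2 Numeric vectors, each with at least two non-missing
#'   values.
#' @return Signed effect size, unitless.
#' @export
cohens_d <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two values")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(group1) - mean(group2)) / sqrt(sp2)
}

#' A-priori power of the Wilcoxon rank-sum test
#'
#' Power to detect a standardized shift of Cohen's d between two normal
#' populations with a (one- or two-tailed) Wilcoxon rank-sum test at level
#' `alpha`. The default `are_approx` method evaluates two-sample t-test
#' power (noncentral t) at effective group sizes `n_i * 3 / pi`, the
#' asymptotic relative efficiency of the rank-sum test versus the t-test
#' under a normal shift; `monte_carlo` estimates the rejection rate by
#' seeded simulation. Unequal allocation is supported via distinct `n1`,
#' `n2`.
#'
#' @param d Cohen's d (standardized mean difference of group 1 over
#'   group 2; the one-tailed test is taken in the direction of `d`).
#' @param n1,n2 Group sizes, each at least 2.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @param tails `"one"` (default) or `"two"`.
#' @param method `"are_approx"` (default) or `"monte_carlo"`.
#' @param reps Monte-Carlo repetitions. Default 10000.
#' @param seed Optional integer seed for the Monte-Carlo method.
#' @return Power in `[0, 1]`; equals `alpha` at `d = 0`.
#' @export
wrs_power <- function(d, n1, n2, alpha = 0.05, tails = c("one", "two"),
                      method = c("are_approx", "monte_carlo"),
                      reps = 10000L, seed = NULL) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  if (n1 < 2L || n2 < 2L) stop("group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (method == "are_approx")
    return(t_shift_power(abs(d), n1 * 3 / pi, n2 * 3 / pi, alpha, tails))
  alt <- if (tails == "one") "greater" else "two.sided"
  rej <- local_rng(seed, {
    vapply(seq_len(reps), function(r) {
      a <- stats::rnorm(n1, mean = abs(d))
      b <- stats::rnorm(n2)
      suppressWarnings(
        stats::wilcox.test(a, b, alternative = alt,
                           exact = FALSE, correct = TRUE)$p.value) <= alpha
    }, logical(1))
  })
  mean(rej)
}

# Two-sample t power under a normal shift of d pooled-SD units, allowing
# non-integer effective group sizes.
t_shift_power <- function(d, n1, n2, alpha, tails) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == "one") {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' Tabulated power surface with bilinear interpolation
#'
#' Evaluates [wrs_power()] over a (d, n) grid (equal group sizes of n per
#' group) and returns the table together with a bilinear interpolator for
#' off-grid queries. Queries outside the grid hull are refused rather than
#' extrapolated.
#'
#' @param d_grid Strictly increasing effect sizes, length >= 2.
#' @param n_grid Strictly increasing per-group sample sizes, length >= 2.
#' @param alpha Significance level. Default 0.05.
#' @param tails `"one"` (default) or `"two"`.
#' @param method Passed to [wrs_power()].
#' @return List of class `"power_surface"`: `d_grid`, `n_grid`, `power`
#'   (matrix, d in rows) and `interpolate(d, n)`.
#' @export
power_surface <- function(d_grid, n_grid, alpha = 0.05,
                          tails = c("one", "two"), method = "are_approx") {
  tails <- match.arg(tails)
  if (length(d_grid) < 2L || any(diff(d_grid) <= 0))
    stop("d_grid must be strictly increasing, length >= 2")
  if (length(n_grid) < 2L || any(diff(n_grid) <= 0))
    stop("n_grid must be strictly increasing, length >= 2")
  pow <- outer(d_grid, n_grid, Vectorize(function(d, n)
    wrs_power(d, n, n, alpha = alpha, tails = tails, method = method)))
  dimnames(pow) <- list(d = d_grid, n = n_grid)
  interp <- function(d, n) {
    if (d < d_grid[1L] || d > d_grid[length(d_grid)] ||
        n < n_grid[1L] || n > n_grid[length(n_grid)])
      stop("query (d = ", d, ", n = ", n, ") outside the tabulated grid")
    i <- max(findInterval(d, d_grid), 1L); i <- min(i, length(d_grid) - 1L)
    j <- max(findInterval(n, n_grid), 1L); j <- min(j, length(n_grid) - 1L)
    td <- (d - d_grid[i]) / (d_grid[i + 1L] - d_grid[i])
    tn <- (n - n_grid[j]) / (n_grid[j + 1L] - n_grid[j])
    (1 - td) * (1 - tn) * pow[i, j] + td * (1 - tn) * pow[i + 1L, j] +
      (1 - td) * tn * pow[i, j + 1L] + td * tn * pow[i + 1L, j + 1L]
  }
  structure(list(d_grid = d_grid, n_grid = n_grid, power = pow,
                 interpolate = interp),
            class = "power_surface")
}
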