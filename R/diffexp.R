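#' Log2 fold change between two groups
#'
#' Difference of group medians on the log2 scale, equal to log2 of the ratio
#' of linear-scale medians (median commutes with monotone transforms).
#' Antisymmetric: `fold_change(a, b) == -fold_change(b, a)`.
#'
#' @param group1,group2 Numeric vectors of log2 intensities; `NA` dropped.
#' @return `median(group1) - median(group2)`.
#' @export
fold_change <- function(group1, group2) {
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (!length(group1) || !length(group2))
    stop("fold_change: empty group")
  stats::median(group1) - stats::median(group2)
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Wraps [stats::wilcox.test()] with the conventions used throughout the
#' package: the one-sided p-value is exact (full enumeration) when the total
#' sample size is at most `exact_threshold` and there are no ties, and a
#' normal approximation with midrank tie correction and continuity
#' correction otherwise. With `alternative = "auto"` the tested tail follows
#' the sign of the observed median difference (group1 greater when
#' `median(group1) >= median(group2)`) and the one-sided p is doubled
#' (capped at 1): picking the tail from the data and reporting the raw
#' one-sided p would double the null rejection rate and void downstream FDR
#' control, as a label-permutation check readily shows. Set
#' `adjust_auto = FALSE` for the unadjusted one-sided p under `"auto"`;
#' an explicitly requested tail is never adjusted.
#'
#' @param group1,group2 Numeric vectors; `NA` dropped.
#' @param alternative `"auto"` (default), `"greater"` (group1 shifted up) or
#'   `"less"`.
#' @param exact_threshold Largest `n1 + n2` for which the exact distribution
#'   is used (ties permitting). Default 12.
#' @param adjust_auto Double the one-sided p when the tail was chosen from
#'   the data. Default `TRUE`.
#' @return List with `p_value`, `direction` (`"up_in_group1"` or
#'   `"up_in_group2"`: the tail actually tested) and `statistic` (the
#'   Mann-Whitney U of group1).
#' @export
wrs_test <- function(group1, group2,
                     alternative = c("auto", "greater", "less"),
                     exact_threshold = 12L, adjust_auto = TRUE) {
  alternative <- match.arg(alternative)
  group1 <- group1[!is.na(group1)]
  group2 <- group2[!is.na(group2)]
  if (!length(group1) || !length(group2)) stop("wrs_test: empty group")
  adjust <- alternative == "auto" && adjust_auto
  if (alternative == "auto") {
    alternative <- if (stats::median(group1) >= stats::median(group2))
      "greater" else "less"
  }
  n <- length(group1) + length(group2)
  ties <- anyDuplicated(c(group1, group2)) > 0L
  use_exact <- (n <= exact_threshold) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group1, group2, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  p <- unname(ht$p.value)
  if (adjust) p <- min(1, 2 * p)
  list(p_value = p,
       direction = if (alternative == "greater") "up_in_group1"
                   else "up_in_group2",
       statistic = unname(ht$statistic))
}

#' Benjamini-Hochberg adjusted Q-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation:
#' all p-values must lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Vector of Q-values, same order, clipped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-miRNA differential expression table
#'
#' Runs the fold-change / one-tailed Wilcoxon rank-sum / BH pipeline on every
#' feature of an expression matrix, contrasting two levels of a clinical
#' label. Features with fewer than `min_per_group` non-missing values in
#' either group are skipped (listed in the `"skipped"` attribute) and the BH
#' correction runs over the retained features only.
#'
#' @param x Numeric matrix, features x samples.
#' @param samples data.frame with `sample_id` matching `colnames(x)` plus
#'   label columns.
#' @param label Name of the label column to contrast.
#' @param level1,level2 The two label values; fold change and test direction
#'   are reported for `level1` relative to `level2`.
#' @param min_per_group Minimum non-missing values per group. Default 3.
#' @param alternative,adjust_auto Passed to [wrs_test()]; the default tests
#'   each miRNA in the direction of its observed median difference, with the
#'   direction-adjusted p-value.
#' @return data.frame with columns `mirna_id`, `fold_change`, `p_value`,
#'   `q_value`, `direction`, `n1`, `n2`; attribute `"skipped"` holds a
#'   data.frame of skipped features and reasons.
#' @export
de_table <- function(x, samples, label, level1, level2,
                     min_per_group = 3L, alternative = "auto",
                     adjust_auto = TRUE) {
  stopifnot(is.matrix(x), is.data.frame(samples))
  if (!label %in% colnames(samples))
    stop("label column '", label, "' absent from sample metadata")
  lab <- samples[[label]][match(colnames(x), samples$sample_id)]
  g1 <- which(lab == level1)
  g2 <- which(lab == level2)
  if (!length(g1)) stop("no samples with ", label, " = '", level1, "'")
  if (!length(g2)) stop("no samples with ", label, " = '", level2, "'")

  ids <- rownames(x)
  res <- vector("list", length(ids))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    v1 <- x[i, g1][!is.na(x[i, g1])]
    v2 <- x[i, g2][!is.na(x[i, g2])]
    if (length(v1) < min_per_group || length(v2) < min_per_group) {
      skipped <- c(skipped, ids[i])
      next
    }
    wt <- wrs_test(v1, v2, alternative = alternative,
                   adjust_auto = adjust_auto)
    res[[i]] <- data.frame(
      mirna_id = ids[i],
      fold_change = fold_change(v1, v2),
      p_value = wt$p_value,
      direction = wt$direction,
      n1 = length(v1), n2 = length(v2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    stop("no feature retained: every miRNA has fewer than ", min_per_group,
         " values per group")
  # wilcox.test can return p slightly above 1 is impossible; 0 can occur only
  # from underflow - clamp into (0, 1] for BH validity
  out$q_value <- bh_fdr(pmin(pmax(out$p_value, .Machine$double.xmin), 1))
  out <- out[, c("mirna_id", "fold_change", "p_value", "q_value",
                 "direction", "n1", "n2")]
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    mirna_id = skipped,
    reason = rep(sprintf("fewer than %d non-missing values in a group",
                         min_per_group), length(skipped)),
    stringsAsFactors = FALSE)
  out
}

#' Label-permutation null for the differential expression pipeline
#'
#' Permutes the clinical labels uniformly at random `n_perms` times
#' (seeded), reruns [de_table()] per permutation, and returns the Q-value
#' vectors — the null overlay for Q-value CDF plots.
#'
#' @inheritParams de_table
#' @param n_perms Number of permutations (0 gives an empty list).
#' @param seed Integer seed; the same seed reproduces the same permutations.
#' @return List of length `n_perms`; each element the `q_value` vector of one
#'   permuted run (named by miRNA id).
#' @export
permutation_null <- function(x, samples, label, level1, level2, n_perms,
                             seed = NULL, min_per_group = 3L) {
  n_perms <- as.integer(n_perms)
  if (n_perms < 0L) stop("n_perms must be >= 0")
  if (n_perms == 0L) return(list())
  local_rng(seed, {
    lapply(seq_len(n_perms), function(k) {
      perm <- samples
      perm[[label]] <- sample(perm[[label]])
      dt <- de_table(x, perm, label, level1, level2,
                     min_per_group = min_per_group)
      stats::setNames(dt$q_value, dt$mirna_id)
    })
  })
}

#' Pair two differential-expression runs
#'
#' Inner-joins two [de_table()] results on miRNA id and tabulates, per
#' miRNA, both Q-values and fold changes with their `-log10` transforms,
#' plus counts of miRNAs achieving a strictly lower Q-value in each run.
#'
#' @param run_a,run_b data.frames from [de_table()].
#' @return data.frame with columns `mirna_id`, `q_a`, `q_b`, `fc_a`, `fc_b`,
#'   `neglog10_q_a`, `neglog10_q_b`; attributes `"n_lower_a"` /
#'   `"n_lower_b"` count miRNAs with strictly lower Q in run a / run b.
#' @export
compare_runs <- function(run_a, run_b) {
  common <- intersect(run_a$mirna_id, run_b$mirna_id)
  if (!length(common)) stop("runs share no miRNA ids")
  a <- run_a[match(common, run_a$mirna_id), ]
  b <- run_b[match(common, run_b$mirna_id), ]
  out <- data.frame(
    mirna_id = common,
    q_a = a$q_value, q_b = b$q_value,
    fc_a = a$fold_change, fc_b = b$fold_change,
    neglog10_q_a = -log10(a$q_value),
    neglog10_q_b = -log10(b$q_value),
    stringsAsFactors = FALSE)
  attr(out, "n_lower_a") <- sum(out$q_a < out$q_b)
  attr(out, "n_lower_b") <- sum(out$q_b < out$q_a)
  out
}
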