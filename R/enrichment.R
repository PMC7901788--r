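#' Rank genes by anti-correlation with a miRNA
#'
#' Builds the pivot gene ranking for target-enrichment analysis: every gene
#' is Spearman-correlated (midranks for ties, pairwise-complete
#' observations) with the miRNA's expression over matched samples and genes
#' are sorted ascending — most anti-correlated first. Genes with fewer than
#' `min_obs` pairwise-complete observations are dropped (listed in the
#' `"dropped"` attribute); correlation ties break by gene id.
#'
#' @param mirna_values Named numeric vector: the miRNA's expression per
#'   sample id.
#' @param gene_matrix Numeric matrix, genes x samples.
#' @param min_obs Minimum paired observations per gene. Default 3.
#' @return data.frame `gene_id`, `score` (Spearman rho), ordered ascending
#'   by score.
#' @export
build_g_mu <- function(mirna_values, gene_matrix, min_obs = 3L) {
  stopifnot(is.matrix(gene_matrix))
  common <- intersect(names(mirna_values), colnames(gene_matrix))
  if (length(common) < 3L) stop("fewer than 3 paired samples")
  mv <- mirna_values[common]
  gm <- gene_matrix[, common, drop = FALSE]
  n_ok <- rowSums(!is.na(gm) & !is.na(matrix(mv, nrow(gm), length(mv),
                                             byrow = TRUE)))
  keep <- n_ok >= min_obs
  dropped <- rownames(gm)[!keep]
  gm <- gm[keep, , drop = FALSE]
  if (!nrow(gm)) stop("no gene with enough paired observations")
  rho <- suppressWarnings(
    as.vector(stats::cor(t(gm), mv, method = "spearman",
                         use = "pairwise.complete.obs")))
  # constant genes have no defined correlation; drop them too
  dropped <- c(dropped, rownames(gm)[is.na(rho)])
  gm <- gm[!is.na(rho), , drop = FALSE]
  rho <- rho[!is.na(rho)]
  if (!nrow(gm)) stop("no gene with a defined correlation")
  out <- data.frame(gene_id = rownames(gm), score = rho,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Minimum-hypergeometric enrichment statistic
#'
#' For a ranked binary membership vector, the mHG statistic is the minimum
#' over all prefixes of the hypergeometric upper-tail probability
#' `P(X >= k_n)` of seeing `k_n` ones in the first `n` positions when the
#' `K` ones are placed uniformly at random among the `N` slots. Small values
#' mean the ones crowd the top of the ranking.
#'
#' @param binary_vector Vector of 0/1 (or logical) memberships in ranked
#'   order, best rank first.
#' @return List with `mhg` (the minimal tail probability) and `n_star` (the
#'   smallest prefix length attaining it).
#' @export
mhg_statistic <- function(binary_vector) {
  v <- as.integer(binary_vector)
  if (length(v) < 1L || anyNA(v) || any(v != 0L & v != 1L))
    stop("binary_vector must contain only 0/1")
  n_tot <- length(v)
  k_tot <- sum(v)
  k_n <- cumsum(v)
  n <- seq_len(n_tot)
  tails <- stats::phyper(k_n - 1L, k_tot, n_tot - k_tot, n,
                         lower.tail = FALSE)
  n_star <- which.min(tails)
  list(mhg = tails[n_star], n_star = n_star)
}

#' Exact p-value for the mHG statistic
#'
#' Probability, over uniformly random arrangements of `K` ones among `N`
#' slots, that the mHG statistic is at most the observed value. `exact_dp`
#' runs the standard O(N*K) lattice-path dynamic program: cells (n, k) whose
#' hypergeometric tail is <= the observed statistic are "significant"; paths
#' from (0,0) to (N,K) that avoid all significant cells are counted and the
#' p-value is one minus their probability mass. `bound` returns the simple
#' union bound `min(1, N * mhg)`.
#'
#' @param mhg Observed statistic in (0, 1].
#' @param N Ranking length.
#' @param K Number of ones.
#' @param method `"exact_dp"` (default) or `"bound"`.
#' @return p-value in (0, 1]; always `>= mhg`.
#' @export
mhg_pvalue <- function(mhg, N, K, method = c("exact_dp", "bound")) {
  method <- match.arg(method)
  N <- as.integer(N); K <- as.integer(K)
  if (K > N) stop("K must not exceed N")
  if (!is.finite(mhg) || mhg <= 0 || mhg > 1) stop("mhg must lie in (0, 1]")
  if (method == "bound") return(min(1, N * mhg))
  if (K == 0L || K == N) return(if (mhg >= 1) 1 else 0)
  thresh <- mhg * (1 + 1e-12)   # guard float noise in tail recomputation
  # w[k + 1] = number of length-n prefixes with k ones avoiding all
  # significant cells so far; rescaled to dodge overflow, exponent tracked.
  w <- c(1, rep(0, K))
  log_scale <- 0
  for (n in seq_len(N)) {
    w <- w + c(0, w[-(K + 1L)])                    # extend by a 0 or a 1
    k_max <- min(n, K)
    k <- 0:k_max
    tails <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    w[1:(k_max + 1L)][tails <= thresh] <- 0
    if (k_max < K) w[(k_max + 2L):(K + 1L)] <- 0   # unreachable
    mx <- max(w)
    if (mx > 1e280) { w <- w / mx; log_scale <- log_scale + log(mx) }
    if (mx == 0) return(1)                         # every path hits a cell
  }
  log_surv <- log(w[K + 1L]) + log_scale - lchoose(N, K)
  max(min(1 - exp(log_surv), 1), mhg)
}

#' MiTEA-style matching of a miRNA to its predicted targets
#'
#' Tests whether the most prominent predicted targets of a miRNA crowd the
#' top of its expression-anti-correlation gene ranking. For each candidate
#' prefix size `B` in `b_grid`, the top-`B` genes of the target ranking
#' `c_nu` are marked inside the anti-correlation ranking `g_mu`, the mHG
#' statistic and its exact p-value are computed, and the minimizing `B*` is
#' reported. The final p-value is Bonferroni-corrected for the scan over
#' `b_grid` (configurable); a matching is declared when it is at most
#' `alpha`.
#'
#' @param g_mu data.frame from [build_g_mu()] (or any data.frame with a
#'   `gene_id` column in ranked order).
#' @param c_nu Character vector of gene ids ranked by target affinity, best
#'   first (or a data.frame with a `gene_id` column).
#' @param b_grid Integer prefix sizes to scan. Default: the geometric grid
#'   `c(10, 20, 50, 100, 200, 500, 1000)` intersected with `1..length(c_nu)`
#'   (after restriction to the shared gene universe).
#' @param alpha Matching threshold on the corrected p-value. Default 0.001.
#' @param correction `"bonferroni"` (default) over the `B` scan, or
#'   `"none"`.
#' @return List with `p_value` (corrected, clipped at 1), `b_star`,
#'   `n_star`, `mhg`, `matched` (`p_value <= alpha`) and `per_b`
#'   (data.frame of the full scan).
#' @export
mitea_match <- function(g_mu, c_nu, b_grid = NULL, alpha = 0.001,
                        correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  genes <- if (is.data.frame(g_mu)) g_mu$gene_id else as.character(g_mu)
  cand <- if (is.data.frame(c_nu)) c_nu$gene_id else as.character(c_nu)
  universe <- intersect(genes, cand)
  if (!length(universe)) stop("empty intersection of gene universes")
  genes <- genes[genes %in% universe]  # both rankings restricted, order kept
  cand <- cand[cand %in% universe]
  if (is.null(b_grid))
    b_grid <- intersect(c(10L, 20L, 50L, 100L, 200L, 500L, 1000L),
                        seq_along(cand))
  b_grid <- sort(unique(as.integer(b_grid)))
  if (!length(b_grid) || any(b_grid < 1L | b_grid > length(cand)))
    stop("b_grid must be a non-empty subset of 1..", length(cand))
  n_genes <- length(genes)
  scan <- lapply(b_grid, function(B) {
    marked <- genes %in% cand[seq_len(B)]
    st <- mhg_statistic(marked)
    p <- mhg_pvalue(st$mhg, n_genes, sum(marked))
    data.frame(B = B, mhg = st$mhg, n_star = st$n_star, p_value = p)
  })
  scan <- do.call(rbind, scan)
  best <- which.min(scan$p_value)
  mult <- if (correction == "bonferroni") nrow(scan) else 1L
  p <- min(1, scan$p_value[best] * mult)
  list(p_value = p, b_star = scan$B[best], n_star = scan$n_star[best],
       mhg = scan$mhg[best], matched = p <= alpha, per_b = scan)
}

#' Read a ranked target-candidate table
#'
#' Three-column TSV `mirna_id`, `gene_id`, `score` with a header; the header
#' of the score column may carry the suffix `":asc"` (smaller score = better
#' candidate, the default) or `":desc"`.
#'
#' @param path Path to the targets TSV.
#' @return Named list: per miRNA, a character vector of gene ids ranked best
#'   candidate first.
#' @export
read_target_ranking <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           check.names = FALSE)
  if (ncol(tab) != 3L)
    stop("targets TSV must have columns mirna_id, gene_id, score")
  desc <- grepl(":desc$", colnames(tab)[3L])
  tab[[3L]] <- as.numeric(tab[[3L]])
  lapply(split(tab, tab[[1L]]), function(d)
    d[[2L]][order(if (desc) -d[[3L]] else d[[3L]], d[[2L]])])
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two sets of correlation values (e.g. target vs background
#' Spearman correlations before and after normalization) by the two-sample
#' KS statistic `D = sup |ECDF_a - ECDF_b|` with its asymptotic p-value.
#'
#' @param sample_a,sample_b Numeric vectors, each non-empty.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  ht <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}
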