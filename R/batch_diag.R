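#' Pairwise Euclidean distances between samples
#'
#' Distances on log2 intensities over a common feature set. The default
#' `common_rows` policy keeps only features with no missing value in any
#' sample (the shared-miRNA subset a joint multi-platform matrix supports);
#' `pairwise_complete` uses, per sample pair, whatever features both
#' measured, rescaled to the full feature count.
#'
#' @param x Numeric matrix, features x samples.
#' @param feature_policy `"common_rows"` (default) or `"pairwise_complete"`.
#' @return Symmetric numeric matrix with zero diagonal and sample dimnames.
#' @export
pairwise_distances <- function(x,
                               feature_policy = c("common_rows",
                                                  "pairwise_complete")) {
  feature_policy <- match.arg(feature_policy)
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (feature_policy == "common_rows") {
    keep <- rowSums(is.na(x)) == 0L
    if (!any(keep))
      stop("no feature is non-missing in every sample; try ",
           "feature_policy = \"pairwise_complete\"")
    d <- as.matrix(stats::dist(t(x[keep, , drop = FALSE])))
  } else {
    n <- ncol(x)
    d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      ok <- !is.na(x[, a]) & !is.na(x[, b])
      if (!any(ok))
        stop("samples '", colnames(x)[a], "' and '", colnames(x)[b],
             "' share no measured feature")
      d[a, b] <- d[b, a] <-
        sqrt(sum((x[ok, a] - x[ok, b])^2) * nrow(x) / sum(ok))
    }
  }
  d
}

#' Silhouette coefficients by batch
#'
#' Classic silhouette `s = (b - a) / max(a, b)` per sample, where `a` is the
#' mean distance to the sample's own batch (excluding itself) and `b` the
#' smallest mean distance to any other batch; members of singleton batches
#' get `s = 0`. High values mean samples cluster by batch — the batch-effect
#' signal this diagnostic quantifies before/after normalization. Computed
#' with [cluster::silhouette()].
#'
#' @param distances Symmetric distance matrix (e.g. from
#'   [pairwise_distances()]).
#' @param batch Character or factor vector of batch labels, one per sample,
#'   at least two distinct values.
#' @return Named numeric vector of silhouette coefficients in `[-1, 1]`.
#' @export
batch_silhouette <- function(distances, batch) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  if (length(batch) != nrow(distances))
    stop("one batch label per sample required")
  batch <- as.factor(batch)
  if (nlevels(droplevels(batch)) < 2L)
    stop("silhouette needs at least two batches")
  sil <- cluster::silhouette(as.integer(droplevels(batch)),
                             dmatrix = distances)
  stats::setNames(sil[, "sil_width"], rownames(distances))
}

#' Hierarchical clustering with batch-purity flags
#'
#' Agglomerative clustering of samples (deterministic: samples are ordered
#' lexicographically by id before linking, so distance ties break by id
#' order) plus, per internal node, whether all leaves below it share one
#' batch — the information needed to colour dendrogram edges by dataset.
#'
#' @param distances Symmetric distance matrix with sample dimnames.
#' @param batch Batch label per sample (same order as `distances`).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return List with `tree` (an [stats::hclust] object), `node_batch`
#'   (character vector, one per merge: the common batch or `NA` if mixed)
#'   and `single_batch` (logical per merge).
#' @export
hclust_batches <- function(distances, batch,
                           linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(distances), nrow(distances) >= 2L)
  ids <- rownames(distances)
  names(batch) <- ids
  ord <- order(ids)
  d <- stats::as.dist(distances[ord, ord])
  tree <- stats::hclust(d, method = linkage)
  batch <- batch[tree$labels]
  merges <- nrow(tree$merge)
  node_batch <- character(merges)
  for (k in seq_len(merges)) {
    part <- lapply(tree$merge[k, ], function(m)
      if (m < 0) unname(batch[-m]) else
        node_batch[m])
    b <- unique(unlist(part))
    node_batch[k] <- if (length(b) == 1L && !is.na(b[1L])) b else NA_character_
  }
  list(tree = tree, node_batch = node_batch,
       single_batch = !is.na(node_batch))
}

#' Cross-cohort rank reproducibility
#'
#' For every feature present in all batches, takes per batch the median over
#' that batch's samples of the feature's intra-sample percentile (and of its
#' log2 expression), then reports the Spearman correlation of these medians
#' for every batch pair — the scatterplot-matrix summary of how well cohorts
#' agree on feature ordering despite platform distortions.
#'
#' @param x Joint numeric matrix, features x samples.
#' @param mask Logical missing-from-platform matrix (same shape); `NULL`
#'   defaults to `is.na(x)`.
#' @param samples data.frame with `sample_id`, `batch`.
#' @return data.frame with one row per unordered batch pair: `batch_a`,
#'   `batch_b`, `spearman_percentile`, `spearman_expression`, `n_features`.
#' @export
cross_dataset_reproducibility <- function(x, mask = NULL, samples) {
  stopifnot(is.matrix(x))
  if (is.null(mask)) mask <- is.na(x)
  batch <- samples$batch[match(colnames(x), samples$sample_id)]
  batches <- unique(batch)
  if (length(batches) < 2L) stop("need at least two batches")
  covered <- vapply(batches, function(b)
    rowSums(mask[, batch == b, drop = FALSE]) == 0L,
    logical(nrow(x)))
  shared <- rowSums(covered) == length(batches)
  if (sum(shared) < 2L)
    stop("fewer than two features shared by all batches")
  xs <- x[shared, , drop = FALSE]
  pct <- apply(xs, 2L, function(v) {
    ok <- !is.na(v)
    p <- rep(NA_real_, length(v))
    p[ok] <- 100 * (rank(v[ok]) - 0.5) / sum(ok)
    p
  })
  med_by_batch <- function(m) vapply(batches, function(b)
    apply(m[, batch == b, drop = FALSE], 1L, stats::median, na.rm = TRUE),
    numeric(nrow(m)))
  mp <- med_by_batch(pct)
  mx <- med_by_batch(xs)
  pairs <- utils::combn(seq_along(batches), 2L)
  out <- data.frame(
    batch_a = batches[pairs[1L, ]],
    batch_b = batches[pairs[2L, ]],
    spearman_percentile = apply(pairs, 2L, function(ij)
      stats::cor(mp[, ij[1L]], mp[, ij[2L]], method = "spearman",
                 use = "pairwise.complete.obs")),
    spearman_expression = apply(pairs, 2L, function(ij)
      stats::cor(mx[, ij[1L]], mx[, ij[2L]], method = "spearman",
                 use = "pairwise.complete.obs")),
    n_features = sum(shared),
    stringsAsFactors = FALSE)
  out
}

#' Rank-distribution polygon for one feature
#'
#' Sorts a feature's values in descending order and walks a lattice path
#' from (0, 0): one step up per positive-group sample, one step right per
#' negative-group sample (ties keep their input order). The path's deviation
#' from the diagonal summarizes how unevenly the two groups distribute over
#' the ranking: the returned statistic is `U / (n_pos * n_neg) - 0.5`, where
#' `U` counts (positive, negative) pairs with the positive value strictly
#' larger (ties count one half) — i.e. AUC minus one half, in `[-0.5, 0.5]`,
#' `+0.5` for perfect separation with positives on top.
#'
#' @param values Numeric vector of one feature's expression; `NA` dropped.
#' @param labels Logical (or two-level) vector: `TRUE` / first level =
#'   positive group (counted on the y axis).
#' @return List with `path` (matrix of x, y lattice coordinates, first row
#'   (0,0)) and `deviation`.
#' @export
rank_polygon <- function(values, labels) {
  if (is.logical(labels)) pos <- labels
  else {
    lev <- unique(as.character(labels))
    if (length(lev) != 2L) stop("labels must have exactly two levels")
    pos <- as.character(labels) == lev[1L]
  }
  ok <- !is.na(values)
  values <- values[ok]; pos <- pos[ok]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both groups must be non-empty")
  ord <- order(-values)           # descending, stable in input order on ties
  steps <- pos[ord]
  path <- cbind(x = c(0, cumsum(!steps)), y = c(0, cumsum(steps)))
  r <- rank(values)               # midranks for the tie-aware U count
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  list(path = path, deviation = u / (n_pos * n_neg) - 0.5)
}
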