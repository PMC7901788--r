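#' Run the merge / normalize / test / diagnose pipeline
#'
#' Reads per-cohort expression TSVs, joins them on feature id with a
#' coverage mask, normalizes (AQuN by default), runs the two-group
#' differential-expression contrast, computes batch diagnostics, and writes
#' every intermediate plus a JSON provenance record to `out_dir`. All
#' randomness (jitter, permutations) derives from `seed`.
#'
#' @param cohort_paths Named character vector of expression TSV paths; names
#'   are batch ids.
#' @param meta_path Metadata TSV (`sample_id`, `batch`, label columns).
#'   Sample ids may be given bare or batch-prefixed (`"<batch>:<id>"`).
#' @param out_dir Output directory (created if needed).
#' @param label,level1,level2 Contrast specification for [de_table()].
#' @param method Normalization: `"aqun"`, `"quantile"`, `"mean-ratio"`,
#'   `"median-subtract"` or `"none"`.
#' @param grid_size,jitter_scale AQuN parameters; see [aqun_normalize()].
#' @param n_perms Label permutations for the null overlay (0 = none).
#' @param seed Integer seed.
#' @return Invisibly, a list with the joint object, normalized matrix, DE
#'   table and diagnostics; files `joint.tsv`, `mask.tsv`, `normalized.tsv`,
#'   `de.tsv`, `silhouette.tsv`, `reproducibility.tsv`, `provenance.json`
#'   (and `permutation_q.tsv` when `n_perms > 0`) under `out_dir`.
#' @export
run_pipeline <- function(cohort_paths, meta_path, out_dir,
                         label, level1, level2,
                         method = c("aqun", "quantile", "mean-ratio",
                                    "median-subtract", "none"),
                         grid_size = 101L, jitter_scale = NULL,
                         n_perms = 0L, seed = 17L) {
  method <- match.arg(method)
  if (!file.exists(meta_path))
    stop("metadata file not found: ", meta_path)
  missing_in <- cohort_paths[!file.exists(cohort_paths)]
  if (length(missing_in))
    stop("cohort file(s) not found: ", paste(missing_in, collapse = ", "))
  if (is.null(names(cohort_paths)) || any(!nzchar(names(cohort_paths))))
    stop("cohort_paths must be named by batch id")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohorts <- lapply(cohort_paths, read_expression_matrix)
  joint <- merge_cohorts(cohorts)
  meta <- read_sample_metadata(meta_path)
  # tolerate bare sample ids when merging had to batch-prefix them
  if (!all(joint$samples$sample_id %in% meta$sample_id)) {
    pref <- paste0(meta$batch, ":", meta$sample_id)
    if (all(joint$samples$sample_id %in% pref)) meta$sample_id <- pref
    else stop("metadata does not cover joint samples: missing ",
              paste(utils::head(setdiff(joint$samples$sample_id,
                                        meta$sample_id), 5L),
                    collapse = ", "))
  }
  samples <- merge(joint$samples, meta[, setdiff(colnames(meta), "batch")],
                   by = "sample_id", sort = FALSE)

  norm <- switch(method,
    "aqun" = aqun_normalize(joint$values, joint$mask, grid_size = grid_size,
                            jitter_scale = jitter_scale, seed = seed),
    "quantile" = normalize_quantile(joint$values),
    "mean-ratio" = normalize_mean_ratio(joint$values),
    "median-subtract" = normalize_median_subtract(joint$values),
    "none" = joint$values)

  de <- de_table(norm, samples, label, level1, level2)
  dists <- pairwise_distances(norm)
  sil <- batch_silhouette(dists, samples$batch[match(colnames(norm),
                                                     samples$sample_id)])
  repro <- cross_dataset_reproducibility(norm, joint$mask, samples)

  write_expression_matrix(joint$values, file.path(out_dir, "joint.tsv"))
  write_expression_matrix((joint$mask) * 1, file.path(out_dir, "mask.tsv"))
  write_expression_matrix(norm, file.path(out_dir, "normalized.tsv"))
  utils::write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sil), silhouette = sil),
    file.path(out_dir, "silhouette.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(repro, file.path(out_dir, "reproducibility.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  perms <- NULL
  if (n_perms > 0L) {
    perms <- permutation_null(norm, samples, label, level1, level2,
                              n_perms = n_perms, seed = seed + 1L)
    ptab <- do.call(cbind, lapply(perms, function(q) q[rownames(norm)]))
    colnames(ptab) <- sprintf("perm%02d", seq_len(n_perms))
    utils::write.table(
      data.frame(mirna_id = rownames(norm), ptab, check.names = FALSE),
      file.path(out_dir, "permutation_q.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA")
  }
  prov <- list(package = "aqun",
               version = as.character(utils::packageVersion("aqun")),
               r_version = R.version.string,
               method = method, grid_size = grid_size, seed = seed,
               n_perms = n_perms, label = label,
               levels = c(level1, level2),
               cohorts = as.list(cohort_paths),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(joint = joint, samples = samples, normalized = norm,
                 de = de, silhouette = sil, reproducibility = repro,
                 permutations = perms))
}

#' Reproduce the published cohort-study numbers from converted supplements
#'
#' Runs the full downstream battery on the merged breast-cancer cohort
#' tables (raw and AQuN-normalized joint matrices plus clinical labels),
#' provided as TSV conversions of the published supplementary spreadsheets
#' (same layout: feature id column then samples; labels with `sample_id`,
#' `batch`, `ER`). Reports the Table-of-top-miRNAs statistics, the count of
#' miRNAs covered by every cohort, the per-miRNA Q-value improvement count
#' and the silhouette before/after comparison.
#'
#' @param raw_path,normalized_path,labels_path TSV paths.
#' @param label,level1,level2 Contrast; defaults `ER`,
#'   `positive`, `negative`.
#' @return List with `de_raw`, `de_norm`, `comparison`, `n_common`,
#'   `n_improved`, `n_strong` (miRNAs at Q <= 1e-18 after normalization),
#'   `silhouette_lower` (samples with lower batch silhouette after
#'   normalization) and `n_samples`.
#' @export
reproduce_cohort_study <- function(raw_path, normalized_path, labels_path,
                                   label = "ER", level1 = "positive",
                                   level2 = "negative") {
  raw <- read_expression_matrix(raw_path)
  norm <- read_expression_matrix(normalized_path)
  meta <- read_sample_metadata(labels_path)
  batch <- meta$batch[match(colnames(raw), meta$sample_id)]
  covered <- !is.na(raw)
  per_batch <- vapply(unique(batch), function(b)
    rowSums(covered[, batch == b, drop = FALSE]) > 0L, logical(nrow(raw)))
  n_common <- sum(rowSums(per_batch) == ncol(per_batch))
  de_raw <- de_table(raw, meta, label, level1, level2)
  de_norm <- de_table(norm, meta, label, level1, level2)
  comparison <- compare_runs(de_norm, de_raw)
  sil_raw <- batch_silhouette(pairwise_distances(raw), batch)
  sil_norm <- batch_silhouette(pairwise_distances(norm), batch)
  list(de_raw = de_raw, de_norm = de_norm, comparison = comparison,
       n_common = n_common,
       n_improved = attr(comparison, "n_lower_a"),
       n_strong = sum(de_norm$q_value <= 1e-18),
       silhouette_lower = sum(sil_norm < sil_raw),
       n_samples = ncol(raw))
}
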