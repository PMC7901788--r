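#' Read an expression matrix from TSV
#'
#' Reads a tab-separated table whose header row holds sample ids and whose
#' first column holds miRNA (or gene) identifiers, into a numeric matrix with
#' feature rownames and sample colnames. Cells equal to `missing_token` become
#' `NA`. Missing is distinct from 0: a 0 means the feature was probed but not
#' detected, `NA` means it was never measured.
#'
#' @param path Path to a TSV file (UTF-8, header `id\\t<sample1>\\t...`).
#' @param missing_token String marking a missing cell. Default `"NA"`.
#' @return Numeric matrix, log2 intensity units, `NA` for missing entries.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("expression TSV needs an id column plus at least one sample column: ",
         path)
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in ", path, ": ",
         paste(dup, collapse = ", "))
  cn <- colnames(tab)[-1L]
  dupc <- unique(cn[duplicated(cn)])
  if (length(dupc))
    stop("duplicate sample ids in ", path, ": ", paste(dupc, collapse = ", "))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(
    matrix(as.numeric(cells), nrow = nrow(cells), ncol = ncol(cells)))
  vals[cells == missing_token] <- NA_real_
  bad <- which(is.na(vals) & cells != missing_token, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at row '", ids[bad[1L, 1L]], "', sample '",
         cn[bad[1L, 2L]], "' in ", path, ": \"",
         cells[bad[1L, 1L], bad[1L, 2L]], "\"")
  dimnames(vals) <- list(ids, cn)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: a read/write/read round trip is
#' value-identical, including missing cells.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param missing_token String written for `NA` cells.
#' @export
write_expression_matrix <- function(x, path, missing_token = "NA") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  out <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = missing_token,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata TSV with columns `sample_id`, `batch`, then any number of
#' clinical-label columns (e.g. `ER` with values `positive`/`negative`/
#' `unknown`). Values are case-sensitive.
#'
#' @param path Path to the metadata TSV.
#' @return data.frame with character columns.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            quote = "", comment.char = "")
  need <- c("sample_id", "batch")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata TSV lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (any(!nzchar(meta$batch))) stop("empty batch id in metadata")
  meta
}

#' Read a two-column alias table (old_id, new_id), no header.
#'
#' @param path Path to the alias TSV.
#' @return Named character vector: `names` are old ids, values new ids.
#' @export
read_alias_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2L) stop("alias TSV must have exactly two columns")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Collapse replicate probe rows to one row per miRNA
#'
#' Probes mapping to the same miRNA id are replaced by their per-sample
#' median; missing values are excluded, and an all-missing set of probes
#' yields a missing cell. Probes absent from `groups` keep their own id.
#' The operation is idempotent.
#'
#' @param x Numeric matrix, probes in rows.
#' @param groups Named character vector mapping probe id to miRNA id.
#' @return Matrix with one row per (mapped) id, rows ordered by first
#'   appearance.
#' @export
collapse_replicates <- function(x, groups) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (length(groups) == 0L) stop("empty probe-to-miRNA mapping")
  if (is.null(names(groups)) || any(!nzchar(groups)))
    stop("groups must be a named map with non-empty target ids")
  ids <- rownames(x)
  target <- ifelse(ids %in% names(groups), groups[ids], ids)
  keep <- unique(target)
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(x),
                dimnames = list(keep, colnames(x)))
  for (id in keep) {
    rows <- x[target == id, , drop = FALSE]
    if (nrow(rows) == 1L) {
      out[id, ] <- rows[1L, ]
    } else {
      out[id, ] <- apply(rows, 2L, function(v)
        if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    }
  }
  out
}

#' Subtract the dataset-wide minimum
#'
#' Shifts all non-missing values so the smallest becomes 0, avoiding negative
#' log-scale values downstream. Applied per dataset (the whole matrix), prior
#' to joining cohorts; set `per_sample = TRUE` to shift each sample
#' independently instead.
#'
#' @param x Numeric matrix with at least one non-missing value.
#' @param per_sample Shift each column by its own minimum instead.
#' @return Shifted matrix; missing cells preserved.
#' @export
min_subtract <- function(x, per_sample = FALSE) {
  stopifnot(is.matrix(x))
  if (all(is.na(x))) stop("min_subtract: matrix has no non-missing values")
  if (per_sample) {
    mins <- apply(x, 2L, function(v) {
      if (all(is.na(v))) stop("min_subtract: all-missing sample")
      min(v, na.rm = TRUE)
    })
    sweep(x, 2L, mins, "-")
  } else {
    x - min(x, na.rm = TRUE)
  }
}

#' Merge cohorts by full outer join on feature ids
#'
#' Builds the joint miRNA-by-sample matrix over the union of feature ids,
#' together with the platform-coverage mask and a per-sample batch
#' annotation. A cell is masked `TRUE` exactly when its miRNA is absent from
#' the row set of the cohort its sample came from (missing-from-platform);
#' such cells are missing in the joint matrix. Values present in a cohort are
#' copied verbatim. Sample-id collisions across cohorts are resolved by
#' prefixing with `"<batch_id>:"`.
#'
#' @param cohorts Named list (names are batch ids) of numeric matrices with
#'   feature rownames and sample colnames. At least two cohorts.
#' @return A list of class `"joint_cohort"` with elements `values` (joint
#'   matrix, union of rows), `mask` (logical, `TRUE` = missing from
#'   platform) and `samples` (data.frame `sample_id`, `batch`).
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2L)
    stop("merge_cohorts needs a named list of at least two cohorts")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stop("every cohort needs a non-empty batch id name")
  for (b in names(cohorts)) {
    m <- cohorts[[b]]
    if (!is.matrix(m) || nrow(m) == 0L || ncol(m) == 0L)
      stop("cohort '", b, "' is empty")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("cohort '", b, "' lacks feature or sample ids")
  }
  all_samples <- unlist(lapply(cohorts, colnames), use.names = FALSE)
  clash <- anyDuplicated(all_samples) > 0L
  rows <- unique(unlist(lapply(cohorts, rownames), use.names = FALSE))
  cols <- character(0)
  batch <- character(0)
  for (b in names(cohorts)) {
    cn <- colnames(cohorts[[b]])
    if (clash) cn <- paste0(b, ":", cn)
    cols <- c(cols, cn)
    batch <- c(batch, rep(b, length(cn)))
  }
  if (anyDuplicated(cols))
    stop("sample ids still collide after batch prefixing: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  values <- matrix(NA_real_, length(rows), length(cols),
                   dimnames = list(rows, cols))
  mask <- matrix(TRUE, length(rows), length(cols),
                 dimnames = list(rows, cols))
  at <- 0L
  for (b in names(cohorts)) {
    m <- cohorts[[b]]
    j <- at + seq_len(ncol(m))
    values[rownames(m), j] <- m
    mask[rownames(m), j] <- FALSE
    at <- at + ncol(m)
  }
  structure(
    list(values = values, mask = mask,
         samples = data.frame(sample_id = cols, batch = batch,
                              stringsAsFactors = FALSE)),
    class = "joint_cohort")
}

#' @export
print.joint_cohort <- function(x, ...) {
  cat("joint_cohort: ", nrow(x$values), " features x ", ncol(x$values),
      " samples, ", length(unique(x$samples$batch)), " batches; ",
      sum(rowSums(x$mask) == 0L), " features covered by every batch\n",
      sep = "")
  invisible(x)
}

#' Rename rows via an alias table
#'
#' Applies an old-id to new-id map to the row names; rows that end up sharing
#' an id are collapsed by per-sample median (the [collapse_replicates()]
#' contract). Unmapped ids are kept as-is or dropped.
#'
#' @param x Numeric matrix with rownames.
#' @param alias Named character vector, old id -> new id.
#' @param unmapped `"keep"` (default) or `"drop"` rows whose id has no alias.
#' @return Renamed (and possibly collapsed) matrix.
#' @export
apply_alias_map <- function(x, alias, unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  if (length(alias) == 0L) stop("empty alias table")
  if (any(!nzchar(alias))) stop("alias targets must be non-empty")
  if (unmapped == "drop") {
    x <- x[rownames(x) %in% names(alias), , drop = FALSE]
    if (nrow(x) == 0L) stop("no rows left after dropping unmapped ids")
  }
  collapse_replicates(x, alias)
}
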