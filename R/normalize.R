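#' Adjusted quantile normalization (AQuN)
#'
#' Normalizes a joint multi-cohort expression matrix by pooling per-sample
#' percentile bins across the whole matrix. Each non-missing value is
#' (1) jittered to break rank ties, (2) assigned the grid percentile nearest
#' to `100 * (r - 0.5) / n_j`, where `r` is its 1-based rank among the
#' sample's `n_j` non-missing entries, and (3) replaced by the median
#' (default) of all un-jittered values in the matrix sharing that quantized
#' percentile. Cells masked as missing-from-platform stay missing. Unlike
#' vanilla quantile normalization this accepts cohorts with only partially
#' overlapping probe sets: percentiles are computed over whatever each sample
#' did measure.
#'
#' Jitter affects ranking only; pooled aggregates use the original values, so
#' the result is seed-independent whenever the input has no ties within a
#' sample. Set `aggregate_jittered = TRUE` to pool the jittered values
#' instead. The output holds at most `grid_size` distinct non-missing values.
#'
#' @param x Numeric matrix (features x samples), log2 intensities, `NA` for
#'   missing. Zeros are ordinary values (probed, not detected) and take part
#'   in percentile computation.
#' @param mask Logical matrix, same shape, `TRUE` where the feature is
#'   missing from the sample's platform. Every masked cell must be `NA` in
#'   `x`. Default: `is.na(x)`.
#' @param grid_size Number of percentile grid points on the uniform 0..100
#'   grid; default 101 (integer percents).
#' @param jitter_scale Standard deviation of the tie-breaking Gaussian
#'   jitter, in data units. Default `1e-9` times the non-missing value range.
#'   `0` switches to deterministic first-occurrence tie-breaking.
#' @param seed Optional integer seed for the jitter; the caller's RNG state
#'   is left untouched.
#' @param aggregate `"median"` (default) or `"mean"` pooling within a bin.
#' @param aggregate_jittered Pool jittered rather than original values,
#'   matching the literal one-pass formulation.
#' @return Normalized matrix, same dimnames; attribute `"aqun_seed"` records
#'   the seed used.
#' @seealso [normalize_quantile()] for the vanilla method on complete
#'   matrices.
#' @export
aqun_normalize <- function(x, mask = NULL, grid_size = 101L,
                           jitter_scale = NULL, seed = NULL,
                           aggregate = c("median", "mean"),
                           aggregate_jittered = FALSE) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(x))
  if (is.null(mask)) mask <- is.na(x)
  if (!is.logical(mask) || !identical(dim(mask), dim(x)))
    stop("mask must be a logical matrix with the shape of x")
  if (any(mask & !is.na(x)))
    stop("masked cells must be missing in x")
  if (any(!is.finite(x[!is.na(x)])))
    stop("non-finite values in input")
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("grid_size must be at least 2")
  n_per_sample <- colSums(!is.na(x))
  if (any(n_per_sample == 0L))
    stop("sample(s) with no non-missing values: ",
         paste(colnames(x)[n_per_sample == 0L], collapse = ", "))

  rng <- range(x, na.rm = TRUE)
  if (is.null(jitter_scale)) jitter_scale <- 1e-9 * max(rng[2L] - rng[1L], 1)
  if (jitter_scale < 0) stop("jitter_scale must be non-negative")

  d <- x
  if (jitter_scale > 0) {
    noise <- local_rng(seed, stats::rnorm(length(x), 0, jitter_scale))
    d <- x + matrix(noise, nrow(x), ncol(x))
  }

  # quantized percentile bin per cell (0 .. grid_size - 1)
  bin <- matrix(NA_integer_, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(d[, j])
    r <- rank(d[ok, j], ties.method = "first")
    bin[ok, j] <- as.integer(round((grid_size - 1) * (r - 0.5) / sum(ok)))
  }

  pool_src <- if (aggregate_jittered) d else x
  agg_fun <- if (aggregate == "median") stats::median else mean
  present <- !is.na(bin)
  pooled <- tapply(pool_src[present], bin[present], agg_fun)

  out <- x
  out[present] <- pooled[as.character(bin[present])]
  out[mask] <- NA_real_
  attr(out, "aqun_seed") <- seed
  out
}

#' Vanilla quantile normalization
#'
#' Standard quantile normalization of a complete matrix: rank-r values in
#' every column are replaced by the cross-column mean of rank-r values, with
#' ties sharing the mean of their rank values. Thin wrapper over
#' [limma::normalizeQuantiles()].
#'
#' @param x Complete numeric matrix (no missing values).
#' @return Normalized matrix with identical per-column distributions.
#' @export
normalize_quantile <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x))
    stop("matrix contains missing values; use aqun_normalize() for ",
         "partially covered multi-platform data")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Mean-ratio normalization
#'
#' Scales each sample by its mean: every cell is divided by the mean of its
#' sample's non-missing values.
#'
#' @param x Numeric matrix; `NA` allowed.
#' @return Scaled matrix; missing cells preserved.
#' @export
normalize_mean_ratio <- function(x) {
  stopifnot(is.matrix(x))
  mu <- colMeans(x, na.rm = TRUE)
  bad <- !is.finite(mu) | mu == 0
  if (any(bad))
    stop("zero or undefined sample mean for: ",
         paste(colnames(x)[bad], collapse = ", "))
  sweep(x, 2L, mu, "/")
}

#' Median-subtraction normalization
#'
#' Subtracts each sample's median, then shifts each sample additively so its
#' minimum equals the global minimum of the median-subtracted matrix.
#'
#' @param x Numeric matrix; each sample needs at least one non-missing value.
#' @return Normalized matrix; missing cells preserved.
#' @export
normalize_median_subtract <- function(x) {
  stopifnot(is.matrix(x))
  n_ok <- colSums(!is.na(x))
  if (any(n_ok == 0L))
    stop("all-missing sample(s): ", paste(colnames(x)[n_ok == 0L],
                                          collapse = ", "))
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  y <- sweep(x, 2L, med, "-")
  gmin <- min(y, na.rm = TRUE)
  mins <- apply(y, 2L, min, na.rm = TRUE)
  sweep(y, 2L, mins - gmin, "-")
}

# Run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's state afterwards.
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
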