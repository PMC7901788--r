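make_mat <- function(..., rows = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- if (is.null(rows)) sprintf("m%d", seq_len(nrow(m))) else rows
  m
}

test_that("aqun reproduces hand-evaluated percentile pooling", {
  # one sample: every bin pools a singleton -> identity
  one <- make_mat(A = c(1, 2, 3))
  expect_equal(unname(aqun_normalize(one, seed = 1)), unname(one),
               ignore_attr = TRUE)
  # two samples, n = 2 each, percentiles {25, 75}
  two <- make_mat(A = c(0, 10), B = c(2, 8))
  out <- aqun_normalize(two, seed = 1)
  expect_equal(unname(out), cbind(c(1, 9), c(1, 9)), ignore_attr = TRUE)
  # median vs mean pooling on three samples (bin 25 = {0,1,5})
  three <- make_mat(A = c(0, 10), B = c(1, 8), C = c(5, 9))
  med <- aqun_normalize(three, seed = 1)
  avg <- aqun_normalize(three, seed = 1, aggregate = "mean")
  expect_equal(unname(med[1, ]), rep(1, 3), ignore_attr = TRUE)
  expect_equal(unname(avg[1, ]), rep(2, 3), ignore_attr = TRUE)
  expect_equal(unname(med[2, ]), rep(9, 3), ignore_attr = TRUE)
})

test_that("aqun preserves the coverage mask and rejects bad input", {
  m <- make_mat(A = c(1, 2, NA), B = c(4, 5, 6))
  mask <- is.na(m)
  out <- aqun_normalize(m, mask, seed = 1)
  expect_identical(is.na(out), mask)
  # masked cell must be missing in x
  bad_mask <- mask; bad_mask[1, 1] <- TRUE
  expect_error(aqun_normalize(m, bad_mask), "masked")
  # all-missing sample named in the error
  m2 <- make_mat(A = c(1, 2), B = c(NA, NA))
  expect_error(aqun_normalize(m2), "B")
  m3 <- make_mat(A = c(1, Inf))
  expect_error(aqun_normalize(m3), "finite")
})

test_that("aqun output obeys distribution equality and cardinality bounds", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(60 * 8, 8, 2), 60, 8,
                dimnames = list(sprintf("m%d", 1:60), sprintf("s%d", 1:8)))
    # equal coverage: knock out the same 10 rows in every sample
    m[sample(60, 10), ] <- NA
    out <- aqun_normalize(m, grid_size = 21L, seed = rep)
    sorted <- apply(out, 2L, function(v) sort(v[!is.na(v)]))
    for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
    expect_lte(length(unique(as.vector(out[!is.na(out)]))), 21L)
  }
})

test_that("aqun is seed-independent on tie-free data and order-preserving", {
  set.seed(7)
  m <- matrix(sample(seq(1, 300)) + 0.5, 50, 6,
              dimnames = list(sprintf("m%d", 1:50), sprintf("s%d", 1:6)))
  a <- aqun_normalize(m, seed = 1)
  b <- aqun_normalize(m, seed = 999)
  expect_equal(unname(a), unname(b), ignore_attr = TRUE)
  # within-sample monotonicity: well-separated inputs keep their order
  for (j in seq_len(ncol(m))) {
    ord <- order(m[, j])
    expect_true(all(diff(a[ord, j]) >= 0))
  }
})

test_that("mean-aggregated aqun on complete data matches vanilla quantile", {
  set.seed(11)
  m <- matrix(rnorm(40 * 5, 10, 3), 40, 5,
              dimnames = list(sprintf("m%d", 1:40), sprintf("s%d", 1:5)))
  # grid fine enough that each of the 40 ranks has its own bin
  aq <- aqun_normalize(m, grid_size = 401L, aggregate = "mean", seed = 3)
  vq <- normalize_quantile(m)
  expect_lt(max(abs(aq - vq)), 1e-9)
})

test_that("vanilla quantile normalizes rank-wise and refuses missing data", {
  m <- make_mat(A = c(0, 10), B = c(2, 8))
  expect_equal(unname(normalize_quantile(m)), cbind(c(1, 9), c(1, 9)))
  same <- make_mat(A = c(1, 5, 3), B = c(1, 5, 3))
  expect_equal(normalize_quantile(same), same)
  single <- make_mat(A = c(4, 2, 9))
  expect_equal(normalize_quantile(single), single)
  withna <- make_mat(A = c(1, NA), B = c(2, 3))
  expect_error(normalize_quantile(withna), "[Aa]qu[Nn]")
})

test_that("mean-ratio scales by sample means", {
  m <- make_mat(A = c(1, 2, 3))
  expect_equal(unname(normalize_mean_ratio(m)), cbind(c(0.5, 1, 1.5)))
  const <- make_mat(A = rep(7, 4))
  expect_true(all(normalize_mean_ratio(const) == 1))
  zero <- make_mat(A = c(-1, 1))
  expect_error(normalize_mean_ratio(zero), "A")
})

test_that("median subtraction centers then aligns minima globally", {
  m <- make_mat(A = c(1, 2, 3), B = c(4, 6, 8))
  out <- normalize_median_subtract(m)
  expect_equal(unname(out), cbind(c(-2, -1, 0), c(-2, 0, 2)))
  # single sample: centered, second step is a no-op
  single <- make_mat(A = c(1, 2, 3))
  expect_equal(unname(normalize_median_subtract(single)),
               cbind(c(-1, 0, 1)))
  # identical samples stay identical
  same <- make_mat(A = c(5, 1, 3), B = c(5, 1, 3))
  out2 <- normalize_median_subtract(same)
  expect_equal(out2[, 1], out2[, 2])
})
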