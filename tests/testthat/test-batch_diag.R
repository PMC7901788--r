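test_that("pairwise distances are Euclidean on complete rows", {
  m <- matrix(c(0, 0, 3, 4, 0, 0), 2, 3,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  d <- pairwise_distances(m)
  expect_equal(d["s1", "s2"], 5)           # 3-4-5 triangle
  expect_equal(d["s1", "s3"], 0)           # identical samples
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), colnames(m)))
  # invariance to row order
  expect_equal(pairwise_distances(m[c(2, 1), ]), d)
  # rows with any missing value are excluded under common_rows
  m2 <- rbind(m, f3 = c(100, NA, 0))
  expect_equal(pairwise_distances(m2), d)
  allna <- matrix(c(NA, 1, 2, NA), 2, 2,
                  dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(pairwise_distances(allna), "no feature")
})

test_that("silhouette matches the O(n^2) reference and conventions", {
  pts <- c(0, 0.2, 10, 10.2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:4), sprintf("s%d", 1:4))
  s <- batch_silhouette(d, c("a", "a", "b", "b"))
  expect_equal(unname(s[1]), (10.1 - 0.2) / 10.1, tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    dm <- as.matrix(dist(x))
    dimnames(dm) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
    labs <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    s <- batch_silhouette(dm, labs)
    expect_equal(unname(s), ref_silhouette(dm, labs), tolerance = 1e-12)
    expect_true(all(s >= -1 & s <= 1))
  }
  # singleton cluster convention
  d3 <- as.matrix(dist(c(0, 1, 5)))
  dimnames(d3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  s3 <- batch_silhouette(d3, c("a", "a", "b"))
  expect_equal(unname(s3["z"]), 0)
  expect_error(batch_silhouette(d3, c("a", "a", "a")), "two")
})

test_that("random labels on i.i.d. data give near-zero mean silhouette", {
  set.seed(19)
  means <- replicate(20, {
    x <- matrix(rnorm(24 * 10), 24, 10)
    dm <- as.matrix(dist(x))
    dimnames(dm) <- list(sprintf("s%d", 1:24), sprintf("s%d", 1:24))
    mean(batch_silhouette(dm, rep(c("a", "b"), 12)))
  })
  expect_lt(abs(mean(means)), 0.05)
})

test_that("hierarchical clustering is deterministic and batch-flagged", {
  pts <- c(A = 0, B = 1, C = 10)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(names(pts), names(pts))
  h <- hclust_batches(d, c("b1", "b1", "b2"))
  first <- h$tree$merge[1, ]
  expect_setequal(h$tree$labels[-first], c("A", "B"))
  expect_equal(h$node_batch[1], "b1")
  expect_false(h$single_batch[2])          # root mixes b1 and b2
  # two samples: a single merge
  d2 <- d[1:2, 1:2]
  h2 <- hclust_batches(d2, c("b1", "b1"))
  expect_equal(nrow(h2$tree$merge), 1)
  expect_true(h2$single_batch[1])          # monochromatic root
})

test_that("cross-dataset reproducibility detects monotone agreement", {
  set.seed(44)
  base <- matrix(rnorm(30 * 4, 8, 2), 30, 4,
                 dimnames = list(sprintf("m%d", 1:30), sprintf("a%d", 1:4)))
  twin <- base; colnames(twin) <- sprintf("b%d", 1:4)
  mono <- 2 + 3 * base + 0.01 * base^2; colnames(mono) <- sprintf("c%d", 1:4)
  rev_m <- -base; colnames(rev_m) <- sprintf("d%d", 1:4)
  x <- cbind(base, twin, mono, rev_m)
  samples <- data.frame(sample_id = colnames(x),
                        batch = rep(c("A", "B", "C", "D"), each = 4))
  rep_tab <- cross_dataset_reproducibility(x, samples = samples)
  get <- function(a, b) {
    row <- rep_tab[(rep_tab$batch_a == a & rep_tab$batch_b == b) |
                   (rep_tab$batch_a == b & rep_tab$batch_b == a), ]
    row$spearman_percentile
  }
  expect_equal(get("A", "B"), 1)           # identical batches
  expect_equal(get("A", "C"), 1)           # monotone transform
  expect_equal(get("A", "D"), -1)          # reversed ranking
  one_batch <- samples[samples$batch == "A", ]
  expect_error(
    cross_dataset_reproducibility(base, samples = one_batch), "two")
})

test_that("rank polygon walks the lattice and measures AUC deviation", {
  # perfect separation: all positives on top
  sep <- rank_polygon(c(10, 9, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$deviation, 0.5)
  expect_equal(sep$path[1, ], c(x = 0, y = 0))
  expect_equal(sep$path[nrow(sep$path), ], c(x = 2, y = 2))
  # identical tied multisets: no deviation
  tie <- rank_polygon(c(1, 1, 2, 2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tie$deviation, 0)
  # pair-count example: U = 3 of 4
  ex <- rank_polygon(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ex$deviation, 0.25)
  expect_error(rank_polygon(c(1, 2), c(TRUE, TRUE)), "non-empty")
})

test_that("polygon deviation equals a brute-force pair-counting oracle", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    vals <- sample(1:8, n, replace = TRUE)   # ties likely
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labs) || !any(labs)) next
    u <- 0
    for (i in which(labs)) for (j in which(!labs))
      u <- u + (vals[i] > vals[j]) + 0.5 * (vals[i] == vals[j])
    expect_equal(rank_polygon(vals, labs)$deviation,
                 u / (sum(labs) * sum(!labs)) - 0.5)
  }
})
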