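test_that("fold change is the difference of medians and antisymmetric", {
  expect_equal(fold_change(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fold_change(c(2, 4, 6), c(1, 3, 5)), 1)
  set.seed(1)
  for (rep in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
    expect_equal(fold_change(a, b), -fold_change(b, a))
  }
  expect_error(fold_change(numeric(0), 1), "empty")
})

test_that("exact rank-sum path matches brute-force enumeration", {
  expect_equal(wrs_test(c(3, 4), c(1, 2), "greater")$p_value, 1 / 6)
  set.seed(23)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(seq_len(50), n1 + n2)    # tie-free
    g1 <- vals[seq_len(n1)]; g2 <- vals[-seq_len(n1)]
    alt <- sample(c("greater", "less"), 1)
    expect_equal(wrs_test(g1, g2, alt)$p_value,
                 brute_wrs_p(g1, g2, alt), tolerance = 1e-12)
  }
})

test_that("identical groups are never called shifted", {
  res <- wrs_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(res$p_value, 0.5)
})

test_that("normal approximation tracks the exact distribution at n=20/20", {
  set.seed(5)
  for (rep in 1:10) {
    g1 <- rnorm(20, 0.3); g2 <- rnorm(20)
    approx_p <- wrs_test(g1, g2, "greater")$p_value
    exact_p <- stats::wilcox.test(g1, g2, alternative = "greater",
                                  exact = TRUE)$p.value
    expect_equal(approx_p, exact_p, tolerance = 0.02)
  }
})

test_that("auto tail follows the median difference, adjusted by default", {
  up <- wrs_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(up$direction, "up_in_group1")
  dn <- wrs_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(dn$direction, "up_in_group2")
  # auto doubles the one-sided p; explicit tails never adjusted
  raw <- wrs_test(c(5, 6, 7, 8), c(1, 2, 3, 4), "greater")$p_value
  expect_equal(up$p_value, min(1, 2 * raw))
  expect_equal(wrs_test(c(5, 6, 7, 8), c(1, 2, 3, 4),
                        adjust_auto = FALSE)$p_value, raw)
})

test_that("BH adjustment matches an independent step-up reference", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(97)
  for (rep in 1:40) {
    p <- runif(sample(c(1, 5, 25, 100), 1))
    q <- bh_fdr(p)
    expect_equal(q, ref_bh(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("de_table ranks a planted shift first and validates labels", {
  set.seed(31)
  m <- matrix(rnorm(30 * 40), 30, 40,
              dimnames = list(sprintf("m%02d", 1:30), sprintf("s%d", 1:40)))
  m["m05", 1:20] <- m["m05", 1:20] + 3    # d = 3 at n = 20/20
  samples <- data.frame(sample_id = colnames(m),
                        grp = rep(c("hi", "lo"), each = 20))
  de <- de_table(m, samples, "grp", "hi", "lo")
  expect_equal(de$mirna_id[which.min(de$q_value)], "m05")
  expect_equal(de$direction[de$mirna_id == "m05"], "up_in_group1")
  expect_gt(de$fold_change[de$mirna_id == "m05"], 0)
  # one-level label is an error
  allsame <- data.frame(sample_id = colnames(m), grp = "hi")
  expect_error(de_table(m, allsame, "grp", "hi", "lo"), "lo")
  expect_error(de_table(m, samples, "nope", "hi", "lo"), "nope")
})

test_that("de_table skips under-covered miRNAs and BH runs on the rest", {
  set.seed(8)
  m <- matrix(rnorm(4 * 12), 4, 12,
              dimnames = list(c("a", "b", "c", "d"), sprintf("s%d", 1:12)))
  m["c", 1:10] <- NA                      # only 2 values in group hi
  samples <- data.frame(sample_id = colnames(m),
                        grp = rep(c("hi", "lo"), each = 6))
  de <- de_table(m, samples, "grp", "hi", "lo")
  expect_false("c" %in% de$mirna_id)
  expect_equal(attr(de, "skipped")$mirna_id, "c")
  expect_equal(de$q_value, bh_fdr(de$p_value))
})

test_that("permutation null is seeded, sized, and calibrated", {
  expect_identical(
    permutation_null(tiny_matrix(), data.frame(sample_id = c("s1", "s2"),
                                               g = c("a", "b")),
                     "g", "a", "b", n_perms = 0),
    list())
  cfg <- sim_config(n_mirnas = 80L,
                    batches = data.frame(batch_id = c("b1", "b2"),
                                         n_samples = 30L, frac_missing = 0,
                                         a = 0, b = 1, c = 0),
                    de_fraction = 0, seed = 4L)
  sim <- simulate_joint(cfg)
  joint <- merge_cohorts(sim$cohorts)
  norm <- aqun_normalize(joint$values, joint$mask, seed = 4)
  p1 <- permutation_null(norm, sim$samples, "group", "g1", "g2",
                         n_perms = 3, seed = 9)
  p2 <- permutation_null(norm, sim$samples, "group", "g1", "g2",
                         n_perms = 3, seed = 9)
  expect_identical(p1, p2)
  expect_length(p1, 3)
  # null calibration: rejection rate at 0.05 close to nominal
  set.seed(12)
  rates <- replicate(50, {
    perm <- sim$samples
    perm$group <- sample(perm$group)
    de <- de_table(norm, perm, "group", "g1", "g2")
    mean(de$p_value < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.011)
})

test_that("compare_runs joins on shared miRNAs and counts improvements", {
  a <- data.frame(mirna_id = c("x", "y", "z"),
                  fold_change = c(1, -1, 0.5),
                  p_value = c(0.01, 0.2, 0.5),
                  q_value = c(0.03, 0.3, 0.5),
                  direction = "up_in_group1", n1 = 5, n2 = 5)
  self <- compare_runs(a, a)
  expect_equal(attr(self, "n_lower_a"), 0)
  expect_equal(attr(self, "n_lower_b"), 0)
  b <- a
  b$q_value <- c(0.01, 0.4, 0.5)           # better on x, worse on y, tie on z
  ab <- compare_runs(a, b)
  expect_equal(attr(ab, "n_lower_a"), 1)   # y lower in run a
  expect_equal(attr(ab, "n_lower_b"), 1)   # x lower in run b
  c_run <- a; c_run$mirna_id <- c("q", "r", "s")
  expect_error(compare_runs(a, c_run), "share no")
})
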