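test_that("fraction of genome altered follows the stated arithmetic", {
  g <- toy_genome()  # chr1 60 Mb + chr2 40 Mb
  # altered blocks of 5 Mb (chr1) and 15 Mb (chr2) on a 100 Mb genome -> 0.20
  seg <- rbind(
    seg_df("S1", "chr1", 0, 5e6, -1.0),
    seg_df("S1", "chr1", 5e6, 60e6, 0.01),
    seg_df("S1", "chr2", 0, 15e6, 0.8),
    seg_df("S1", "chr2", 15e6, 40e6, -0.05))
  expect_equal(fraction_genome_altered(seg, g), 0.20)
  # nothing beyond threshold -> 0; whole genome deleted -> 1
  expect_equal(fraction_genome_altered(seg_df("S1", "chr1", 0, 60e6, 0.1), g), 0)
  whole <- rbind(seg_df("S1", "chr1", 0, 60e6, -1),
                 seg_df("S1", "chr2", 0, 40e6, -1))
  expect_equal(fraction_genome_altered(whole, g), 1)
  expect_warning(out <- fraction_genome_altered(empty <- seg_df(character(), character(), numeric(), numeric(), numeric()), g),
                 "empty")
  expect_equal(out, 0)
})

test_that("FGA is invariant to splitting segments and excludes sex chromosomes", {
  g <- genome_def(c("chr1", "chrX"), c(60e6, 40e6))
  one <- seg_df("S1", "chr1", 0, 30e6, -0.5)
  split <- rbind(seg_df("S1", "chr1", 0, 12e6, -0.5),
                 seg_df("S1", "chr1", 12e6, 30e6, -0.5))
  expect_equal(fraction_genome_altered(one, g), fraction_genome_altered(split, g))
  # chrX excluded from numerator and denominator by default
  withX <- rbind(one, seg_df("S1", "chrX", 0, 40e6, -1))
  expect_equal(fraction_genome_altered(withX, g), 0.5)
  expect_equal(fraction_genome_altered(withX, g, include_sex = TRUE), 0.7)
})

test_that("FGA histogram bins are left-closed with open extremes and conserve n", {
  h <- bin_fga(c(0.005, 0.02))
  expect_equal(h$count[1:2], c(1L, 1L))
  expect_equal(h$bin[1], "<0.01")
  # exact 0.5 lands in the >=0.5 bin
  h2 <- bin_fga(0.5)
  expect_equal(h2$count[h2$bin == ">=0.5"], 1L)
  # conservation for arbitrary inputs
  set.seed(30)
  vals <- rbeta(137, 1, 5)
  expect_equal(sum(bin_fga(vals)$count), 137L)
  grp <- sample(c("a", "b"), 137, replace = TRUE)
  hg <- bin_fga(vals, groups = grp)
  expect_equal(colSums(hg[, c("a", "b")]), table(grp)[c("a", "b")],
               ignore_attr = TRUE)
  expect_error(bin_fga(1.2), "\\[0, 1\\]")
  expect_error(bin_fga(0.5, edges = c(0.2, 0.1)), "increasing")
})

test_that("exact rank-sum p equals exhaustive enumeration for all small splits", {
  # tie-free splits cross-checked against the enumeration oracle and wilcox.test
  vals <- c(3.2, 1.1, 4.7, 1.5, 9.3, 2.6, 5.4)
  for (nx in 1:6) {
    idx <- utils::combn(7, nx)
    for (j in seq_len(ncol(idx))) {
      x <- vals[idx[, j]]; y <- vals[-idx[, j]]
      rs <- rank_sum_test(x, y)
      expect_identical(rs$method, "exact")
      expect_equal(rs$p_one, oracle_ranksum_one_sided(x, y))
      w <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
      expect_equal(rs$p_greater, w$p.value, tolerance = 1e-12)
    }
  }
  # tied values still enumerate exactly over midranks
  tied <- c(1, 1, 2, 2, 3, 5)
  for (nx in c(2, 3)) {
    idx <- utils::combn(6, nx)
    for (j in seq_len(ncol(idx))) {
      x <- tied[idx[, j]]; y <- tied[-idx[, j]]
      expect_equal(rank_sum_test(x, y)$p_one, oracle_ranksum_one_sided(x, y))
    }
  }
})

test_that("rank-sum worked examples and symmetries hold", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_one, 1 / 20)
  expect_equal(rank_sum_test(c(200, 210, 220), c(20, 25, 30, 35))$p_one, 1 / 35)
  # identical multisets: two-sided p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_two, 1)
  # swapping the groups leaves the two-sided p unchanged
  set.seed(31)
  x <- rnorm(12); y <- rnorm(15, 1)
  expect_equal(rank_sum_test(x, y)$p_two, rank_sum_test(y, x)$p_two)
})

test_that("normal-approximation branch matches the tie-corrected reference", {
  set.seed(32)
  x <- rnbinom(20, size = 5, mu = 30)
  y <- rnbinom(25, size = 5, mu = 45)
  rs <- rank_sum_test(x, y)
  expect_identical(rs$method, "normal")
  ref <- stats::wilcox.test(x, y, alternative = "greater",
                            exact = FALSE, correct = FALSE)
  expect_equal(rs$p_greater, ref$p.value, tolerance = 1e-12)
})

test_that("one-sided burden comparison is calibrated under the null", {
  set.seed(33)
  p <- replicate(2000, {
    rank_sum_test(rbeta(20, 2, 38), rbeta(20, 2, 38))$p_greater
  })
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("burden comparison detects a shifted FGA distribution", {
  set.seed(34)
  rej <- replicate(500, {
    rank_sum_test(rbeta(20, 5, 15), rbeta(20, 2, 38))$p_greater <= 0.05
  })
  expect_gte(mean(rej), 0.95)
})

test_that("compare_burden reports groups, medians, and histogram", {
  set.seed(35)
  vals <- c(rbeta(15, 2, 38), rbeta(15, 5, 15))
  grp <- rep(c("wt", "mut"), each = 15)
  cmp <- compare_burden(vals, grp)
  expect_equal(cmp$groups, c("mut", "wt"))
  expect_equal(sum(vapply(cmp$histogram[-1], sum, numeric(1))), 30)
  expect_lt(cmp$p_two, 0.05)
  # label swap keeps the two-sided p
  cmp2 <- compare_burden(vals, rev(grp))
  expect_equal(cmp2$p_two, cmp$p_two)
  expect_error(compare_burden(vals, rep("a", 30)), "two levels")
})
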