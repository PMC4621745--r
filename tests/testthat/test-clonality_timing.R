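test_that("multiplicity estimation rounds the copy-weighted VAF with clamps", {
  expect_equal(estimate_multiplicity(0.5, 1, 2L), 1L)
  expect_equal(estimate_multiplicity(0.95, 1, 2L), 2L)
  expect_equal(estimate_multiplicity(0.25, 0.6, 2L), 1L)  # round(0.25 * 2 / 0.6)
  expect_equal(estimate_multiplicity(0.01, 1, 2L), 1L)    # clamped up to 1
  expect_equal(estimate_multiplicity(1, 1, 3L), 3L)
  expect_error(estimate_multiplicity(0.5, 0, 2L), "purity")
})

test_that("CCF point estimates invert the expected-VAF formula", {
  expect_equal(estimate_ccf(mut_df("S1", "g", 50, 50, 1))$ccf, 1.0)
  expect_equal(estimate_ccf(mut_df("S1", "g", 50, 0, 0.8))$ccf, 0)
  # vaf 0.25, purity 0.6, CN 2, m 1 -> 0.25 * 2 / 0.6
  est <- estimate_ccf(mut_df("S1", "g", 75, 25, 0.6))
  expect_equal(est$ccf, 0.25 * 2 / 0.6, tolerance = 1e-12)
  # grid-search inversion of the forward VAF model agrees to 1e-6
  v_of <- function(ccf, p, cn, m) m * ccf * p / (p * cn + 2 * (1 - p))
  grid <- seq(0, 1, by = 1e-6)
  inv <- grid[which.min(abs(v_of(grid, 0.6, 2, 1) - 0.25))]
  expect_equal(est$ccf, inv, tolerance = 1e-6)
  expect_error(estimate_ccf(mut_df("S1", "g", 0, 0, 0.6)), "depth")
})

test_that("CCF is monotone in VAF at fixed multiplicity, with valid intervals", {
  # alt capped so the estimated multiplicity stays at 1 throughout
  alt <- seq(0, 50, by = 5)
  est <- estimate_ccf(mut_df("S1", "g", 100 - alt, alt, 0.7))
  expect_true(all(est$multiplicity == 1L))
  expect_true(all(diff(est$ccf) >= 0))
  expect_true(all(est$ci_low <= est$ccf & est$ccf <= est$ci_high))
  expect_true(all(est$ccf >= 0 & est$ccf <= 1))
})

test_that("read-count CCF recovery is unbiased with calibrated intervals", {
  set.seed(50)
  n <- 200
  truth <- sample(c(0.2, 0.5, 1.0), n, replace = TRUE)
  purity <- runif(n, 0.4, 0.9)
  reads <- simulate_mutation_reads(truth, purity, 2L, 1L, 100)
  est <- estimate_ccf(data.frame(sample_id = seq_len(n), gene = "g",
                                 ref_count = reads$ref_count,
                                 alt_count = reads$alt_count,
                                 purity = purity, local_cn = 2L))
  # near-zero bias in the interior strata; the clonal stratum can only be
  # underestimated (estimates clamp at 1) but stays close
  for (cc in c(0.2, 0.5)) {
    expect_lt(abs(mean(est$ccf[truth == cc]) - cc), 0.05)
  }
  expect_gte(mean(est$ccf[truth == 1]), 0.9)
  expect_gte(mean(est$ci_low <= truth & truth <= est$ci_high), 0.9)
})

test_that("deletion clonality solves the two-population mixture equation", {
  g <- toy_genome()
  region <- list(chrom = "chr1", start = 10e6, end = 12e6)
  est0 <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, 0), region, 0.5)
  expect_equal(est0$ccf, 0)
  # L = log2(0.75), purity 0.5 -> c = 2 * 0.25 / 0.5 = 1.0
  est1 <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, log2(0.75)),
                             region, 0.5)
  expect_equal(est1$ccf, 1.0, tolerance = 1e-12)
  # L = -1, purity 1 -> c = 1 exactly (full heterozygous loss in a pure tumor)
  est2 <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, -1), region, 1)
  expect_equal(est2$ccf, 1.0)
  # gains are flagged, not inverted
  gain <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, 0.4), region, 0.5)
  expect_true(gain$not_deletion)
  expect_equal(gain$ccf, 0)
  # implied c > 1 flags possible bi-allelic loss
  bi <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, -1.5), region, 1)
  expect_true(bi$biallelic)
  expect_equal(bi$ccf, 1)
  expect_error(deletion_clonality(seg_df("S1", "chr2", 0, 40e6, -1), region, 1),
               "not covered")
})

test_that("deletion closed form matches brute-force mixture inversion to 1e-9", {
  region <- list(chrom = "chr1", start = 10e6, end = 12e6)
  for (purity in c(0.3, 0.5, 0.8, 1)) {
    for (ccf_true in seq(0.05, 1, by = 0.05)) {
      L <- log2((2 - purity * ccf_true) / 2)
      est <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, L), region, purity)
      expect_equal(est$ccf, oracle_deletion_ccf(L, purity), tolerance = 1e-9)
    }
  }
})

test_that("deletion clonality uses the length-weighted mean log2 over a region", {
  region <- list(chrom = "chr1", start = 0, end = 10e6)
  seg <- rbind(seg_df("S1", "chr1", 0, 8e6, -0.5),
               seg_df("S1", "chr1", 8e6, 60e6, -0.1))
  L <- (8e6 * -0.5 + 2e6 * -0.1) / 10e6
  est <- deletion_clonality(seg, region, 0.9)
  expect_equal(est$ccf, min(1, 2 * (1 - 2^L) / 0.9), tolerance = 1e-12)
  expect_true(est$ci_high > est$ci_low)  # multi-segment spread widens the interval
})

test_that("read-count and segment-based clonality agree on paired simulations", {
  set.seed(51)
  region <- list(chrom = "chr1", start = 10e6, end = 12e6)
  for (i in 1:25) {
    ccf <- runif(1, 0.2, 1)
    purity <- runif(1, 0.4, 0.9)
    reads <- simulate_mutation_reads(ccf, purity, 2L, 1L, 10000)
    snv <- estimate_ccf(mut_df("S1", "g", reads$ref_count, reads$alt_count, purity))
    L <- log2((2 - purity * ccf) / 2)
    del <- deletion_clonality(seg_df("S1", "chr1", 0, 60e6, L), region, purity)
    expect_lt(abs(snv$ccf - del$ccf), 0.05)
  }
})

test_that("precedence test counts wins outside the tie zone", {
  r <- precedence_test(rep(1, 5), rep(0.6, 5))
  expect_equal(r$wins_a, 5L)
  expect_equal(r$p_value, 2^-5)
  expect_true(r$edge)
  # all ties -> no evidence either way
  tie <- precedence_test(rep(0.7, 6), rep(0.7, 6))
  expect_equal(tie$p_value, 1)
  expect_false(tie$edge)
  # antisymmetry
  fwd <- precedence_test(c(1, 1, 1, 0.9, 1), c(0.5, 0.6, 0.4, 0.5, 0.7))
  rev <- precedence_test(c(0.5, 0.6, 0.4, 0.5, 0.7), c(1, 1, 1, 0.9, 1))
  expect_true(fwd$edge)
  expect_false(rev$edge)
  expect_equal(rev$wins_b, fwd$wins_a)
  # too few shared samples
  few <- precedence_test(1, 0.5)
  expect_equal(few$status, "insufficient_data")
  expect_false(few$edge)
})

test_that("evolution graph recovers a planted hierarchy and stays acyclic", {
  cfg <- cohort_config(n_samples = 300, seed = 61)
  co <- simulate_cohort(cfg)
  est <- cohort_clonality_estimates(co)
  est <- est[est$lesion %in% c(cfg$driver_gene, cfg$deletion_lesions$lesion), ]
  g <- build_evolution_graph(est, min_cooccurrence = 10L)
  edges <- paste(g$edges$from, g$edges$to)
  planted <- paste(cfg$driver_gene, cfg$deletion_lesions$lesion)
  expect_true(all(planted %in% edges))
  expect_false(any(g$edges$to == cfg$driver_gene))
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      vertices = g$nodes)
  expect_true(igraph::is_dag(ig))
})

test_that("cycle resolution removes the weakest edge", {
  # non-transitive dominance across disjoint sample subsets (Condorcet cycle);
  # C -> A is supported by 5/6 wins, the weakest of the three edges
  est <- rbind(
    data.frame(sample_id = paste0("p", 1:5), lesion = "A", ccf = 1),
    data.frame(sample_id = paste0("p", 1:5), lesion = "B", ccf = 0.5),
    data.frame(sample_id = paste0("q", 1:5), lesion = "B", ccf = 1),
    data.frame(sample_id = paste0("q", 1:5), lesion = "C", ccf = 0.5),
    data.frame(sample_id = paste0("r", 1:6), lesion = "C", ccf = c(1, 1, 1, 1, 1, 0.5)),
    data.frame(sample_id = paste0("r", 1:6), lesion = "A", ccf = c(0.5, 0.5, 0.5, 0.5, 0.5, 1)))
  g <- build_evolution_graph(est, alpha = 0.2)
  edges <- paste(g$edges$from, g$edges$to)
  expect_setequal(edges, c("A B", "B C"))
  expect_equal(paste(g$removed_edges$from, g$removed_edges$to), "C A")
  # a single lesion gives one node and no edges
  solo <- build_evolution_graph(data.frame(sample_id = paste0("s", 1:4),
                                           lesion = "A", ccf = 1))
  expect_equal(solo$nodes, "A")
  expect_equal(nrow(solo$edges), 0L)
  # DOT export names every node and edge
  dot <- evolution_graph_dot(g)
  expect_true(any(grepl("\"A\" -> \"B\"", dot)))
})
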