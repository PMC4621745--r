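test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- cohort_config(n_samples = 40, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$data, b$data)
})

test_that("p_high = 0 yields a pure low-rearrangement cohort", {
  cfg <- cohort_config(n_samples = 30, p_high = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$class == "low"))
  ev <- classify_events(co$data$rearrangements)
  b <- count_by_sample(ev, co$data$sample_sheet)
  # intra counts track the low rate, nowhere near the high rate
  expect_lt(mean(b$n_intra), cohort_config()$intra_rate_high / 2)
})

test_that("per-class intra-count means track the generating rates", {
  cfg <- cohort_config(n_samples = 400, intra_rate_low = 20,
                       intra_rate_high = 200, dispersion = 10, seed = 1)
  co <- simulate_cohort(cfg)
  ev <- classify_events(co$data$rearrangements)
  b <- count_by_sample(ev, co$data$sample_sheet)
  m_low <- mean(b$n_intra[co$truth$class == "low"])
  m_high <- mean(b$n_intra[co$truth$class == "high"])
  expect_lt(abs(m_low - 20) / 20, 0.15)
  expect_lt(abs(m_high - 200) / 200, 0.15)
})

test_that("simulated rearrangements have the requested composition and classify back", {
  g <- default_genome()
  expect_equal(nrow(simulate_rearrangements(0, 0, g)), 0L)
  set.seed(2)
  ev <- simulate_rearrangements(50, 20, g, "S1")
  expect_equal(sum(ev$chrom_a == ev$chrom_b), 50L)
  expect_equal(sum(ev$chrom_a != ev$chrom_b), 20L)
  # round trip: the classifier recovers the generated subtype of every event
  generated <- ev$subtype
  ev$subtype <- NA_character_
  expect_equal(classify_events(ev)$subtype, generated)
})

test_that("segment simulation hits the target fraction altered", {
  g <- toy_genome()  # 100 Mb
  for (target in c(0, 0.25, 1)) {
    seg <- simulate_segments(target, g, sample_id = "S1")
    validate_segments(seg, g)
    expect_equal(fraction_genome_altered(seg, g), target, tolerance = 0.02)
  }
  expect_equal(fraction_genome_altered(simulate_segments(0, g), g), 0)
  # a positive target below the minimum segment size cannot be realized
  expect_error(simulate_segments(5e-4, g), "unreachable")
})

test_that("planted deletion segments appear verbatim and count toward the target", {
  g <- toy_genome()
  forced <- data.frame(chrom = "chr2", start = 10e6, end = 12e6,
                       log2_ratio = -0.6)
  set.seed(5)
  seg <- simulate_segments(0.3, g, forced = forced)
  validate_segments(seg, g)
  hit <- seg$chrom == "chr2" & seg$start == 10e6 & seg$end == 12e6
  expect_equal(sum(hit), 1L)
  expect_equal(seg$log2_ratio[hit], -0.6)
  expect_equal(fraction_genome_altered(seg, g), 0.3, tolerance = 0.02)
})

test_that("simulated read counts follow the expected VAF model", {
  set.seed(8)
  expect_true(all(simulate_mutation_reads(rep(0, 50), 0.7)$alt_count == 0))
  # ccf=1, purity=1, CN=2, m=1 -> v = 0.5
  r <- simulate_mutation_reads(1, 1, 2L, 1L, depth_mean = 1e5)
  expect_equal(r$alt_count / (r$alt_count + r$ref_count), 0.5,
               tolerance = 3 * sqrt(0.25 / 1e5) / 0.5)
  # ccf=0.8, purity=0.6, CN=2, m=1 -> v = 0.24
  r <- simulate_mutation_reads(0.8, 0.6, 2L, 1L, depth_mean = 1e5)
  vaf <- r$alt_count / (r$alt_count + r$ref_count)
  expect_equal(vaf, 0.24, tolerance = 3 * sqrt(0.24 * 0.76 / 1e5) / 0.24)
  expect_error(simulate_mutation_reads(1.2, 0.5), "ccf")
  expect_error(simulate_mutation_reads(0.5, 0.5, 2L, 3L), "multiplicity")
})

test_that("generated cohorts pass the cohort_io validators via a file round trip", {
  cfg <- cohort_config(n_samples = 12, seed = 11)
  co <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  g <- read_genome_tsv(paths["genome"])
  sheet <- read_sample_sheet(paths["sample_sheet"])
  expect_identical(sheet$sample_id, co$data$sample_sheet$sample_id)
  ev <- read_rearrangements(paths["rearrangements"], g)
  expect_equal(nrow(ev), nrow(co$data$rearrangements))
  seg <- read_segments(paths["segments"], g)
  expect_equal(nrow(seg), nrow(co$data$segments))
  expect_equal(seg$log2_ratio, co$data$segments$log2_ratio, tolerance = 1e-12)
  mut <- read_mutations(paths["mutations"], sheet)
  expect_equal(mut$alt_count, co$data$mutations$alt_count)
  expect_equal(mut$purity, co$data$mutations$purity, tolerance = 1e-12)
  reg <- read_regions_bed(paths["regions"], g)
  expect_equal(reg$name, cfg$deletion_lesions$lesion)
})

test_that("planted deletion CCFs stay below the driver CCF in co-occurring samples", {
  cfg <- cohort_config(n_samples = 200, driver_ccf = 0.9, seed = 13)
  co <- simulate_cohort(cfg)
  for (lesion in cfg$deletion_lesions$lesion) {
    ccf <- co$truth[[paste0("ccf_", lesion)]]
    both <- co$truth$driver == 1L & !is.na(ccf)
    expect_true(all(ccf[both] < 0.9))
  }
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(p_high = 1.2), "p_high")
  expect_error(cohort_config(dispersion = -1), "positive")
  expect_error(cohort_config(purity_range = c(0, 0.9)), "purity_range")
  expect_error(cohort_config(driver_ccf = 0), "driver_ccf")
})
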