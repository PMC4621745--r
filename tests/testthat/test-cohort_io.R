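test_that("BEDPE records map to events with sorted ends and validated chromosomes", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c(
    "chr1\t100\t101\tchr1\t5000\t5001\tS1\t.\t+\t-",
    "chr1\t9000\t9001\tchr1\t200\t201\tS1\t.\t-\t+",   # unsorted on disk
    "chr2\t50\t51\tchr1\t70\t71\tS2\t.\t+\t+"
  ), f)
  ev <- read_rearrangements(f, g)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$pos_a[1], 100)
  expect_equal(ev$pos_b[1], 5000)
  expect_true(all(is.na(ev$subtype)))
  # ends sorted, strands swapped along with positions
  expect_equal(ev$pos_a[2], 200)
  expect_equal(ev$strand_a[2], "+")
  expect_equal(ev$strand_b[2], "-")
  # interchromosomal events are left as given
  expect_equal(ev$chrom_a[3], "chr2")
  expect_equal(ev$sample_id, c("S1", "S1", "S2"))
})

test_that("BEDPE reader rejects unknown chromosomes and malformed lines", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t1\t2\tchrX\t10\t11\tS1\t.\t+\t-", f)
  expect_error(read_rearrangements(f, g), "chrX")
  writeLines(c("chr1\t1\t2\tchr1\t10\t11\tS1\t.\t+\t-", "chr1\t5\t6"), f)
  expect_error(read_rearrangements(f, g), "line 2")
  writeLines(character(), f)
  expect_equal(nrow(read_rearrangements(f, g)), 0L)
})

test_that("rearrangements survive a write/read round trip exactly", {
  g <- default_genome()
  set.seed(4)
  ev <- classify_events(simulate_rearrangements(20, 10, g, "S9"))
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_rearrangements(ev, f)
  back <- classify_events(read_rearrangements(f, g))
  expect_equal(back, ev, ignore_attr = TRUE)
})

test_that("SEG coordinates convert 1-based inclusive to 0-based half-open", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "S1\tchr1\t1\t1000000\t50\t-1.0"), f)
  seg <- read_segments(f, g)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 1e6)
  expect_equal(seg$log2_ratio, -1)

  # round trip through write_segments is the identity
  f2 <- withr::local_tempfile(fileext = ".seg")
  write_segments(seg, f2)
  expect_equal(read_segments(f2, g), seg, ignore_attr = TRUE)
})

test_that("overlapping segments are rejected with sample and chromosome named", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t1\t500\t0.0",
               "S1\tchr1\t400\t900\t-0.5"), f)
  expect_error(read_segments(f, g), "S1 on chr1")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean"), f)
  expect_equal(nrow(read_segments(f, g)), 0L)
})

test_that("mutation reader joins purity and applies defaults and contracts", {
  sheet <- data.frame(sample_id = "S1", purity = 0.8)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tgene\tref_count\talt_count",
               "S1\tchr2\t47677762\tSPOP\t60\t40"), f)
  mut <- read_mutations(f, sheet)
  expect_equal(mut$purity, 0.8)
  expect_equal(mut$local_cn, 2L)
  expect_equal(mut$pos, 47677761)  # stored 0-based

  writeLines(c("sample_id\tchrom\tpos\tgene\tref_count\talt_count",
               "S2\tchr2\t100\tSPOP\t60\t40"), f)
  expect_error(read_mutations(f, sheet), "S2")

  writeLines(c("sample_id\tchrom\tpos\tgene\tref_count\talt_count",
               "S1\tchr2\t100\tSPOP\t-1\t40"), f)
  expect_error(read_mutations(f, sheet), "non-negative")

  # zero alternate reads is a valid observation (VAF 0)
  writeLines(c("sample_id\tchrom\tpos\tgene\tref_count\talt_count",
               "S1\tchr2\t100\tSPOP\t50\t0"), f)
  expect_equal(read_mutations(f, sheet)$alt_count, 0)
})

test_that("write_results emits one TSV per table and a faithful manifest", {
  d <- withr::local_tempdir()
  tabs <- list(alpha = data.frame(x = 1:3, y = c("a", "b", "c")),
               empty = data.frame(x = numeric(), y = character()))
  man <- write_results(tabs, d, metadata = list(seed = 1))
  expect_equal(man$n_rows, c(3L, 0L))
  expect_true(all(file.exists(file.path(d, man$file))))
  # empty table still has its header
  lines <- readLines(file.path(d, "empty.tsv"))
  expect_equal(lines[length(lines)], "x\ty")
  # rerun is byte-identical
  d2 <- withr::local_tempdir()
  write_results(tabs, d2, metadata = list(seed = 1))
  expect_identical(readLines(file.path(d, "alpha.tsv")),
                   readLines(file.path(d2, "alpha.tsv")))
})

test_that("genome definition enforces its invariants", {
  expect_error(genome_def(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(genome_def("chr1", 0), "positive")
  g <- genome_def(c("chr1", "chrX"), c(100, 50))
  expect_equal(genome_total_length(g), 100)
  expect_equal(genome_total_length(g, include_sex = TRUE), 150)
})
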