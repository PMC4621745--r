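# Shared fixtures and independent oracles, built in code.

toy_genome <- function() genome_def(c("chr1", "chr2"), c(60e6, 40e6))

# one-sample segment table builder (internal 0-based half-open convention)
seg_df <- function(sample_id, chrom, start, end, log2_ratio) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2_ratio = log2_ratio, stringsAsFactors = FALSE)
}

event_df <- function(sample_id, chrom_a, pos_a, strand_a,
                     chrom_b, pos_b, strand_b, subtype = NA_character_) {
  data.frame(sample_id = sample_id, chrom_a = chrom_a, pos_a = pos_a,
             strand_a = strand_a, chrom_b = chrom_b, pos_b = pos_b,
             strand_b = strand_b, subtype = subtype, stringsAsFactors = FALSE)
}

mut_df <- function(sample_id, gene, ref, alt, purity, local_cn = 2L) {
  data.frame(sample_id = sample_id, gene = gene, ref_count = ref,
             alt_count = alt, purity = purity, local_cn = local_cn,
             stringsAsFactors = FALSE)
}

# Independent rank-sum oracle: one-sided p in the observed direction by
# exhaustive enumeration over index subsets, re-ranking from scratch.
oracle_ranksum_one_sided <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); nx <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(n, nx)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9))
}

# Independent hypergeometric lower-tail sum for the exclusivity test.
oracle_hyper_tail <- function(overlap, n_a, n_b, n) {
  ks <- 0:overlap
  sum(choose(n_a, ks) * choose(n - n_a, n_b - ks)) / choose(n, n_b)
}

# Brute-force solution of the two-population deletion mixture equation
# 2 * 2^L = purity * (2 - c) + 2 * (1 - purity), solved for c by uniroot.
oracle_deletion_ccf <- function(L, purity) {
  f <- function(c) 2 * 2^L - (purity * (2 - c) + 2 * (1 - purity))
  if (f(0) * f(1) > 0) return(if (abs(f(0)) < abs(f(1))) 0 else 1)
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

# Deletion-clonality estimates for every carrier of the planted deletion
# lesions of a synthetic cohort, by lesion name.
cohort_deletion_estimates <- function(cohort) {
  cfg <- cohort$config
  dels <- cfg$deletion_lesions
  sheet <- cohort$data$sample_sheet
  rows <- list()
  for (j in seq_len(nrow(dels))) {
    carried <- which(!is.na(cohort$truth[[paste0("ccf_", dels$lesion[j])]]))
    for (i in carried) {
      s <- sheet$sample_id[i]
      seg <- cohort$data$segments[cohort$data$segments$sample_id == s, ]
      rows[[paste(j, i)]] <- deletion_clonality(
        seg, list(chrom = dels$chrom[j], start = dels$start[j], end = dels$end[j]),
        sheet$purity[i], sample_id = s, lesion = dels$lesion[j])
    }
  }
  do.call(rbind, rows)
}

# All clonality estimates (driver/passenger SNVs + planted deletions) of a
# synthetic cohort, ready for build_evolution_graph().
cohort_clonality_estimates <- function(cohort) {
  cols <- c("sample_id", "lesion", "ccf")
  snv <- estimate_ccf(cohort$data$mutations)[, cols]
  del <- cohort_deletion_estimates(cohort)
  if (!is.null(del)) rbind(snv, del[, cols]) else snv
}
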