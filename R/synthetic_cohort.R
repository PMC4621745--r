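# Synthetic tumor-cohort generator. The generator plants exactly the
# structure the downstream analyses assume: two latent instability classes
# differing in intrachromosomal rearrangement rate, a driver point lesion
# enriched in the high-instability class, per-sample copy-number profiles
# with controllable fraction of genome altered, and a clonal hierarchy
# (clonal driver, subclonal deletions) realized as binomial allele read
# counts given purity, local copy number, and multiplicity.

#' Default toy genome for simulation
#'
#' Eight autosomes totalling 680 Mb; a scaled-down coordinate frame that
#' keeps segment tables small while leaving room for non-overlapping
#' recurrent deletion regions.
#' @return a [genome_def()].
#' @export
default_genome <- function() {
  genome_def(paste0("chr", 1:8),
             c(120e6, 110e6, 100e6, 90e6, 80e6, 70e6, 60e6, 50e6))
}

#' Default planted recurrent-deletion lesions
#'
#' Two 2-Mb regions on different chromosomes, enriched in the
#' high-instability class, with subclonal cancer-cell-fraction bounds. The
#' structure mirrors recurrent cytoband deletions (e.g. 5q21/6q21-type loci)
#' that co-occur with a clonal driver mutation.
#' @return data.frame with columns `lesion`, `chrom`, `start`, `end`,
#'   `prob_low`, `prob_high`, `ccf_lo`, `ccf_hi`.
#' @export
default_deletion_lesions <- function() {
  data.frame(
    lesion = c("DEL_chr5", "DEL_chr6"),
    chrom = c("chr5", "chr6"),
    start = c(30e6, 40e6),
    end = c(32e6, 42e6),
    prob_low = c(0.05, 0.05),
    prob_high = c(0.60, 0.50),
    ccf_lo = c(0.3, 0.3),
    ccf_hi = c(0.8, 0.8),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the emulated study conditions: a 55-tumor cohort with a
#' common low-rearrangement class and a less frequent high-rearrangement
#' class (20%), overdispersed negative-binomial rearrangement counts (means
#' 20 vs 200 intrachromosomal, class-independent interchromosomal mean 15,
#' size 10), a clonal driver point mutation strongly enriched in the high
#' class (odds ratio 20 over a 10% baseline), subclonal recurrent deletions,
#' per-class fraction-of-genome-altered Beta distributions centred at 0.05
#' and 0.25, sequencing depth 100, and purity uniform on [0.4, 0.9].
#'
#' @param n_samples number of tumors.
#' @param p_high share of the high-rearrangement class in `[0, 1]`.
#' @param intra_rate_low,intra_rate_high mean intrachromosomal events per
#'   sample in the low/high class.
#' @param inter_rate mean interchromosomal events (class-independent).
#' @param dispersion negative-binomial size parameter for all event counts.
#' @param driver_gene name of the planted driver point-mutation lesion.
#' @param driver_or odds ratio of driver presence, high vs low class.
#' @param driver_prob_low driver presence probability in the low class.
#' @param driver_ccf true cancer cell fraction of the driver in carriers.
#' @param deletion_lesions data.frame as [default_deletion_lesions()].
#' @param passenger_genes names of class-independent passenger point lesions.
#' @param passenger_prob presence probability of each passenger lesion.
#' @param fga_beta_low,fga_beta_high `(alpha, beta)` of the per-class
#'   fraction-of-genome-altered Beta distributions.
#' @param depth mean sequencing depth (Poisson).
#' @param purity_range `(lo, hi)` of the uniform purity distribution, in (0, 1].
#' @param seed integer seed; identical seed + config gives identical cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 55, p_high = 0.2,
                          intra_rate_low = 20, intra_rate_high = 200,
                          inter_rate = 15, dispersion = 10,
                          driver_gene = "DRIVER1", driver_or = 20,
                          driver_prob_low = 0.1, driver_ccf = 1.0,
                          deletion_lesions = default_deletion_lesions(),
                          passenger_genes = paste0("PSG", 1:5),
                          passenger_prob = 0.15,
                          fga_beta_low = c(2, 38), fga_beta_high = c(5, 15),
                          depth = 100, purity_range = c(0.4, 0.9),
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), p_high = p_high,
              intra_rate_low = intra_rate_low, intra_rate_high = intra_rate_high,
              inter_rate = inter_rate, dispersion = dispersion,
              driver_gene = driver_gene, driver_or = driver_or,
              driver_prob_low = driver_prob_low, driver_ccf = driver_ccf,
              deletion_lesions = deletion_lesions,
              passenger_genes = passenger_genes, passenger_prob = passenger_prob,
              fga_beta_low = fga_beta_low, fga_beta_high = fga_beta_high,
              depth = depth, purity_range = purity_range, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
    if (p_high < 0 || p_high > 1) stop("p_high must lie in [0, 1]", call. = FALSE)
    rates <- c(intra_rate_low, intra_rate_high, inter_rate, dispersion, depth)
    if (any(!is.finite(rates)) || any(rates <= 0)) {
      stop("rates, dispersion and depth must be positive", call. = FALSE)
    }
    if (driver_or <= 0) stop("driver_or must be positive", call. = FALSE)
    if (driver_prob_low <= 0 || driver_prob_low >= 1) {
      stop("driver_prob_low must lie in (0, 1)", call. = FALSE)
    }
    if (driver_ccf <= 0 || driver_ccf > 1) stop("driver_ccf must lie in (0, 1]", call. = FALSE)
    if (purity_range[1] <= 0 || purity_range[2] > 1 || purity_range[1] > purity_range[2]) {
      stop("purity_range must be within (0, 1] with lo <= hi", call. = FALSE)
    }
    if (nrow(deletion_lesions) > 0) {
      if (any(deletion_lesions$ccf_lo <= 0) || any(deletion_lesions$ccf_hi > 1) ||
          any(deletion_lesions$ccf_lo > deletion_lesions$ccf_hi)) {
        stop("deletion lesion ccf bounds must be within (0, 1] with lo <= hi", call. = FALSE)
      }
    }
    if (any(c(fga_beta_low, fga_beta_high) <= 0)) {
      stop("fga beta parameters must be positive", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Simulate breakpoint pairs for one sample
#'
#' Intrachromosomal events draw a subtype uniformly from
#' deletion/tandem duplication/inversion and receive the corresponding
#' strand pair; interchromosomal events join two distinct chromosomes.
#' Positions are uniform within chromosomes (chromosomes chosen
#' length-proportionally).
#'
#' @param n_intra,n_inter event counts (>= 0).
#' @param genome a [genome_def()].
#' @param sample_id sample identifier stored on every event.
#' @return rearrangement data.frame (see [read_rearrangements()]) with
#'   `subtype` filled by construction.
#' @export
simulate_rearrangements <- function(n_intra, n_inter, genome, sample_id = "S1") {
  stopifnot(n_intra >= 0, n_inter >= 0)
  prob <- genome$length / sum(genome$length)
  parts <- list()
  if (n_intra > 0) {
    chrom <- sample(genome$chrom, n_intra, replace = TRUE, prob = prob)
    len <- chrom_length_of(genome, chrom)
    p1 <- floor(stats::runif(n_intra, 0, len - 1))
    p2 <- floor(stats::runif(n_intra, 0, len - 1))
    same <- p1 == p2
    p2[same] <- p1[same] + 1
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    subtype <- sample(c("deletion", "tandem_duplication", "inversion"),
                      n_intra, replace = TRUE)
    strand_a <- ifelse(subtype == "deletion", "+",
                       ifelse(subtype == "tandem_duplication", "-",
                              sample(c("+", "-"), n_intra, replace = TRUE)))
    strand_b <- ifelse(subtype == "deletion", "-",
                       ifelse(subtype == "tandem_duplication", "+", strand_a))
    parts$intra <- data.frame(sample_id = sample_id, chrom_a = chrom, pos_a = lo,
                              strand_a = strand_a, chrom_b = chrom, pos_b = hi,
                              strand_b = strand_b, subtype = subtype,
                              stringsAsFactors = FALSE)
  }
  if (n_inter > 0) {
    idx_a <- sample.int(nrow(genome), n_inter, replace = TRUE, prob = prob)
    # second chromosome drawn among the remaining ones, length-proportional
    idx_b <- vapply(idx_a, function(i) {
      cand <- which(seq_len(nrow(genome)) != i)
      cand[sample.int(length(cand), 1L, prob = prob[cand])]
    }, integer(1))
    len_a <- genome$length[idx_a]; len_b <- genome$length[idx_b]
    parts$inter <- data.frame(
      sample_id = sample_id, chrom_a = genome$chrom[idx_a],
      pos_a = floor(stats::runif(n_inter, 0, len_a)),
      strand_a = sample(c("+", "-"), n_inter, replace = TRUE),
      chrom_b = genome$chrom[idx_b],
      pos_b = floor(stats::runif(n_inter, 0, len_b)),
      strand_b = sample(c("+", "-"), n_inter, replace = TRUE),
      subtype = "interchromosomal", stringsAsFactors = FALSE)
  }
  if (length(parts) == 0L) return(empty_rearrangements())
  sort_event_ends(do.call(rbind, parts))
}

#' Simulate a copy-number segment profile with a target fraction altered
#'
#' Builds a full-coverage segmentation of the genome in which the total
#' length of segments whose |log2 ratio| reaches `log2_threshold` matches
#' `target_fga` (up to rounding). Altered segments get log2 ratios of random
#' sign with magnitude in [0.3, 1]; neutral segments lie within +/- 0.05.
#' `forced` segments (planted deletions with known log2) are laid down
#' first and respected by the filler.
#'
#' @param target_fga desired fraction of genome altered, in `[0, 1]`.
#' @param genome a [genome_def()].
#' @param sample_id sample identifier.
#' @param log2_threshold |log2| at or above which a segment counts as altered.
#' @param min_seg_length smallest altered block the generator will create;
#'   an unreachable positive target below this size is an error.
#' @param forced optional data.frame `chrom`, `start`, `end`, `log2_ratio`
#'   of segments that must appear verbatim in the profile.
#' @return segment data.frame (see [read_segments()]).
#' @export
simulate_segments <- function(target_fga, genome, sample_id = "S1",
                              log2_threshold = 0.2, min_seg_length = 1e5,
                              forced = NULL) {
  if (target_fga < 0 || target_fga > 1) stop("target_fga must lie in [0, 1]", call. = FALSE)
  total <- sum(genome$length)
  target_len <- round(target_fga * total)
  if (target_len > 0 && target_len < min_seg_length) {
    stop("target FGA unreachable: implied altered length below min_seg_length",
         call. = FALSE)
  }
  forced_alt <- 0
  forced_by_chrom <- vector("list", nrow(genome))
  names(forced_by_chrom) <- genome$chrom
  if (!is.null(forced) && nrow(forced) > 0) {
    forced_alt <- sum((forced$end - forced$start)[abs(forced$log2_ratio) >= log2_threshold])
    forced_by_chrom <- split(forced, factor(forced$chrom, levels = genome$chrom))
  }
  remaining <- max(0, target_len - forced_alt)

  # free intervals per chromosome = chromosome minus forced segments
  free <- lapply(seq_len(nrow(genome)), function(i) {
    f <- forced_by_chrom[[genome$chrom[i]]]
    if (is.null(f) || nrow(f) == 0) {
      data.frame(start = 0, end = genome$length[i])
    } else {
      o <- order(f$start)
      bounds <- c(0, as.vector(rbind(f$start[o], f$end[o])), genome$length[i])
      iv <- data.frame(start = bounds[seq(1, length(bounds), 2)],
                       end = bounds[seq(2, length(bounds), 2)])
      iv[iv$end > iv$start, , drop = FALSE]
    }
  })
  free_len <- vapply(free, function(iv) sum(iv$end - iv$start), numeric(1))
  total_free <- sum(free_len)
  alloc <- floor(remaining * free_len / max(total_free, 1))
  alloc <- pmin(alloc, free_len)
  short <- remaining - sum(alloc)
  # hand out the rounding shortfall to chromosomes with spare capacity
  for (i in order(free_len - alloc, decreasing = TRUE)) {
    if (short <= 0) break
    add <- min(short, free_len[i] - alloc[i])
    alloc[i] <- alloc[i] + add
    short <- short - add
  }

  segs <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    f <- forced_by_chrom[[chrom]]
    if (!is.null(f) && nrow(f) > 0) {
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = chrom, start = f$start, end = f$end,
        log2_ratio = f$log2_ratio, stringsAsFactors = FALSE)
    }
    left <- alloc[i]
    for (k in seq_len(nrow(free[[i]]))) {
      iv <- free[[i]][k, ]
      iv_len <- iv$end - iv$start
      alt_here <- min(left, iv_len)
      left <- left - alt_here
      if (alt_here == iv_len) {
        pieces <- data.frame(start = iv$start, end = iv$end, altered = TRUE)
      } else if (alt_here > 0) {
        off <- floor(stats::runif(1, 0, iv_len - alt_here))
        a0 <- iv$start + off; a1 <- a0 + alt_here
        pieces <- rbind(
          if (a0 > iv$start) data.frame(start = iv$start, end = a0, altered = FALSE),
          data.frame(start = a0, end = a1, altered = TRUE),
          if (a1 < iv$end) data.frame(start = a1, end = iv$end, altered = FALSE))
      } else {
        pieces <- data.frame(start = iv$start, end = iv$end, altered = FALSE)
      }
      sgn <- sample(c(-1, 1), nrow(pieces), replace = TRUE)
      log2r <- ifelse(pieces$altered,
                      sgn * stats::runif(nrow(pieces), max(0.3, log2_threshold), 1),
                      stats::runif(nrow(pieces), -0.05, 0.05))
      segs[[length(segs) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = chrom, start = pieces$start,
        end = pieces$end, log2_ratio = log2r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  out <- out[order(match(out$chrom, genome$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate allele read counts for a lesion of known cancer cell fraction
#'
#' Sequencing depth is Poisson with mean `depth_mean` (floored at one read),
#' and the alternate-allele count is binomial with success probability
#' `v = multiplicity * ccf * purity / (purity * local_cn + 2 * (1 - purity))`,
#' the expected variant allele fraction of a lesion carried by a fraction
#' `ccf` of tumor cells in a specimen of the given purity.
#'
#' @param ccf true cancer cell fraction in `[0, 1]` (vectorized).
#' @param purity tumor purity in (0, 1].
#' @param local_cn total copy number at the locus in tumor cells.
#' @param multiplicity mutated copies per carrier cell, in `[1, local_cn]`.
#' @param depth_mean mean sequencing depth.
#' @return data.frame with columns `ref_count`, `alt_count`.
#' @export
simulate_mutation_reads <- function(ccf, purity, local_cn = 2L,
                                    multiplicity = 1L, depth_mean = 100) {
  n <- max(length(ccf), length(purity))
  ccf <- rep_len(ccf, n); purity <- rep_len(purity, n)
  local_cn <- rep_len(local_cn, n); multiplicity <- rep_len(multiplicity, n)
  if (any(ccf < 0 | ccf > 1)) stop("ccf must lie in [0, 1]", call. = FALSE)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]", call. = FALSE)
  if (any(multiplicity < 1 | multiplicity > local_cn)) {
    stop("multiplicity must lie in [1, local_cn]", call. = FALSE)
  }
  depth <- stats::rpois(n, depth_mean)
  depth[depth == 0L] <- 1L
  v <- multiplicity * ccf * purity / (purity * local_cn + 2 * (1 - purity))
  alt <- stats::rbinom(n, depth, v)
  data.frame(ref_count = depth - alt, alt_count = alt)
}

#' Simulate a full synthetic cohort
#'
#' Draws class labels Bernoulli(`p_high`); negative-binomial intra- and
#' interchromosomal event counts; driver presence with class-conditional
#' odds; deletion-lesion presence with class-conditional probabilities and
#' subclonal cancer cell fractions constrained below the driver's; a segment
#' profile per sample hitting a class-specific Beta-drawn fraction of genome
#' altered, with planted deletion segments whose log2 ratio encodes purity
#' and deletion clonality (`log2((2 - purity * ccf) / 2)`, mono-allelic
#' loss); and binomial allele read counts for every point lesion.
#'
#' @param config a [cohort_config()].
#' @param genome a [genome_def()] (default [default_genome()]).
#' @return list of class `synthetic_cohort` with elements `truth` (sample
#'   classes, per-lesion true CCFs, planted lesion order), `data`
#'   (rearrangements, segments, mutations, sample_sheet), `genome`, `config`.
#' @export
simulate_cohort <- function(config, genome = default_genome()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sample_id <- sprintf("S%03d", seq_len(n))
  class_high <- stats::rbinom(n, 1L, config$p_high)
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])

  n_intra <- stats::rnbinom(n, size = config$dispersion,
                            mu = ifelse(class_high == 1L,
                                        config$intra_rate_high,
                                        config$intra_rate_low))
  n_inter <- stats::rnbinom(n, size = config$dispersion, mu = config$inter_rate)

  odds_low <- config$driver_prob_low / (1 - config$driver_prob_low)
  p_driver <- ifelse(class_high == 1L,
                     odds_low * config$driver_or / (1 + odds_low * config$driver_or),
                     config$driver_prob_low)
  driver <- stats::rbinom(n, 1L, p_driver)

  dels <- config$deletion_lesions
  del_present <- matrix(0L, n, nrow(dels),
                        dimnames = list(sample_id, dels$lesion))
  del_ccf <- matrix(NA_real_, n, max(1L, nrow(dels)),
                    dimnames = list(sample_id, if (nrow(dels)) dels$lesion))
  for (j in seq_len(nrow(dels))) {
    p <- ifelse(class_high == 1L, dels$prob_high[j], dels$prob_low[j])
    del_present[, j] <- stats::rbinom(n, 1L, p)
    ccf <- stats::runif(n, dels$ccf_lo[j], dels$ccf_hi[j])
    # planted order: in driver carriers the deletion stays below the driver CCF
    cap <- ifelse(driver == 1L, config$driver_ccf * 0.999, 1)
    del_ccf[, j] <- ifelse(del_present[, j] == 1L, pmin(ccf, cap), NA_real_)
  }

  fga_target <- ifelse(class_high == 1L,
                       stats::rbeta(n, config$fga_beta_high[1], config$fga_beta_high[2]),
                       stats::rbeta(n, config$fga_beta_low[1], config$fga_beta_low[2]))
  # Beta draws below the segment-size resolution collapse to zero burden
  fga_target[fga_target * sum(genome$length) < 1e5] <- 0

  events <- vector("list", n)
  segments <- vector("list", n)
  for (i in seq_len(n)) {
    events[[i]] <- simulate_rearrangements(n_intra[i], n_inter[i], genome,
                                           sample_id = sample_id[i])
    forced <- NULL
    carried <- which(del_present[i, ] == 1L)
    if (length(carried)) {
      forced <- data.frame(
        chrom = dels$chrom[carried], start = dels$start[carried],
        end = dels$end[carried],
        log2_ratio = log2((2 - purity[i] * del_ccf[i, carried]) / 2))
    }
    segments[[i]] <- simulate_segments(fga_target[i], genome,
                                       sample_id = sample_id[i],
                                       forced = forced)
  }

  # point-mutation observations: driver + class-independent passengers
  psg <- config$passenger_genes
  psg_present <- matrix(stats::rbinom(n * length(psg), 1L, config$passenger_prob),
                        n, length(psg), dimnames = list(sample_id, psg))
  psg_ccf <- matrix(stats::runif(n * length(psg), 0.3, 1), n, length(psg),
                    dimnames = list(sample_id, psg))
  gene_pos <- gene_loci(c(config$driver_gene, psg), genome)
  mut_rows <- list()
  add_mut <- function(i, gene, ccf) {
    reads <- simulate_mutation_reads(ccf, purity[i], 2L, 1L, config$depth)
    data.frame(sample_id = sample_id[i], chrom = gene_pos$chrom[gene_pos$gene == gene],
               pos = gene_pos$pos[gene_pos$gene == gene], gene = gene,
               ref_count = reads$ref_count, alt_count = reads$alt_count,
               local_cn = 2L, purity = purity[i], stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (driver[i] == 1L) {
      mut_rows[[length(mut_rows) + 1L]] <- add_mut(i, config$driver_gene, config$driver_ccf)
    }
    for (j in seq_along(psg)) {
      if (psg_present[i, j] == 1L) {
        mut_rows[[length(mut_rows) + 1L]] <- add_mut(i, psg[j], psg_ccf[i, j])
      }
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample_id = character(), chrom = character(), pos = numeric(),
               gene = character(), ref_count = integer(), alt_count = integer(),
               local_cn = integer(), purity = numeric())

  sheet <- data.frame(sample_id = sample_id, purity = purity,
                      driver_status = ifelse(driver == 1L, "mutant", "wildtype"),
                      stringsAsFactors = FALSE)

  truth_samples <- data.frame(
    sample_id = sample_id,
    class = ifelse(class_high == 1L, "high", "low"),
    fga_target = fga_target, driver = driver,
    driver_ccf = ifelse(driver == 1L, config$driver_ccf, NA_real_),
    stringsAsFactors = FALSE)
  truth_dels <- as.data.frame(del_ccf)
  if (nrow(dels)) names(truth_dels) <- paste0("ccf_", dels$lesion)
  truth <- cbind(truth_samples, if (nrow(dels)) truth_dels)
  order_df <- if (nrow(dels)) {
    data.frame(before = config$driver_gene, after = dels$lesion,
               stringsAsFactors = FALSE)
  } else {
    data.frame(before = character(), after = character())
  }

  out <- list(truth = truth, planted_order = order_df,
              data = list(rearrangements = do.call(rbind, events),
                          segments = do.call(rbind, segments),
                          mutations = mutations, sample_sheet = sheet),
              genome = genome, config = config)
  class(out) <- "synthetic_cohort"
  out
}

# Fixed, deterministic loci for the simulated point-mutation genes.
gene_loci <- function(genes, genome) {
  idx <- ((seq_along(genes) - 1L) %% nrow(genome)) + 1L
  data.frame(gene = genes, chrom = genome$chrom[idx],
             pos = floor(genome$length[idx] / 10) + 1000 * seq_along(genes),
             stringsAsFactors = FALSE)
}

#' Regions of the planted deletion lesions as a BED-style data.frame
#' @param config a [cohort_config()].
#' @return data.frame `chrom`, `start`, `end`, `name` usable wherever a
#'   recurrent-region table is expected.
#' @export
deletion_regions <- function(config) {
  dels <- config$deletion_lesions
  data.frame(chrom = dels$chrom, start = dels$start, end = dels$end,
             name = dels$lesion, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk in the package's input formats
#'
#' Produces `rearrangements.bedpe`, `segments.seg`, `mutations.tsv`,
#' `sample_sheet.tsv`, `genome.tsv`, `regions.bed`, and a `truth.tsv` with
#' the generating labels.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return named character vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    rearrangements = file.path(dir, "rearrangements.bedpe"),
    segments = file.path(dir, "segments.seg"),
    mutations = file.path(dir, "mutations.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    genome = file.path(dir, "genome.tsv"),
    regions = file.path(dir, "regions.bed"),
    truth = file.path(dir, "truth.tsv"))
  write_rearrangements(cohort$data$rearrangements, paths["rearrangements"])
  write_segments(cohort$data$segments, paths["segments"])
  write_mutations(cohort$data$mutations, paths["mutations"])
  write_tsv_with_meta(cohort$data$sample_sheet, paths["sample_sheet"])
  write_tsv_with_meta(as.data.frame(cohort$genome), paths["genome"])
  reg <- deletion_regions(cohort$config)
  utils::write.table(
    data.frame(reg$chrom, format_coord(reg$start), format_coord(reg$end), reg$name),
    paths["regions"], sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_with_meta(cohort$truth, paths["truth"])
  paths
}
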