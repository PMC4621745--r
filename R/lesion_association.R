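# Samples x lesions presence matrix, rank-sum association of lesions with
# rearrangement burden (with Benjamini-Hochberg control), and one-tail
# Fisher mutual-exclusivity testing.

#' Build the samples x lesions presence matrix
#'
#' A point-mutation lesion is present in a sample iff the sample has at
#' least one mutation in that gene. A deletion lesion (one per supplied
#' recurrent region) is present iff any segment overlapping the region has
#' `log2_ratio <= -log2_del_threshold`. Lesions seen in fewer than
#' `min_recurrence` samples are dropped (with a message) -- "recurrent"
#' means at least 3 carriers by default.
#'
#' @param mutations mutation data.frame ([read_mutations()]).
#' @param segments segment data.frame ([read_segments()]).
#' @param sample_ids sample universe (rows of the matrix).
#' @param regions optional data.frame `chrom`, `start`, `end`, `name` of
#'   recurrent regions defining deletion lesions.
#' @param genome optional [genome_def()] used to validate region chromosomes.
#' @param log2_del_threshold deletion call threshold (segment log2 at or
#'   below its negative counts as deleted; default 0.2).
#' @param min_recurrence minimum carriers for a lesion to be kept.
#' @return binary integer matrix (samples x lesions) with attribute
#'   `lesion_kind` (`"point_mutation"` or `"deletion"` per column).
#' @export
build_lesion_matrix <- function(mutations, segments, sample_ids,
                                regions = NULL, genome = NULL,
                                log2_del_threshold = 0.2, min_recurrence = 3L) {
  stopifnot(log2_del_threshold > 0)
  cols <- list(); kind <- character()
  genes <- sort(unique(mutations$gene))
  for (g in genes) {
    carriers <- unique(mutations$sample_id[mutations$gene == g])
    cols[[g]] <- as.integer(sample_ids %in% carriers)
    kind[g] <- "point_mutation"
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    if (!is.null(genome)) check_chroms(regions$chrom, genome, "region")
    for (j in seq_len(nrow(regions))) {
      hit <- segments$chrom == regions$chrom[j] &
        segments$start < regions$end[j] & segments$end > regions$start[j] &
        segments$log2_ratio <= -log2_del_threshold
      carriers <- unique(segments$sample_id[hit])
      nm <- regions$name[j]
      cols[[nm]] <- as.integer(sample_ids %in% carriers)
      kind[nm] <- "deletion"
    }
  }
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(integer(), nrow = length(sample_ids), ncol = 0)
  rownames(m) <- sample_ids
  low <- colSums(m) < min_recurrence
  if (any(low)) {
    message("dropping non-recurrent lesion(s): ",
            paste(colnames(m)[low], collapse = ", "))
    kind <- kind[!low]
    m <- m[, !low, drop = FALSE]
  }
  attr(m, "lesion_kind") <- kind
  m
}

#' Associate one lesion with rearrangement burden
#'
#' Rank-sum comparison (same engine as [compare_burden()]) of per-sample
#' burden between carriers and non-carriers of a lesion.
#'
#' @param presence binary vector over samples.
#' @param burden per-sample burden counts, aligned with `presence`.
#' @return one-row data.frame: `n_carrier`, `n_noncarrier`, `direction`
#'   (sign of carrier-minus-noncarrier median difference), `p_value`,
#'   `minus_log10_p`.
#' @export
associate_lesion_with_burden <- function(presence, burden) {
  if (length(presence) != length(burden)) {
    stop("presence and burden must be aligned", call. = FALSE)
  }
  carriers <- presence == 1L
  if (all(carriers) || !any(carriers)) {
    stop("association needs both carriers and non-carriers", call. = FALSE)
  }
  rs <- rank_sum_test(burden[carriers], burden[!carriers])
  data.frame(n_carrier = sum(carriers), n_noncarrier = sum(!carriers),
             direction = sign(stats::median(burden[carriers]) -
                                stats::median(burden[!carriers])),
             p_value = rs$p_two, p_one_sided = rs$p_one,
             minus_log10_p = -log10(rs$p_two))
}

#' Associate every lesion with every burden channel
#'
#' @param lesion_matrix matrix from [build_lesion_matrix()].
#' @param burden_table data.frame from [count_by_sample()].
#' @param channels burden channels to test (columns `n_intra`, `n_inter`,
#'   `n_total` of the burden table, named `intra`/`inter`/`total`).
#' @return data.frame with one row per lesion x channel, unadjusted; feed to
#'   [rank_associations()] for q-values.
#' @export
associate_all <- function(lesion_matrix, burden_table,
                          channels = c("intra", "inter", "total")) {
  stopifnot(all(rownames(lesion_matrix) == burden_table$sample_id))
  kind <- attr(lesion_matrix, "lesion_kind")
  rows <- list()
  for (ch in channels) {
    b <- burden_table[[paste0("n_", ch)]]
    for (lesion in colnames(lesion_matrix)) {
      res <- associate_lesion_with_burden(lesion_matrix[, lesion], b)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(lesion = lesion, kind = unname(kind[lesion]), channel = ch,
                   stringsAsFactors = FALSE), res)
    }
  }
  do.call(rbind, rows)
}

#' Rank associations with Benjamini-Hochberg q-values
#'
#' Adds a `q_value` per burden channel (BH step-up across the lesions tested
#' in that channel) and sorts by channel then ascending p.
#'
#' @param results data.frame from [associate_all()] (or rows shaped like
#'   [associate_lesion_with_burden()] output plus `lesion` and `channel`).
#' @return the ranked, annotated data.frame.
#' @export
rank_associations <- function(results) {
  if (nrow(results) == 0L) stop("no association results", call. = FALSE)
  if (is.null(results$channel)) results$channel <- "total"
  results$q_value <- NA_real_
  for (ch in unique(results$channel)) {
    i <- results$channel == ch
    results$q_value[i] <- stats::p.adjust(results$p_value[i], method = "BH")
  }
  results <- results[order(results$channel, results$p_value), , drop = FALSE]
  rownames(results) <- NULL
  results
}

#' One-tail Fisher test of mutual exclusivity
#'
#' Tests whether two lesions co-occur less often than expected: the p-value
#' is the hypergeometric probability of an overlap at most as large as
#' observed, given the two lesion margins. A zero margin (a lesion present
#' in no or all samples) is degenerate and returns p = 1.
#'
#' @param presence_a,presence_b binary vectors over the same samples.
#' @return list: `n`, `n_a`, `n_b`, `overlap`, `odds_ratio`, `p_value`,
#'   `degenerate`.
#' @export
mutual_exclusivity <- function(presence_a, presence_b) {
  if (length(presence_a) != length(presence_b)) {
    stop("presence vectors must cover the same samples", call. = FALSE)
  }
  a <- presence_a == 1L; b <- presence_b == 1L
  n <- length(a); n_a <- sum(a); n_b <- sum(b); both <- sum(a & b)
  degenerate <- n_a == 0L || n_b == 0L || n_a == n || n_b == n
  p <- if (degenerate) 1 else stats::phyper(both, n_a, n - n_a, n_b)
  tab_b <- n_a - both; tab_c <- n_b - both; tab_d <- n - n_a - n_b + both
  or <- (both * tab_d) / (tab_b * tab_c)
  list(n = n, n_a = n_a, n_b = n_b, overlap = both,
       odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Pairwise mutual-exclusivity table for a lesion matrix
#' @param lesion_matrix matrix from [build_lesion_matrix()].
#' @return data.frame with one row per unordered lesion pair.
#' @export
exclusivity_all <- function(lesion_matrix) {
  lesions <- colnames(lesion_matrix)
  if (length(lesions) < 2L) {
    return(data.frame(lesion_a = character(), lesion_b = character(),
                      overlap = integer(), odds_ratio = numeric(),
                      p_value = numeric(), degenerate = logical()))
  }
  pairs <- utils::combn(lesions, 2)
  rows <- apply(pairs, 2, function(p) {
    r <- mutual_exclusivity(lesion_matrix[, p[1]], lesion_matrix[, p[2]])
    data.frame(lesion_a = p[1], lesion_b = p[2], overlap = r$overlap,
               odds_ratio = r$odds_ratio, p_value = r$p_value,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
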