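# Cancer-cell-fraction (clonality) estimation with purity and copy-number
# correction, pairwise lesion precedence testing, and assembly of an acyclic
# tumor-evolution graph.
#
# Model: a lesion carried by a fraction ccf of tumor cells at multiplicity m
# in a specimen of purity p with local total copy number CN has expected
# variant allele fraction
#     v = m * ccf * p / (p * CN + 2 * (1 - p)).
# The estimators below invert this map.

#' Estimate mutation multiplicity from the variant allele fraction
#'
#' `m = round(vaf * (purity * local_cn + 2 * (1 - purity)) / purity)`,
#' clamped to `[1, local_cn]`. Rounding the copy-weighted VAF is the
#' simplest estimator with correct behavior at m = 1 and m = CN.
#'
#' @param vaf variant allele fraction in `[0, 1]` (vectorized).
#' @param purity tumor purity in (0, 1].
#' @param local_cn total copy number at the locus.
#' @return integer multiplicity.
#' @export
estimate_multiplicity <- function(vaf, purity, local_cn = 2L) {
  if (any(purity <= 0)) stop("purity must be positive", call. = FALSE)
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]", call. = FALSE)
  m <- round(vaf * (purity * local_cn + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(m, 1), local_cn))
}

#' Estimate cancer cell fraction from allele read counts
#'
#' For each observation, `vaf = alt / (alt + ref)`; multiplicity comes from
#' [estimate_multiplicity()]; then
#' `ccf = vaf * (purity * local_cn + 2 * (1 - purity)) / (purity * m)`,
#' clamped to `[0, 1]`. The 95% interval propagates a central
#' `Beta(alt + 0.5, ref + 0.5)` (Jeffreys) interval on the VAF through the
#' same linear map, clamped, and widened if needed so it contains the point
#' estimate.
#'
#' @param mutations mutation data.frame with columns `sample_id`, `gene`,
#'   `ref_count`, `alt_count`, `purity`, `local_cn`
#'   (see [read_mutations()]); zero total depth is an error.
#' @return data.frame with columns `sample_id`, `lesion`, `ccf`, `ci_low`,
#'   `ci_high`, `multiplicity`, `method` (`"snv_readcount"`).
#' @export
estimate_ccf <- function(mutations) {
  depth <- mutations$ref_count + mutations$alt_count
  if (any(depth <= 0)) stop("zero sequencing depth in mutation observation", call. = FALSE)
  if (any(mutations$purity <= 0 | mutations$purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  vaf <- mutations$alt_count / depth
  m <- estimate_multiplicity(vaf, mutations$purity, mutations$local_cn)
  scale <- (mutations$purity * mutations$local_cn + 2 * (1 - mutations$purity)) /
    (mutations$purity * m)
  ccf <- pmin(1, pmax(0, vaf * scale))
  lo <- pmin(1, pmax(0, stats::qbeta(0.025, mutations$alt_count + 0.5,
                                     mutations$ref_count + 0.5) * scale))
  hi <- pmin(1, pmax(0, stats::qbeta(0.975, mutations$alt_count + 0.5,
                                     mutations$ref_count + 0.5) * scale))
  data.frame(sample_id = mutations$sample_id, lesion = mutations$gene,
             ccf = ccf, ci_low = pmin(lo, ccf), ci_high = pmax(hi, ccf),
             multiplicity = m, method = "snv_readcount",
             stringsAsFactors = FALSE)
}

#' Estimate deletion clonality from segment log-ratios
#'
#' With `L` the length-weighted mean log2 ratio of segments overlapping the
#' region, the two-population mixture for a mono-allelic deletion carried by
#' a fraction `c` of tumor cells satisfies `2 * 2^L = 2 - purity * c`, so
#' `c = 2 * (1 - 2^L) / purity`, clamped to `[0, 1]`. An implied `c > 1`
#' before clamping is flagged as possible bi-allelic loss; `L > 0` (a gain)
#' returns ccf 0 with a not-a-deletion flag. The interval propagates the
#' length-weighted standard deviation of the per-segment log2 ratios through
#' the same map.
#'
#' @param segments segment data.frame for one sample.
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param purity tumor purity in (0, 1].
#' @param sample_id sample label for the output (default from segments).
#' @param lesion lesion name for the output (default `"deletion"`).
#' @return one-row data.frame matching [estimate_ccf()] output, with
#'   `method = "segment_logratio"` plus flags `not_deletion`, `biallelic`.
#' @export
deletion_clonality <- function(segments, region, purity,
                               sample_id = segments$sample_id[1],
                               lesion = "deletion") {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]", call. = FALSE)
  ov <- segments$chrom == region$chrom &
    segments$start < region$end & segments$end > region$start
  if (!any(ov)) stop("region not covered by any segment", call. = FALSE)
  seg <- segments[ov, , drop = FALSE]
  w <- pmin(seg$end, region$end) - pmax(seg$start, region$start)
  w <- w / sum(w)
  L <- sum(w * seg$log2_ratio)
  if (L > 0) {
    return(data.frame(sample_id = sample_id, lesion = lesion, ccf = 0,
                      ci_low = 0, ci_high = 0, multiplicity = NA_integer_,
                      method = "segment_logratio", not_deletion = TRUE,
                      biallelic = FALSE, stringsAsFactors = FALSE))
  }
  c_raw <- 2 * (1 - 2^L) / purity
  ccf <- min(1, max(0, c_raw))
  se_L <- sqrt(sum(w * (seg$log2_ratio - L)^2))
  deriv <- 2 * log(2) * 2^L / purity  # |d c / d L|
  lo <- min(1, max(0, c_raw - 1.96 * deriv * se_L))
  hi <- min(1, max(0, c_raw + 1.96 * deriv * se_L))
  data.frame(sample_id = sample_id, lesion = lesion, ccf = ccf,
             ci_low = min(lo, ccf), ci_high = max(hi, ccf),
             multiplicity = NA_integer_, method = "segment_logratio",
             not_deletion = FALSE, biallelic = c_raw > 1,
             stringsAsFactors = FALSE)
}

#' Test whether lesion A precedes lesion B
#'
#' Within samples carrying both lesions, a "win" for A is a sample where
#' `ccf_a >= ccf_b + delta` (delta is the tie zone; default 0.1 CCF).
#' Samples within the tie zone are ignored, and the wins are compared
#' against a fair coin by a one-sided binomial sign test. An edge A -> B is
#' declared when the p-value falls below `alpha`.
#'
#' @param ccf_a,ccf_b CCF estimates of the two lesions over shared samples
#'   (aligned vectors).
#' @param delta tie zone in CCF units.
#' @param alpha edge significance threshold.
#' @param min_cooccurrence minimum shared samples for an informative test.
#' @return list: `n_shared`, `wins_a`, `wins_b`, `p_value`, `edge`,
#'   `mean_gap` (mean of `ccf_a - ccf_b`), `status`
#'   (`"ok"` or `"insufficient_data"`).
#' @export
precedence_test <- function(ccf_a, ccf_b, delta = 0.1, alpha = 0.05,
                            min_cooccurrence = 3L) {
  stopifnot(length(ccf_a) == length(ccf_b))
  n <- length(ccf_a)
  if (n < min_cooccurrence) {
    return(list(n_shared = n, wins_a = NA_integer_, wins_b = NA_integer_,
                p_value = 1, edge = FALSE, mean_gap = NA_real_,
                status = "insufficient_data"))
  }
  wins_a <- sum(ccf_a >= ccf_b + delta)
  wins_b <- sum(ccf_b >= ccf_a + delta)
  n_eff <- wins_a + wins_b
  p <- if (n_eff == 0L) 1 else
    stats::pbinom(wins_a - 1L, n_eff, 0.5, lower.tail = FALSE)
  list(n_shared = n, wins_a = wins_a, wins_b = wins_b, p_value = p,
       edge = p < alpha, mean_gap = mean(ccf_a - ccf_b), status = "ok")
}

#' Build an acyclic lesion-evolution graph from clonality estimates
#'
#' Runs [precedence_test()] for every ordered lesion pair with sufficient
#' co-occurrence (samples holding CCF estimates for both lesions) and keeps
#' the significant edges. If the edge set contains a cycle, the edge with
#' the largest sign-test p-value inside a cycle is removed, repeatedly,
#' until the graph is acyclic. The result is deterministic given the
#' estimates.
#'
#' @param estimates data.frame with columns `sample_id`, `lesion`, `ccf`
#'   (rows = lesion observed in sample), e.g. rbind-ed output of
#'   [estimate_ccf()] and [deletion_clonality()].
#' @param delta,alpha,min_cooccurrence see [precedence_test()].
#' @return list of class `evolution_graph`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `n_shared`, `wins`, `losses`, `mean_gap`, `p_value`),
#'   `removed_edges` (edges dropped during cycle resolution).
#' @export
build_evolution_graph <- function(estimates, delta = 0.1, alpha = 0.05,
                                  min_cooccurrence = 3L) {
  lesions <- sort(unique(estimates$lesion))
  edge_rows <- list()
  for (a in lesions) for (b in lesions) {
    if (a == b) next
    ea <- estimates[estimates$lesion == a, ]
    eb <- estimates[estimates$lesion == b, ]
    shared <- intersect(ea$sample_id, eb$sample_id)
    if (length(shared) < min_cooccurrence) next
    pt <- precedence_test(ea$ccf[match(shared, ea$sample_id)],
                          eb$ccf[match(shared, eb$sample_id)],
                          delta = delta, alpha = alpha,
                          min_cooccurrence = min_cooccurrence)
    if (isTRUE(pt$edge)) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        from = a, to = b, n_shared = pt$n_shared, wins = pt$wins_a,
        losses = pt$wins_b, mean_gap = pt$mean_gap, p_value = pt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(from = character(), to = character(), n_shared = integer(),
               wins = integer(), losses = integer(), mean_gap = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  removed <- edges[0, , drop = FALSE]
  while (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       vertices = lesions)
    comp <- igraph::components(g, mode = "strong")
    if (max(comp$csize) == 1L) break
    in_cycle <- comp$membership[edges$from] == comp$membership[edges$to] &
      comp$csize[comp$membership[edges$from]] > 1L
    drop <- which(in_cycle)[which.max(edges$p_value[in_cycle])]
    removed <- rbind(removed, edges[drop, , drop = FALSE])
    edges <- edges[-drop, , drop = FALSE]
  }
  rownames(edges) <- NULL
  out <- list(nodes = lesions, edges = edges, removed_edges = removed)
  class(out) <- "evolution_graph"
  out
}

#' @export
print.evolution_graph <- function(x, ...) {
  cat(sprintf("Evolution graph: %d lesion(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -> %s (wins %d/%d, p = %.3g)\n",
                  x$edges$from[i], x$edges$to[i], x$edges$wins[i],
                  x$edges$wins[i] + x$edges$losses[i], x$edges$p_value[i]))
    }
  }
  invisible(x)
}

#' Render an evolution graph in DOT format
#' @param graph an [build_evolution_graph()] result.
#' @return character vector of DOT lines.
#' @export
evolution_graph_dot <- function(graph) {
  stopifnot(inherits(graph, "evolution_graph"))
  body <- c(sprintf('  "%s";', graph$nodes),
            if (nrow(graph$edges)) {
              sprintf('  "%s" -> "%s" [label="p=%.3g"];',
                      graph$edges$from, graph$edges$to, graph$edges$p_value)
            })
  c("digraph evolution {", body, "}")
}
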