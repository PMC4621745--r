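# Fraction of genome altered, binned histograms, and the rank-sum engine
# used for all burden comparisons in the package.

#' Fraction of genome altered for one sample
#'
#' FGA is the summed length of segments whose |log2 ratio| reaches
#' `log2_threshold`, divided by the total length of the included
#' chromosomes. Genome not covered by any segment counts as unaltered, and
#' both gains and losses count as altered. Sex chromosomes are excluded from
#' the denominator by default.
#'
#' @param segments segment data.frame for a single sample.
#' @param genome a [genome_def()].
#' @param log2_threshold positive |log2| alteration cutoff (default 0.2, a
#'   conventional array copy-number threshold).
#' @param include_sex include sex chromosomes in numerator and denominator.
#' @return FGA in `[0, 1]`.
#' @export
fraction_genome_altered <- function(segments, genome, log2_threshold = 0.2,
                                    include_sex = FALSE) {
  stopifnot(log2_threshold > 0)
  if (nrow(segments) == 0L) {
    warning("empty segment profile; FGA = 0")
    return(0)
  }
  if (length(unique(segments$sample_id)) > 1L) {
    stop("segments contain several samples; use fga_by_sample()", call. = FALSE)
  }
  keep <- if (include_sex) rep(TRUE, nrow(segments)) else !is_sex_chrom(segments$chrom)
  seg <- segments[keep, , drop = FALSE]
  altered <- sum((seg$end - seg$start)[abs(seg$log2_ratio) >= log2_threshold])
  altered / genome_total_length(genome, include_sex = include_sex)
}

#' Fraction of genome altered for every sample in a segment table
#'
#' @param segments segment data.frame covering one or more samples.
#' @param sample_ids sample universe; samples without segments get FGA 0.
#' @inheritParams fraction_genome_altered
#' @return named numeric vector of FGA values.
#' @export
fga_by_sample <- function(segments, genome, sample_ids = NULL,
                          log2_threshold = 0.2, include_sex = FALSE) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  vapply(sample_ids, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) == 0L) 0 else
      fraction_genome_altered(seg, genome, log2_threshold, include_sex)
  }, numeric(1))
}

DEFAULT_FGA_EDGES <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Bin per-sample FGA values into a histogram
#'
#' Binning is left-closed except for the open first bin: with the default
#' edges the bins are `<0.01`, `[0.01,0.05)`, ..., `[0.4,0.5)`, `>=0.5`.
#' Counts always sum to the number of samples per group.
#'
#' @param values FGA values in `[0, 1]`.
#' @param edges strictly increasing interior bin edges.
#' @param groups optional per-sample group labels; one count column per group.
#' @return data.frame with a `bin` column and one count column per group
#'   (or a single `count` column).
#' @export
bin_fga <- function(values, edges = DEFAULT_FGA_EDGES, groups = NULL) {
  if (any(values < 0 | values > 1)) stop("FGA values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  k <- length(edges)
  labels <- c(paste0("<", edges[1]),
              if (k > 1) sprintf("[%s,%s)", edges[-k], edges[-1]),
              paste0(">=", edges[k]))
  idx <- findInterval(values, edges) + 1L  # left-closed; exact edge goes up
  out <- data.frame(bin = labels, stringsAsFactors = FALSE)
  if (is.null(groups)) {
    out$count <- tabulate(idx, nbins = k + 1L)
  } else {
    groups <- as.character(groups)
    for (g in sort(unique(groups))) {
      out[[g]] <- tabulate(idx[groups == g], nbins = k + 1L)
    }
  }
  out
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' The shared test engine for burden comparisons and lesion associations.
#' When both groups have at most `exact_max` observations the null
#' distribution of the rank sum is enumerated exhaustively over all
#' assignments of the pooled (tied) ranks, so ties are handled exactly;
#' otherwise the tie-corrected normal approximation is used (no continuity
#' correction). The one-sided p-value is the tail in the direction of the
#' observed effect; the two-sided p doubles it, capped at 1.
#'
#' Note that `p_one` (the observed-direction tail) is the quantity usually
#' quoted alongside an effect, but it is not a fixed-direction test: under
#' the null it is uniform on (0, 1/2). For calibration or a prespecified
#' alternative use `p_greater`/`p_less`.
#'
#' @param x,y numeric vectors of the two groups (both non-empty).
#' @param exact_max maximum per-group size for exhaustive enumeration
#'   (default 8).
#' @return list with `W` (rank sum of `x`), `p_one`, `p_two`, `p_greater`
#'   (fixed-direction: `x` above `y`), `p_less`, `direction` (+1 if `x`
#'   ranks above `y`), `method` ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    sums <- utils::combn(r, nx, sum)
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu) / sqrt(sigma2)
    p_lo <- stats::pnorm(z)
    p_hi <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  p_one <- min(p_lo, p_hi)
  list(W = W, p_one = p_one, p_two = min(1, 2 * p_one),
       p_greater = p_hi, p_less = p_lo,
       direction = sign(W - mu), method = method)
}

#' Compare FGA burden between two groups
#'
#' Two-sample Wilcoxon-Mann-Whitney comparison of per-sample fractions of
#' genome altered, with the binned histogram per group.
#'
#' @param values per-sample FGA (named or aligned with `groups`).
#' @param groups binary group labels (exactly two levels, both non-empty).
#' @param edges histogram bin edges, as in [bin_fga()].
#' @return list of class `burden_comparison`: `groups`, `n`, `median`,
#'   `W`, `p_one`, `p_two`, `method`, `histogram`.
#' @export
compare_burden <- function(values, groups, edges = DEFAULT_FGA_EDGES) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("groups must have exactly two levels", call. = FALSE)
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty", call. = FALSE)
  rs <- rank_sum_test(x, y)
  out <- list(groups = lev,
              n = c(length(x), length(y)),
              median = c(stats::median(x), stats::median(y)),
              W = rs$W, p_one = rs$p_one, p_two = rs$p_two,
              p_greater = rs$p_greater, p_less = rs$p_less,
              direction = rs$direction, method = rs$method,
              histogram = bin_fga(values, edges, groups))
  class(out) <- "burden_comparison"
  out
}

#' @export
print.burden_comparison <- function(x, ...) {
  cat(sprintf("FGA burden comparison: %s (n=%d, median %.3f) vs %s (n=%d, median %.3f)\n",
              x$groups[1], x$n[1], x$median[1], x$groups[2], x$n[2], x$median[2]))
  cat(sprintf("  rank-sum W = %g, one-sided p = %.4g, two-sided p = %.4g (%s)\n",
              x$W, x$p_one, x$p_two, x$method))
  invisible(x)
}
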