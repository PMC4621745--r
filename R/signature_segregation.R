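# Unsupervised clustering of samples on a signature gene set and a
# permutation-calibrated statistic for how strongly a binary sample label
# segregates across the two top-level clusters.

#' Hierarchically cluster samples on a signature gene set
#'
#' Restricts the expression matrix to the signature genes (missing genes are
#' reported; at least 10 must match), computes the correlation distance
#' `1 - Pearson r` between sample profiles, and clusters with average
#' linkage. Samples are ordered lexicographically before clustering so the
#' result is deterministic and invariant to input order.
#'
#' @param expr numeric matrix, genes x samples (library-normalized,
#'   log-scale expected; used as given).
#' @param signature character vector of gene ids.
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_samples <- function(expr, signature) {
  matched <- intersect(signature, rownames(expr))
  missing <- setdiff(signature, rownames(expr))
  if (length(matched) < 10L) {
    stop("fewer than 10 signature genes matched; missing: ",
         paste(utils::head(missing, 20), collapse = ", "), call. = FALSE)
  }
  if (length(missing)) {
    message(length(missing), " signature gene(s) absent from the matrix")
  }
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  sub <- expr[matched, order(colnames(expr)), drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(sub))
  stats::hclust(d, method = "average")
}

#' Cut a sample dendrogram into its two top-level clusters
#'
#' Cluster 1 is the smaller of the two (on a size tie, the one containing
#' the lexicographically first sample).
#'
#' @param hc an [stats::hclust] tree (>= 2 samples).
#' @return named integer vector of cluster labels 1/2 per sample.
#' @export
cut_two <- function(hc) {
  k <- stats::cutree(hc, k = 2)
  n1 <- sum(k == 1); n2 <- sum(k == 2)
  swap <- n2 < n1 ||
    (n1 == n2 && k[sort(names(k))[1]] != 1)
  if (swap) k <- 3L - k
  k
}

#' Permutation-calibrated segregation of a label across two clusters
#'
#' The observed statistic is the smaller of the two clusters' hypergeometric
#' upper-tail enrichment p-values for labeled samples. Its null distribution
#' is obtained by permuting the label vector `n_permutations` times while
#' keeping the clustering fixed; the reported p-value is
#' `(1 + #(null <= observed)) / (n_permutations + 1)`.
#'
#' @param cluster_labels integer vector of 1/2 per sample ([cut_two()]).
#' @param mutation_labels binary/logical label per sample (>= 1 labeled).
#' @param n_permutations number of label permutations (> 0).
#' @param seed integer seed; the result is bit-for-bit reproducible.
#' @return list of class `segregation_result`: `cluster_sizes`,
#'   `labeled_per_cluster`, `observed` (min hypergeometric p), `p_value`,
#'   `n_permutations`, `seed`.
#' @export
segregation_pvalue <- function(cluster_labels, mutation_labels,
                               n_permutations = 1000L, seed = 1L) {
  if (length(cluster_labels) != length(mutation_labels)) {
    stop("labels must cover the same samples", call. = FALSE)
  }
  if (n_permutations < 1L) stop("n_permutations must be positive", call. = FALSE)
  lab <- as.integer(mutation_labels != 0)
  if (sum(lab) == 0L) stop("at least one labeled sample required", call. = FALSE)
  n <- length(lab); n_lab <- sum(lab)
  sizes <- c(sum(cluster_labels == 1L), sum(cluster_labels == 2L))

  stat <- function(lab) {
    k1 <- sum(lab[cluster_labels == 1L])
    k2 <- n_lab - k1
    # upper-tail enrichment P(X >= k) in each cluster
    min(stats::phyper(k1 - 1, n_lab, n - n_lab, sizes[1], lower.tail = FALSE),
        stats::phyper(k2 - 1, n_lab, n - n_lab, sizes[2], lower.tail = FALSE))
  }
  observed <- stat(lab)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations),
                 function(i) stat(lab[sample.int(n)]), numeric(1))
  out <- list(cluster_sizes = sizes,
              labeled_per_cluster = c(sum(lab[cluster_labels == 1L]),
                                      sum(lab[cluster_labels == 2L])),
              observed = observed,
              p_value = (1 + sum(null <= observed)) / (n_permutations + 1),
              n_permutations = n_permutations, seed = seed)
  class(out) <- "segregation_result"
  out
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation: clusters %d/%d, labeled %d/%d\n",
              x$cluster_sizes[1], x$cluster_sizes[2],
              x$labeled_per_cluster[1], x$labeled_per_cluster[2]))
  cat(sprintf("  min hypergeometric p = %.4g, permutation p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_permutations))
  invisible(x)
}
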