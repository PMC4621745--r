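# Rearrangement classification, per-sample burden counting, and decomposition
# of the burden distribution into low/high-instability subpopulations.

#' Classify rearrangement events by breakpoint geometry
#'
#' Events joining two chromosomes are interchromosomal. For same-chromosome
#' events with ends stored in sorted order, the strand pair determines the
#' subtype under the common paired-end convention:
#' `(+,-)` deletion, `(-,+)` tandem duplication, `(+,+)`/`(-,-)` inversion.
#'
#' @param events rearrangement data.frame with sorted ends
#'   (as produced by [read_rearrangements()] or [simulate_rearrangements()]).
#' @return the same data.frame with `subtype` filled in.
#' @export
classify_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  check_strands(c(events$strand_a, events$strand_b))
  same <- events$chrom_a == events$chrom_b
  if (any(same & events$pos_a > events$pos_b)) {
    stop("same-chromosome events must have pos_a <= pos_b; normalize ends first",
         call. = FALSE)
  }
  events$subtype <- ifelse(
    !same, "interchromosomal",
    ifelse(events$strand_a == "+" & events$strand_b == "-", "deletion",
           ifelse(events$strand_a == "-" & events$strand_b == "+",
                  "tandem_duplication", "inversion")))
  events
}

REARRANGEMENT_SUBTYPES <- c("deletion", "tandem_duplication", "inversion",
                            "interchromosomal")

#' Count rearrangement burden per sample
#'
#' Every sample in the sheet appears in the result (zero counts allowed);
#' events for samples absent from the sheet are an error.
#'
#' @param events classified rearrangement data.frame.
#' @param sample_sheet data.frame with a `sample_id` column.
#' @return data.frame with one row per sample: subtype counts plus
#'   `n_intra`, `n_inter`, `n_total`.
#' @export
count_by_sample <- function(events, sample_sheet) {
  ids <- sample_sheet$sample_id
  if (nrow(events) > 0) {
    if (anyNA(events$subtype)) stop("events must be classified first", call. = FALSE)
    unknown <- setdiff(unique(events$sample_id), ids)
    if (length(unknown)) {
      stop("event sample(s) absent from sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  tab <- table(factor(events$sample_id, levels = ids),
               factor(events$subtype, levels = REARRANGEMENT_SUBTYPES))
  out <- as.data.frame.matrix(tab)
  out <- data.frame(sample_id = ids, out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$n_intra <- out$deletion + out$tandem_duplication + out$inversion
  out$n_inter <- out$interchromosomal
  out$n_total <- out$n_intra + out$n_inter
  out
}

#' Fit a two-component Gaussian mixture to rearrangement counts
#'
#' Counts are modelled on the `log10(count + 1)` scale (burden spans orders
#' of magnitude across tumors; +1 guards zeros) with two Gaussian components
#' fitted by EM. Initialization splits the data at the median and uses the
#' two halves' moments, so the fit is deterministic and invariant to sample
#' order. Components are reported sorted by mean, making "low" and "high"
#' well defined. A one-component fit is computed alongside and compared by
#' BIC; on degenerate data (all counts equal) the one-component fit is
#' preferred rather than failing.
#'
#' @param counts non-negative per-sample totals (>= 6 samples); names are
#'   carried into the responsibilities.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below `tol` (default 1e-8) or after `max_iter` (default 500)
#'   iterations.
#' @return list of class `mixture_fit`: `mean`, `sd`, `weight` (each length
#'   2, ordered low/high), `responsibility` (n x 2 matrix), `loglik_trace`,
#'   `bic_one`, `bic_two`, `delta_bic` (`bic_one - bic_two`; positive favors
#'   two components), `one_component_preferred`, `converged`, `n_iter`.
#' @export
fit_two_component_mixture <- function(counts, max_iter = 500L, tol = 1e-8) {
  if (length(counts) < 6L) stop("need at least 6 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  x <- log10(counts + 1)
  n <- length(x)

  # one-component reference fit (MLE variance)
  mu0 <- mean(x)
  v0 <- max(mean((x - mu0)^2), 1e-12)
  ll1 <- sum(stats::dnorm(x, mu0, sqrt(v0), log = TRUE))
  bic_one <- -2 * ll1 + 2 * log(n)

  if (v0 < 1e-12 || length(unique(x)) == 1L) {
    resp <- matrix(c(rep(1, n), rep(0, n)), n, 2,
                   dimnames = list(names(counts), c("low", "high")))
    fit <- list(mean = c(low = mu0, high = mu0), sd = c(low = 0, high = 0),
                weight = c(low = 1, high = 0), responsibility = resp,
                loglik_trace = ll1, bic_one = bic_one, bic_two = Inf,
                delta_bic = -Inf, one_component_preferred = TRUE,
                converged = TRUE, n_iter = 0L)
    class(fit) <- "mixture_fit"
    return(fit)
  }

  # median-split (2-quantile) initialization
  lower <- x[x <= stats::median(x)]
  upper <- x[x > stats::median(x)]
  if (length(upper) == 0L) { upper <- max(x); lower <- x[x < max(x)] }
  mu <- c(mean(lower), mean(upper))
  v <- pmax(c(stats::var(lower), stats::var(upper)), v0 / 10, 1e-6)
  v[is.na(v)] <- v0
  w <- c(0.5, 0.5)

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- cbind(w[1] * stats::dnorm(x, mu[1], sqrt(v[1])),
                  w[2] * stats::dnorm(x, mu[2], sqrt(v[2])))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    gamma <- dens / rowsum_d
    if (ll - ll_prev < tol && iter > 1L) { converged <- TRUE; break }
    ll_prev <- ll
    nk <- pmax(colSums(gamma), 1e-12)
    mu <- colSums(gamma * x) / nk
    v <- pmax(colSums(gamma * (x - rep(mu, each = n))^2) / nk, 1e-6)
    w <- nk / n
  }

  ord <- order(mu)
  mu <- mu[ord]; v <- v[ord]; w <- w[ord]; gamma <- gamma[, ord, drop = FALSE]
  dimnames(gamma) <- list(names(counts), c("low", "high"))
  ll2 <- trace[length(trace)]
  bic_two <- -2 * ll2 + 5 * log(n)
  fit <- list(mean = c(low = mu[1], high = mu[2]),
              sd = c(low = sqrt(v[1]), high = sqrt(v[2])),
              weight = c(low = w[1], high = w[2]),
              responsibility = gamma, loglik_trace = trace,
              bic_one = bic_one, bic_two = bic_two,
              delta_bic = bic_one - bic_two,
              one_component_preferred = bic_one <= bic_two,
              converged = converged, n_iter = length(trace))
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture on log10(count + 1)\n")
  cat(sprintf("  low : mean %.3f sd %.3f weight %.3f\n",
              x$mean["low"], x$sd["low"], x$weight["low"]))
  cat(sprintf("  high: mean %.3f sd %.3f weight %.3f\n",
              x$mean["high"], x$sd["high"], x$weight["high"]))
  cat(sprintf("  delta BIC (one - two): %.2f%s\n", x$delta_bic,
              if (x$one_component_preferred) "  [one component preferred]" else ""))
  invisible(x)
}

#' Assign samples to the low/high subpopulation
#'
#' Label is the arg-max responsibility; ties go to "low" (in the degenerate
#' one-component case all responsibility already sits on "low").
#'
#' @param fit a [fit_two_component_mixture()] result.
#' @return named character vector of `"low"`/`"high"` per sample.
#' @export
assign_subpopulation <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  r <- fit$responsibility
  labels <- ifelse(r[, "high"] > r[, "low"], "high", "low")
  stats::setNames(labels, rownames(r))
}
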