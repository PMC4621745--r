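---
title: "Methods: cohort analysis of genomic instability, clonality, and lesion timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort analysis of genomic instability, clonality, and lesion timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gicohort)
```

This vignette documents the statistical models behind `gicohort`, the
choices that were genuinely open when the package was designed, and what
the synthetic-cohort generator does and does not emulate. The package
operates downstream of variant calling: its inputs are per-sample
structural-rearrangement calls (BEDPE), copy-number segments (SEG),
somatic point mutations with allele read counts, and a sample sheet with
tumor purity.

## Coordinate conventions

BEDPE is 0-based half-open on disk; SEG and the mutation table are 1-based
inclusive. Everything is converted once, at read time, to a single
internal convention (0-based half-open), and converted back on write. The
breakpoint position of a BEDPE end interval is its start coordinate: end
intervals are typically one base wide and a single representative point is
needed for ordering. For intrachromosomal events the two ends are stored
sorted (`pos_a <= pos_b`), which makes the strand-pair classification
below unambiguous.

## Rearrangement classification and burden decomposition

Same-chromosome breakpoint pairs are typed by the common paired-end strand
convention — (+,−) deletion, (−,+) tandem duplication, (+,+) or (−,−)
inversion — and cross-chromosome pairs are interchromosomal. The
convention varies between callers, so it is fixed in one function
(`classify_events()`) rather than scattered through the code.

Cohorts of this kind show rearrangement totals spanning two orders of
magnitude, with a common quiet population and a rarer unstable one. We
model per-sample totals on the `log10(count + 1)` scale as a two-component
Gaussian mixture fitted by EM. Design choices:

* **Scale.** Raw counts are heavily skewed; the log transform makes
  near-Gaussian components plausible, and +1 guards zero counts.
* **Initialization.** The sample is split at the median and each half
  supplies the initial mean and variance of one component. This is
  deterministic, order-invariant, and adequate because the regime of
  interest is well separated; a seed argument is unnecessary.
* **Stopping.** EM stops when the log-likelihood gain drops below 1e-8 or
  after 500 iterations; the trace is returned so monotonicity is
  checkable. Variances are floored at 1e-6 to prevent component collapse.
* **Model choice.** A one-component fit is always computed alongside and
  compared by BIC (`delta_bic = bic_one - bic_two`, positive favoring two
  components). Degenerate input (all counts equal) returns the
  one-component fit with a flag instead of failing.
* **Labels.** Components are sorted by mean so "low"/"high" are well
  defined; samples take the arg-max responsibility, ties going to "low".

Whether the original two-subpopulation split was delineated by a model or
by eye is not recorded anywhere we could consult; the mixture model is
this package's explicit, documented choice. The decomposition defaults to
total counts, but every downstream function accepts the intrachromosomal
channel, which is where the biological signal concentrates.

## Fraction of genome altered

FGA for a sample is the summed length of segments whose |log2 ratio|
meets a threshold, divided by the total length of the included
chromosomes. Three aspects are under-determined by convention and are
therefore explicit configuration with defaults:

* **Threshold** |log2| ≥ 0.2, a conventional array copy-number cutoff.
* **Direction**: gains and losses both count ("altered", not "deleted").
* **Denominator**: autosomes only; sex chromosomes are accepted in input
  but excluded by default (`include_sex = FALSE`) because hemizygous sex
  chromosomes distort log-ratio thresholds.

Uncovered genome counts as unaltered, so FGA is invariant to splitting a
segment into sub-segments of equal log2 — a property the tests assert.
The histogram uses left-closed bins with an open first bin (`<0.01`, ...,
`>=0.5`); only the extreme bin labels are conventional, the interior
edges are this package's choice.

## The rank-sum engine

All burden comparisons (FGA between classes, lesion carriers vs
non-carriers) share one Wilcoxon–Mann–Whitney implementation. When both
groups have at most eight observations the null distribution of the rank
sum is enumerated exhaustively over all assignments of the pooled
(mid)ranks, which is exact under ties; otherwise the tie-corrected normal
approximation is used, without continuity correction, which matches
`wilcox.test(..., exact = FALSE, correct = FALSE)` (a cross-check in the
test suite).

One subtlety: the "one-sided p in the observed direction" that accompanies
a reported effect is `min(P(W ≤ w), P(W ≥ w))`, which is uniform on
(0, 1/2) under the null — it is a description of the observed extreme, not
a calibrated fixed-direction test. `rank_sum_test()` therefore also
returns `p_greater` and `p_less` for prespecified alternatives, and the
calibration tests (type-I error ≈ 5% at α = 0.05, uniformity by
Kolmogorov–Smirnov) use those.

## Lesion association and mutual exclusivity

The lesion matrix marks a point-mutation lesion present if the sample has
any mutation in the gene, and a region-deletion lesion present if any
overlapping segment has log2 ≤ −0.2. Recurrent-region discovery is out of
scope; regions are an input. "Recurrent" is operationalized as ≥ 3
carriers (`min_recurrence`), below which a lesion is dropped with a
message — the threshold is a judgment call with no external definition to
defer to.

Each retained lesion is compared carrier vs non-carrier on the intra-,
inter-, and total-rearrangement channels; two-sided p-values receive
Benjamini–Hochberg q-values *within a channel*. Raw p (and −log10 p) are
kept in the output because burden-association figures are conventionally
drawn from unadjusted values, but a modern analysis must also control
multiplicity across the tested lesions. Which test underlies such
association figures is typically unstated; the rank-sum choice is recorded
in the output metadata.

Mutual exclusivity between two lesions is the one-tail Fisher test: with
margins fixed, p = P(overlap ≤ observed) under the hypergeometric null. A
zero margin makes the table degenerate and returns p = 1 with a flag
rather than a spurious signal.

## Clonality (cancer cell fraction)

A lesion carried at multiplicity $m$ by a fraction $c$ of tumor cells, at
total local copy number $CN$ in a specimen of purity $p$, has expected
variant allele fraction

$$v = \frac{m \, c \, p}{p \cdot CN + 2(1 - p)}.$$

`estimate_ccf()` inverts this linear map at the observed VAF.
Multiplicity is estimated by rounding $v (p \cdot CN + 2(1-p)) / p$ and
clamping to $[1, CN]$ — the simplest estimator that is correct at the two
ends ($m = 1$, $m = CN$); model-comparison alternatives exist but need
priors this package does not want to impose. The 95% interval propagates a
Jeffreys $\mathrm{Beta}(alt + 0.5,\ ref + 0.5)$ interval on the VAF
through the same map, clamps to $[0, 1]$, and is widened if necessary to
contain the (clamped) point estimate at the boundaries. Purity is an
input, not estimated; local copy number defaults to 2 when the mutation
table does not provide it.

Deletion clonality uses the segment channel: with $L$ the length-weighted
mean log2 ratio over a recurrent region, the two-population mixture for a
mono-allelic deletion gives $2 \cdot 2^L = 2 - p c$, hence
$c = 2(1 - 2^L)/p$, clamped. An implied $c > 1$ is flagged as possible
bi-allelic loss; $L > 0$ is flagged as not-a-deletion and returns 0. The
interval propagates the length-weighted spread of per-segment log2 values
through the same map, so a region covered by one segment gets a
zero-width interval — segment-level noise models are deliberately out of
scope.

At depth ~100 the per-observation CCF error is dominated by binomial VAF
noise amplified by the $2/p$ correction; with purity in [0.4, 0.9] the
mean absolute error of single observations sits near 0.07 (computed by
the acceptance script), while the intervals remain calibrated. Users
should average across observations or samples when they need tighter
estimates.

## Precedence testing and evolution graphs

Within samples carrying two lesions, lesion A "wins" where
$\mathrm{ccf}_A \ge \mathrm{ccf}_B + \delta$; the tie zone $\delta$
defaults to 0.1 CCF, absorbing estimation noise at typical depths.
Ignoring ties, wins are referred to a one-sided binomial sign test against
1/2, and p < α (default 0.05) declares the edge A→B. Pairs with fewer
than `min_cooccurrence` (default 3) shared samples are uninformative and
yield no edge. If the resulting directed graph contains a cycle, the edge
with the largest p inside a strongly connected component is removed,
repeatedly, until the graph is acyclic — preferring to discard the weakest
evidence. All of δ, α, and the co-occurrence floor are configuration; none
has a canonical published value.

## Signature segregation

Samples are clustered on the signature genes only, with
1 − Pearson-correlation distance and average linkage — the most common
transcriptome-dendrogram defaults, both configurable. Samples are sorted
lexicographically before clustering so the tree (and its root cut) is
deterministic and input-order invariant. The tree is cut at the root into
two clusters, and segregation of a binary sample label is scored as the
smaller of the two clusters' hypergeometric upper-tail enrichment
p-values; the score is calibrated by permuting the label vector with the
clustering held fixed, reporting
$(1 + \#\{\text{null} \le \text{observed}\})/(B + 1)$.

Two caveats discovered during validation, both inherent to this (simple,
conventional) pipeline:

* Correlation distance is blind to any uniform shift of the signature. A
  signature must move genes in both directions (as knockdown-derived
  signatures do) to be visible, and the expression matrix must carry the
  shared per-gene structure of real transcriptomes for the root cut to be
  meaningful. The synthetic expression used in the tests therefore draws a
  shared per-gene baseline (sd 2 against unit noise) and a signed
  per-gene signature pattern.
* The min-hypergeometric statistic is highly discrete, and under a true
  null the root cut of exchangeable samples is often very unbalanced, so
  the permutation p has large atoms (much of its mass at 1). It is valid
  but conservative — its null distribution is far from uniform, which any
  user comparing it against a nominal level should know.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions under which the pipeline's properties are asserted. Defaults
(all overridable in `cohort_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 55 | cohort size of the emulated whole-genome study |
| `p_high` | 0.2 | high-instability class is the less frequent one |
| `intra_rate_low/high` | 20 / 200 | order-of-magnitude burden separation between classes |
| `inter_rate` | 15 | interchromosomal burden is class-independent |
| `dispersion` | 10 | negative-binomial size; tumor counts are overdispersed, Poisson would be too tight |
| `driver_or` | 20 | strong enrichment of the driver lesion in the unstable class |
| `driver_prob_low` | 0.1 | baseline driver frequency; an odds ratio needs a baseline, cohort-level driver frequency ≈ 10% |
| `driver_ccf` | 1.0 | the driver is clonal |
| deletion lesions | 2 × 2 Mb regions | recurrent cytoband-deletion analogs, enriched in the unstable class, CCF ∈ [0.3, 0.8] (subclonal) |
| `fga_beta_low/high` | Beta(2,38) / Beta(5,15) | class FGA centred at 0.05 vs 0.25 |
| `depth` | 100 | typical whole-genome sequencing depth for clonality work |
| `purity_range` | [0.4, 0.9] | realistic primary-tumor purity |

The planted clonal hierarchy constrains each deletion's CCF below the
driver's in samples carrying both, realizing "driver first". Planted
deletion segments encode purity and clonality exactly through
$\log_2((2 - p c)/2)$, so the segment channel carries no additional noise
— deviations between read-count and segment clonality in the agreement
tests come from the read-count side only. Read counts are
Poisson-depth/binomial draws from the expected-VAF formula; depth is
floored at one read so every observation is usable.

What the generator does **not** emulate: breakpoint clustering or complex
events (chromoplexy/chromothripsis), mutational signatures, allele-specific
copy number, whole-genome doubling, purity estimation error, segmentation
noise, and read-level artifacts. Passing tests therefore demonstrate that
the estimators and tests are correct under their own model assumptions —
not that those assumptions absorb every pathology of real data.

## Problem sizes and replicate counts

Mixture recovery is asserted on one 400-tumor cohort (rates 20 vs 200,
where component means should land within 0.1 of log10(21) and log10(201)).
Association properties run on 100 replicate cohorts at the default size of
55. Timing analyses simulate 300 tumors so that driver–deletion
co-occurrence comfortably exceeds the 10-sample floor the precedence test
needs; 50 replicate cohorts are used. Null calibrations use 2000
rank-sum replicates and 1000 clustering datasets (199 permutations each);
the signature-detection property uses 200 replicates of a 200-gene
signature shifted 1 SD in 10 of 64 samples. These sizes were chosen as the
smallest at which the asserted properties are stable, and they are stated
here so that a reader can reproduce the same conditions.

## Known limitations

* Purity is trusted as given; biased purity biases every CCF linearly.
* The deletion model is mono-allelic; bi-allelic events are only flagged.
* No subclonal deconvolution: CCFs are per-lesion point estimates, not
  clone trees, and the evolution graph orders lesions, not clones.
* BH control is per burden channel; results across channels are not
  jointly corrected.
* The segregation p-value is conservative (see above); treat it as an
  upper bound on significance.
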