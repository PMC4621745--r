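Package: gicohort
Title: Cohort Analysis of Structural Rearrangement Burden, Copy-Number
    Instability, and Lesion Clonality in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-level genomic-instability analysis of tumor
    genomes: classification of paired-breakpoint structural rearrangements
    (deletion, tandem duplication, inversion, interchromosomal) and
    per-sample burden counting; two-component Gaussian mixture decomposition
    of rearrangement burden into low- and high-instability subpopulations;
    fraction of genome altered from copy-number segments with rank-sum
    burden comparison; rank-sum association of recurrent lesions with
    rearrangement burden under Benjamini-Hochberg control and one-tail
    Fisher mutual-exclusivity testing; purity- and copy-number-corrected
    cancer cell fraction (clonality) estimation from allele read counts and
    from segment log-ratios; lesion precedence testing and assembly of
    acyclic tumor-evolution graphs; hierarchical clustering on a signature
    gene set with a permutation-calibrated segregation statistic; and a
    seeded synthetic tumor-cohort generator with planted instability
    classes, driver enrichment, and clonal hierarchy so the whole pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
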