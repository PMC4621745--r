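# End-to-end orchestration from a single YAML configuration: load or
# simulate a cohort, classify and count rearrangements, decompose burden,
# compute FGA, run lesion associations and exclusivity, estimate clonality,
# assemble the evolution graph, and (when expression data is supplied)
# quantify signature segregation. Every output table carries a metadata
# block so identical config + seed reruns are byte-identical.

#' Read a pipeline run configuration from YAML
#'
#' The file must contain exactly one of an `inputs:` section (paths to
#' BEDPE/SEG/TSV files) or a `synthetic:` section ([cohort_config()] fields).
#' Optional sections: `thresholds` (`log2_alteration`, `log2_deletion`,
#' `delta`, `alpha`, `min_recurrence`, `min_cooccurrence`), `bin_edges`,
#' `group_label`, `output_dir`, `seed`.
#'
#' @param path YAML file.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Validate and normalize a run configuration
#' @param cfg a list as produced by [read_run_config()] or built in code.
#' @return config list of class `run_config` with defaults filled in.
#' @export
as_run_config <- function(cfg) {
  has_inputs <- !is.null(cfg$inputs)
  has_synth <- !is.null(cfg$synthetic)
  if (has_inputs == has_synth) {
    stop("config must contain exactly one of 'inputs' or 'synthetic'", call. = FALSE)
  }
  th <- cfg$thresholds
  defaults <- list(log2_alteration = 0.2, log2_deletion = 0.2, delta = 0.1,
                   alpha = 0.05, min_recurrence = 3L, min_cooccurrence = 3L)
  for (nm in names(defaults)) if (is.null(th[[nm]])) th[[nm]] <- defaults[[nm]]
  if (th$log2_alteration <= 0 || th$log2_deletion <= 0) {
    stop("log2 thresholds must be positive", call. = FALSE)
  }
  if (th$delta < 0 || th$delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  if (th$alpha <= 0 || th$alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  cfg$thresholds <- th
  if (is.null(cfg$bin_edges)) cfg$bin_edges <- DEFAULT_FGA_EDGES
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$group_label)) cfg$group_label <- "driver_status"
  if (is.null(cfg$output_dir)) cfg$output_dir <- "gicohort_output"
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

load_cohort_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    sc_args <- cfg$synthetic
    if (is.null(sc_args$seed)) sc_args$seed <- cfg$seed
    if (!is.null(sc_args$deletion_lesions)) {
      sc_args$deletion_lesions <-
        do.call(rbind, lapply(sc_args$deletion_lesions, as.data.frame))
    }
    scfg <- do.call(cohort_config, sc_args)
    genome <- if (!is.null(cfg$genome)) read_genome_tsv(cfg$genome) else default_genome()
    cohort <- simulate_cohort(scfg, genome)
    list(genome = genome, data = cohort$data,
         regions = deletion_regions(scfg), truth = cohort$truth,
         expression = NULL, signature = NULL)
  } else {
    inp <- cfg$inputs
    genome <- read_genome_tsv(inp$genome)
    sheet <- read_sample_sheet(inp$sample_sheet)
    data <- list(
      rearrangements = read_rearrangements(inp$rearrangements, genome),
      segments = read_segments(inp$segments, genome),
      mutations = read_mutations(inp$mutations, sheet),
      sample_sheet = sheet)
    regions <- if (!is.null(inp$regions)) read_regions_bed(inp$regions, genome)
    expression <- if (!is.null(inp$expression)) read_expression_tsv(inp$expression)
    signature <- if (!is.null(inp$signature)) {
      sets <- read_gmt(inp$signature)
      sets[[1]]
    }
    list(genome = genome, data = data, regions = regions, truth = NULL,
         expression = expression, signature = signature)
  }
}

#' Run the full genomic-instability pipeline
#'
#' Stages, in order: load or simulate the cohort; classify rearrangements
#' and count burden per sample; fit the two-component burden mixture and
#' assign subpopulations; compute fraction of genome altered and compare it
#' between the two groups given by `group_label` (a sample-sheet column;
#' falls back to the mixture subpopulations); build the lesion matrix and
#' run burden associations per channel with BH q-values; pairwise mutual
#' exclusivity; clonality estimation for point lesions (read counts) and
#' deletion lesions (segment log-ratios); evolution-graph assembly; and, if
#' expression plus a signature are configured, segregation testing. All
#' tables are written under `output_dir` with a shared metadata block.
#'
#' @param config a `run_config` (see [read_run_config()] / [as_run_config()]).
#' @param out_dir overrides `config$output_dir` when given.
#' @return invisible list: `manifest` (file, n_rows), `tables`, plus the
#'   fitted `mixture`, `comparison`, `graph`, and `segregation` objects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$output_dir
  th <- config$thresholds

  loaded <- load_cohort_inputs(config)
  data <- loaded$data
  genome <- loaded$genome
  sheet <- data$sample_sheet

  events <- classify_events(data$rearrangements)
  burden <- count_by_sample(events, sheet)

  fit <- fit_two_component_mixture(stats::setNames(burden$n_total, burden$sample_id))
  subpop <- assign_subpopulation(fit)
  mixture_tbl <- data.frame(
    component = c("low", "high"), mean_log10 = unname(fit$mean),
    sd_log10 = unname(fit$sd), weight = unname(fit$weight),
    delta_bic = fit$delta_bic,
    one_component_preferred = fit$one_component_preferred)
  subpop_tbl <- data.frame(sample_id = burden$sample_id,
                           subpopulation = unname(subpop[burden$sample_id]),
                           resp_high = unname(fit$responsibility[burden$sample_id, "high"]))

  set.seed(config$seed + 1L)
  fga <- fga_by_sample(data$segments, genome, sample_ids = sheet$sample_id,
                       log2_threshold = th$log2_alteration)
  groups <- if (config$group_label %in% names(sheet)) {
    sheet[[config$group_label]]
  } else {
    unname(subpop[sheet$sample_id])
  }
  comparison <- if (length(unique(groups)) == 2L) {
    compare_burden(fga, groups, edges = config$bin_edges)
  }
  fga_tbl <- data.frame(sample_id = sheet$sample_id, fga = unname(fga),
                        group = groups)
  hist_tbl <- bin_fga(fga, edges = config$bin_edges, groups = groups)
  comp_tbl <- if (!is.null(comparison)) {
    data.frame(group = comparison$groups, n = comparison$n,
               median_fga = comparison$median, W = comparison$W,
               p_one_sided = comparison$p_one, p_two_sided = comparison$p_two,
               method = comparison$method)
  } else {
    data.frame(group = character(), n = integer(), median_fga = numeric(),
               W = numeric(), p_one_sided = numeric(), p_two_sided = numeric(),
               method = character())
  }

  lm <- build_lesion_matrix(data$mutations, data$segments, sheet$sample_id,
                            regions = loaded$regions, genome = genome,
                            log2_del_threshold = th$log2_deletion,
                            min_recurrence = th$min_recurrence)
  assoc_tbl <- if (ncol(lm) > 0) {
    rank_associations(associate_all(lm, burden))
  } else {
    data.frame(lesion = character(), kind = character(), channel = character(),
               p_value = numeric(), q_value = numeric())
  }
  excl_tbl <- exclusivity_all(lm)

  kind <- attr(lm, "lesion_kind")
  est_list <- list()
  if (nrow(data$mutations) > 0) est_list$snv <- estimate_ccf(data$mutations)
  if (!is.null(loaded$regions) && nrow(loaded$regions) > 0) {
    del_lesions <- intersect(names(kind)[kind == "deletion"], colnames(lm))
    for (nm in del_lesions) {
      reg <- loaded$regions[loaded$regions$name == nm, ]
      for (s in sheet$sample_id[lm[, nm] == 1L]) {
        seg_s <- data$segments[data$segments$sample_id == s, , drop = FALSE]
        est_list[[paste(nm, s)]] <- deletion_clonality(
          seg_s, reg, sheet$purity[sheet$sample_id == s],
          sample_id = s, lesion = nm)[, 1:7]
      }
    }
  }
  clonality_tbl <- if (length(est_list)) {
    do.call(rbind, c(lapply(est_list, function(d) d[, c("sample_id", "lesion", "ccf",
                                                        "ci_low", "ci_high", "method")]),
                     make.row.names = FALSE))
  } else {
    data.frame(sample_id = character(), lesion = character(), ccf = numeric(),
               ci_low = numeric(), ci_high = numeric(), method = character())
  }
  keep_lesions <- colnames(lm)
  graph_est <- clonality_tbl[clonality_tbl$lesion %in% keep_lesions, , drop = FALSE]
  graph <- build_evolution_graph(graph_est, delta = th$delta, alpha = th$alpha,
                                 min_cooccurrence = th$min_cooccurrence)

  segregation <- NULL
  segregation_status <- "skipped (no expression/signature configured)"
  if (!is.null(loaded$expression) && !is.null(loaded$signature)) {
    hc <- cluster_samples(loaded$expression, loaded$signature)
    cl <- cut_two(hc)
    lab <- sheet[[config$group_label]][match(names(cl), sheet$sample_id)]
    segregation <- segregation_pvalue(cl, lab == sort(unique(lab))[1],
                                      n_permutations = 10000L,
                                      seed = config$seed + 2L)
    segregation_status <- "run"
  }
  seg_tbl <- if (!is.null(segregation)) {
    data.frame(cluster = 1:2, size = segregation$cluster_sizes,
               labeled = segregation$labeled_per_cluster,
               observed_min_hyper_p = segregation$observed,
               permutation_p = segregation$p_value,
               n_permutations = segregation$n_permutations)
  } else {
    data.frame(status = segregation_status)
  }

  meta <- list(tool = paste0("gicohort ", utils::packageVersion("gicohort")),
               config_hash = config_hash(config), seed = config$seed)
  tables <- list(burden = burden, mixture = mixture_tbl,
                 subpopulations = subpop_tbl, fga = fga_tbl,
                 fga_histogram = hist_tbl, burden_comparison = comp_tbl,
                 associations = assoc_tbl, exclusivity = excl_tbl,
                 clonality = clonality_tbl, evolution_edges = graph$edges,
                 segregation = seg_tbl)
  if (!is.null(loaded$truth)) tables$truth <- loaded$truth
  manifest <- write_results(tables, out_dir, metadata = meta)
  writeLines(evolution_graph_dot(graph), file.path(out_dir, "evolution_graph.dot"))
  manifest <- rbind(manifest,
                    data.frame(file = "evolution_graph.dot",
                               n_rows = nrow(graph$edges)))
  write_tsv_with_meta(manifest, file.path(out_dir, "manifest.tsv"), meta)

  invisible(list(manifest = manifest, tables = tables, mixture = fit,
                 comparison = comparison, lesion_matrix = lm, graph = graph,
                 segregation = segregation))
}
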