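#' Configuration for the full synthetic analysis pipeline
#'
#' Combines the synthetic-data settings with every analysis parameter.
#' Analysis defaults are the standard ones for this kind of study:
#' 100 bp windows, DMR seed threshold p < 1e-6 with extension at
#' p < 0.1 within 1000 bp, differential expression at p < 0.001, gene
#' association within 10 kb, FDR reporting threshold 0.1, disease
#' cutoffs at mean + 2 SD with 2-of-3 observer consensus.
#'
#' @param simulation A [simulation_config()].
#' @param seed_p DMR seed p-value threshold.
#' @param extend_p,extend_dist_bp DMR edge-extension rule.
#' @param de_p Transcript differential-expression threshold.
#' @param gene_max_dist_bp Gene association distance.
#' @param fdr_threshold FDR threshold used in report summaries.
#' @param sd_multiplier,min_observers Pathology cutoff and consensus
#'   parameters.
#' @param thresholds Seed thresholds for the DMR threshold table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            seed_p = 1e-6,
                            extend_p = 0.1,
                            extend_dist_bp = 1000,
                            de_p = 0.001,
                            gene_max_dist_bp = 10000,
                            fdr_threshold = 0.1,
                            sd_multiplier = 2,
                            min_observers = 2L,
                            thresholds = 10^-(2:8)) {
  stopifnot(inherits(simulation, "simulation_config"))
  check_scalar(seed_p, "seed_p", lower = 0, upper = 1)
  check_scalar(extend_p, "extend_p", lower = 0, upper = 1)
  check_scalar(extend_dist_bp, "extend_dist_bp", lower = 0)
  check_scalar(de_p, "de_p", lower = 0, upper = 1)
  check_scalar(gene_max_dist_bp, "gene_max_dist_bp", lower = 0)
  check_scalar(fdr_threshold, "fdr_threshold", lower = 0, upper = 1)
  check_scalar(sd_multiplier, "sd_multiplier", lower = 0)
  check_scalar(min_observers, "min_observers", lower = 1,
               integer = TRUE)
  structure(list(simulation = simulation, seed_p = seed_p,
                 extend_p = extend_p, extend_dist_bp = extend_dist_bp,
                 de_p = de_p, gene_max_dist_bp = gene_max_dist_bp,
                 fdr_threshold = fdr_threshold,
                 sd_multiplier = sd_multiplier,
                 min_observers = as.integer(min_observers),
                 thresholds = thresholds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; keys under
#' `simulation`, `de` and `pathology` override [simulation_config()],
#' [de_config()] and [pathology_config()] arguments respectively.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the yaml package.")
  }
  y <- yaml::read_yaml(path)
  dc <- do.call(de_config, y$de %||% list())
  pc <- do.call(pathology_config, y$pathology %||% list())
  sim_args <- y$simulation %||% list()
  sim_args$de_config <- dc
  sim_args$pathology_config <- pc
  if (!is.null(seed)) sim_args$seed <- seed
  sim <- do.call(simulation_config, sim_args)
  top <- y[setdiff(names(y), c("simulation", "de", "pathology"))]
  do.call(pipeline_config, c(list(simulation = sim), top))
}

#' Run the full synthetic analysis end to end
#'
#' Simulates the genome, the MeDIP experiment, transcript counts, gene
#' models and pathology scores; then runs window testing, DMR calling
#' (threshold table, feature summaries, clusters), differential
#' expression with class tallies, gene association and category/pathway
#' tallies, DMR-by-transcript interval overlap, and the pathology
#' comparison. Because the inputs carry ground truth, a recovery
#' scorecard (sensitivity and precision against planted DMRs and
#' planted DE) is attached.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is
#'   written as TSV/BED (with provenance headers) plus a JSON summary
#'   and a plain-text run log.
#' @return A list of class `pipeline_result` with elements
#'   `window_results`, `dmrs`, `threshold_table`, `dmr_features`,
#'   `clusters`, `de`, `gene_associations`, `category_counts`,
#'   `pathway_counts`, `venn_dmr_de`, `pathology`, `scorecard`,
#'   `truth`, `config`.
#' @export
run_full_analysis <- function(config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  sim_cfg <- config$simulation
  say("simulate: genome (%d chromosome(s) x %d bp, seed %d)",
      sim_cfg$n_chromosomes, sim_cfg$chrom_length_bp, sim_cfg$seed)
  genome <- simulate_genome(sim_cfg)
  say("simulate: MeDIP experiment (%d planted regions)",
      sim_cfg$n_planted_dmrs)
  medip <- simulate_medip_experiment(sim_cfg, genome)
  rna <- simulate_transcript_counts(sim_cfg, genome)
  genes <- simulate_gene_models(sim_cfg, genome)
  path_sim <- simulate_pathology_scores(sim_cfg)

  say("test: differential coverage over %d windows",
      nrow(medip$counts$counts))
  window_results <- test_windows(medip$counts, medip$groups)
  say("dmrs: calling at seed p < %g", config$seed_p)
  dmrs <- call_dmrs(window_results, seed_p = config$seed_p,
                    extend_p = config$extend_p,
                    extend_dist_bp = config$extend_dist_bp)
  threshold_table <- dmr_threshold_table(
    window_results, thresholds = config$thresholds,
    extend_p = config$extend_p,
    extend_dist_bp = config$extend_dist_bp)
  features <- summarize_dmr_features(dmrs)
  clusters <- cluster_dmrs(dmrs)
  say("dmrs: %d called (%d multiple-window)", nrow(dmrs),
      sum(dmrs$is_multiple_window))

  say("de: testing %d transcripts at p < %g", nrow(rna$transcripts),
      config$de_p)
  de <- differential_expression(rna$transcripts, rna$groups,
                                p_threshold = config$de_p)

  assoc <- associate_genes(dmrs, genes$genes,
                           max_dist_bp = config$gene_max_dist_bp)
  assoc_genes <- unique(assoc$gene_id)
  category_counts <- map_counts(assoc_genes, genes$category_map)
  pathway_counts <- map_counts(assoc_genes, genes$pathway_map)
  venn_dmr_de <- venn_intervals(
    dmrs, de$de[!is.na(de$de$chrom), c("chrom", "start", "end")])

  say("pathology: %d animals, %d observers",
      length(unique(path_sim$records$animal_id)),
      length(unique(path_sim$records$observer)))
  pathology <- compare_lineages(path_sim$records,
                                sd_multiplier = config$sd_multiplier,
                                min_observers = config$min_observers)

  scorecard <- bind_cols(
    score_dmr_recovery(dmrs, medip$truth),
    score_de_recovery(de, rna$truth))
  say("scorecard: DMR sensitivity %.3f, precision %.3f; DE sensitivity %.3f",
      scorecard$dmr_sensitivity, scorecard$dmr_precision,
      scorecard$de_sensitivity)

  result <- structure(list(
    window_results = window_results, dmrs = dmrs,
    threshold_table = threshold_table, dmr_features = features,
    clusters = clusters, de = de, gene_associations = assoc,
    category_counts = category_counts, pathway_counts = pathway_counts,
    venn_dmr_de = venn_dmr_de, pathology = pathology,
    scorecard = scorecard,
    truth = list(dmrs = medip$truth, de = rna$truth,
                 pathology = path_sim$truth),
    config = config, log = log_lines
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Score called DMRs against planted truth
#'
#' Sensitivity is the fraction of planted regions overlapped (>= 1 bp)
#' by a called DMR; precision is the fraction of called DMRs that
#' overlap a planted region; the multiple-window fraction is computed
#' over called DMRs.
#'
#' @param dmrs A `dmr_set`.
#' @param truth_dmrs Tibble of planted regions (`chrom`, `start`,
#'   `end`, `direction`).
#' @return One-row tibble: `dmr_sensitivity`, `dmr_precision`,
#'   `dmr_multiple_window_fraction`, `n_dmrs_called`, `n_dmrs_planted`,
#'   `dmr_direction_agreement`.
#' @export
score_dmr_recovery <- function(dmrs, truth_dmrs) {
  if (nrow(truth_dmrs) == 0L || nrow(dmrs) == 0L) {
    return(tibble(dmr_sensitivity = NA_real_,
                  dmr_precision = NA_real_,
                  dmr_multiple_window_fraction = NA_real_,
                  n_dmrs_called = nrow(dmrs),
                  n_dmrs_planted = nrow(truth_dmrs),
                  dmr_direction_agreement = NA_real_))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(granges_from_df(dmrs),
                                granges_from_df(truth_dmrs)))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  sens <- length(unique(si)) / nrow(truth_dmrs)
  prec <- length(unique(qi)) / nrow(dmrs)
  dir_called <- dmrs$direction[qi]
  dir_truth <- truth_dmrs$direction[si]
  tibble(dmr_sensitivity = sens, dmr_precision = prec,
         dmr_multiple_window_fraction = mean(dmrs$is_multiple_window),
         n_dmrs_called = nrow(dmrs),
         n_dmrs_planted = nrow(truth_dmrs),
         dmr_direction_agreement = if (length(qi)) {
           mean(dir_called == dir_truth)
         } else {
           NA_real_
         })
}

#' Score differential-expression calls against planted truth
#'
#' @param de A `de_result`.
#' @param truth_de Tibble of planted transcripts (`id`, `direction`).
#' @return One-row tibble: `de_sensitivity`,
#'   `de_false_positive_rate` (fraction of null transcripts called),
#'   `n_de_called`, `n_de_planted`.
#' @export
score_de_recovery <- function(de, truth_de) {
  called <- de$de$id
  tested <- de$table$id
  planted <- intersect(truth_de$id, tested)
  nulls <- setdiff(tested, truth_de$id)
  tibble(
    de_sensitivity = if (length(planted)) {
      mean(planted %in% called)
    } else {
      NA_real_
    },
    de_false_positive_rate = if (length(nulls)) {
      mean(nulls %in% called)
    } else {
      NA_real_
    },
    n_de_called = length(called),
    n_de_planted = nrow(truth_de))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$scorecard)
  invisible(x)
}

#' @rdname glance-dmrkit
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) x$scorecard

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- result$config$simulation$seed
  w <- function(df, name) {
    write_tsv_provenance(df, file.path(out_dir, name), seed = seed)
  }
  w(result$window_results, "window_results.tsv")
  write_dmr_tables(result$dmrs,
                   bed_path = file.path(out_dir, "dmrs.bed"),
                   tsv_path = file.path(out_dir, "dmrs.tsv"),
                   seed = seed)
  w(result$threshold_table, "dmr_threshold_table.tsv")
  w(result$dmr_features$cpg_density, "dmr_cpg_density_histogram.tsv")
  w(result$dmr_features$length, "dmr_length_histogram.tsv")
  w(result$dmr_features$chromosome, "dmr_per_chromosome.tsv")
  w(result$clusters, "dmr_clusters.tsv")
  w(result$de$table, "de_results.tsv")
  w(result$de$class_tally, "de_class_tally.tsv")
  w(result$de$subclass_tally, "de_subclass_tally.tsv")
  w(result$gene_associations, "dmr_gene_associations.tsv")
  w(result$category_counts, "gene_category_counts.tsv")
  w(result$pathway_counts, "gene_pathway_counts.tsv")
  w(result$venn_dmr_de, "venn_dmr_de.tsv")
  w(result$pathology$consensus, "pathology_calls.tsv")
  summary <- list(
    scorecard = as.list(result$scorecard),
    pathology = list(
      frequencies = result$pathology$frequencies,
      fisher_p = result$pathology$fisher_p),
    seed = seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
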