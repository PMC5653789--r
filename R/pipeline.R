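#' Write a synthetic study bundle to disk
#'
#' Materializes every file the pipeline consumes: the two expression
#' matrices with group maps, the compendium GMT, the annotation TSV, a
#' truth JSON, and a synthetic Ct table.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param ct_cfg A [ct_sim_config()] for the bundled Ct table; `NULL`
#'   skips it.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_bundle <- function(cfg, dir, ct_cfg = ct_sim_config(seed = cfg$seed),
                            force = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_two_tissue_study(cfg)
  p <- function(f) file.path(dir, f)
  paths <- list(tissue1 = p("tissue1_expression.tsv"),
                tissue1_groups = p("tissue1_groups.tsv"),
                tissue2 = p("tissue2_expression.tsv"),
                tissue2_groups = p("tissue2_groups.tsv"),
                compendium = p("compendium.gmt"),
                annotation = p("annotation.tsv"),
                truth = p("truth.json"))
  write_expression(study$tissue1, paths$tissue1, paths$tissue1_groups)
  write_expression(study$tissue2, paths$tissue2, paths$tissue2_groups)
  write_gmt(study$compendium, paths$compendium)
  write_annotation(study$annotation, paths$annotation)
  jsonlite::write_json(study$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  if (!is.null(ct_cfg)) {
    paths$ct <- p("ct_table.tsv")
    write_ct(generate_ct_experiment(ct_cfg), paths$ct)
  }
  invisible(paths)
}

#' Assemble a pipeline configuration
#'
#' @param tissue1,tissue1_groups,tissue2,tissue2_groups Paths to the two
#'   expression matrices and their group maps.
#' @param compendium Path to the signature GMT.
#' @param annotation Path to the gene-to-term TSV.
#' @param ct Optional path to a tidy Ct table.
#' @param fc_threshold,fdr_threshold DEG thresholds (defaults 2, 0.05).
#' @param term_p_threshold Raw p threshold for term enrichment (0.001).
#' @param treatment_q_threshold FDR threshold for reporting significant
#'   treatments (0.05).
#' @param reference_gene,target_gene Ct-table genes for the synergy stage.
#' @param ct_conditions Named list with `a`, `b`, `combo`, `control`
#'   condition labels for the synergy stage.
#' @param seed Seed echoed into the report (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tissue1, tissue1_groups, tissue2,
                            tissue2_groups, compendium, annotation,
                            ct = NULL, fc_threshold = 2,
                            fdr_threshold = 0.05,
                            term_p_threshold = 0.001,
                            treatment_q_threshold = 0.05,
                            reference_gene = "RPLP0",
                            target_gene = "CXCL10",
                            ct_conditions = list(a = "A", b = "B",
                                                 combo = "A+B",
                                                 control = "control"),
                            seed = 1L) {
  cfg <- list(tissue1 = tissue1, tissue1_groups = tissue1_groups,
              tissue2 = tissue2, tissue2_groups = tissue2_groups,
              compendium = compendium, annotation = annotation, ct = ct,
              fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
              term_p_threshold = term_p_threshold,
              treatment_q_threshold = treatment_q_threshold,
              reference_gene = reference_gene, target_gene = target_gene,
              ct_conditions = ct_conditions, seed = as.integer(seed))
  required <- c("tissue1", "tissue1_groups", "tissue2", "tissue2_groups",
                "compendium", "annotation")
  for (f in required)
    if (!file.exists(cfg[[f]])) stop("input file missing: ", cfg[[f]])
  if (!is.null(cfg$ct) && !file.exists(cfg$ct))
    stop("input file missing: ", cfg$ct)
  if (cfg$fc_threshold <= 0 || cfg$fdr_threshold <= 0 ||
      cfg$fdr_threshold > 1 || cfg$term_p_threshold <= 0 ||
      cfg$term_p_threshold > 1)
    stop("thresholds out of range")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full concordance pipeline on a study bundle
#'
#' Executes differential expression on both tissues, directional DEG
#' overlap, term enrichment and treatment attribution on the shared
#' up-regulated genes, and (when a Ct table is configured) ddCt
#' quantification with Bliss synergy scoring. Every intermediate count
#' that determines a p-value — above all the intersection universe size —
#' is logged to stderr and recorded in the report, which is a pure
#' function of the inputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for the JSON report and per-stage
#'   TSVs; `NULL` returns the report without writing.
#' @return The pipeline report (nested list), invisibly written to
#'   `out_dir/report.json` when requested.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message("[concordia] ", ...)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_tsv <- function(write_fn, obj, file) {
    if (!is.null(out_dir)) write_fn(obj, file.path(out_dir, file))
  }

  log_msg("stage deg: tissue 1")
  t1 <- read_expression(config$tissue1, config$tissue1_groups)
  c1 <- welch_contrast(t1)
  d1 <- call_degs(c1, config$fc_threshold, config$fdr_threshold)
  save_tsv(write_contrast, c1, "tissue1_contrast.tsv")
  log_msg("stage deg: tissue 2")
  t2 <- read_expression(config$tissue2, config$tissue2_groups)
  c2 <- welch_contrast(t2)
  d2 <- call_degs(c2, config$fc_threshold, config$fdr_threshold)
  save_tsv(write_contrast, c2, "tissue2_contrast.tsv")
  log_msg("DEG counts: tissue1 up/down = ", length(d1$up), "/",
          length(d1$down), "; tissue2 up/down = ", length(d2$up), "/",
          length(d2$down))

  report <- list(
    config = unclass(config),
    seed = config$seed,
    differential = list(
      tissue1 = list(n_genes = length(d1$universe),
                     n_up = length(d1$up), n_down = length(d1$down)),
      tissue2 = list(n_genes = length(d2$universe),
                     n_up = length(d2$up), n_down = length(d2$down))))

  log_msg("stage concord")
  ov <- directional_overlap(d1, d2)
  log_msg("intersection universe = ", ov$n_universe,
          " genes (the hidden determinant of every overlap p-value)")
  report$concordance <- list(n_universe = ov$n_universe,
                             up = ov$up, down = ov$down,
                             n_shared_up = length(ov$shared_up),
                             n_shared_down = length(ov$shared_down))
  if (!is.null(out_dir))
    write_gmt(signature_compendium(list(
      shared = list(induced = sort(ov$shared_up),
                    repressed = sort(ov$shared_down)))),
      file.path(out_dir, "shared_sets.gmt"))

  universe <- intersect(d1$universe, d2$universe)
  if (length(ov$shared_up)) {
    log_msg("stage enrich: ", length(ov$shared_up), " shared up genes")
    ann <- read_annotation(config$annotation)
    terms <- enrich_terms(ov$shared_up, universe, ann,
                          p_threshold = config$term_p_threshold)
    report$term_enrichment <- list(
      n_terms_tested = nrow(terms),
      n_enriched = sum(terms$enriched),
      top_terms = utils::head(terms, 10L))
    if (!is.null(out_dir))
      utils::write.table(terms, file.path(out_dir, "term_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    log_msg("stage attribute")
    compendium <- read_gmt(config$compendium)
    ranked <- attribute_signatures(ov$shared_up, universe, compendium)
    report$attribution <- list(
      n_treatments = nrow(ranked),
      n_significant = sum(ranked$q_value < config$treatment_q_threshold),
      ranking = ranked)
    if (!is.null(out_dir))
      utils::write.table(ranked, file.path(out_dir, "attribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    log_msg("shared up-set empty; enrichment and attribution skipped")
    report$term_enrichment <- list(skipped = "empty shared up-regulated set")
    report$attribution <- list(skipped = "empty shared up-regulated set")
  }

  log_msg("stage correlate")
  p1 <- fold_change_profile(t1, "tissue1")
  p2 <- fold_change_profile(t2, "tissue2")
  sp <- spearman_correlation(p1, p2)
  report$response_correlation <- list(rho = sp$rho, n_genes = sp$n_genes,
                                      p_value = sp$p_value)

  if (!is.null(config$ct)) {
    log_msg("stage synergy")
    ct <- read_ct(config$ct, config$reference_gene)
    cc <- config$ct_conditions
    syn <- ct_synergy(ct, config$target_gene, config$reference_gene,
                      cc$a, cc$b, cc$combo, cc$control)
    report$synergy <- list(fold_a = syn$fold_a, fold_b = syn$fold_b,
                           fold_combo = syn$fold_combo,
                           model = syn$model, expected = syn$expected,
                           index = syn$index,
                           classification = syn$classification)
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
  invisible(report)
}
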