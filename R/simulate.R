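#' Simulation configuration for the two-tissue study generator
#'
#' Defines the conditions of the synthetic cross-disease study: a
#' 42-treatment stimulation compendium with a small number of planted
#' driver treatments whose signature genes receive a shared log2 effect
#' in the case group of both tissues, a background rate of tissue-private
#' effects, and gene-wise independent Gaussian noise on the log2 scale
#' around a log-normal baseline.
#'
#' Defaults mirror the intended use: 2000 genes, 42 treatments, 2
#' drivers, 100-gene signatures split 70% induced / 30% repressed, a
#' shared effect of log2(3) (threefold), residual sd 0.5 on the log2
#' scale, and group sizes of 13 (tissue 1) and 16 (tissue 2) per group —
#' the scale of the carotid-plaque cohorts (13 early, 16 advanced) this
#' design emulates.
#'
#' @param n_genes Genes in the universe.
#' @param n_treatments Treatments in the compendium (default 42).
#' @param n_driver_treatments Planted drivers (first treatments, by
#'   convention named starting "IFN-g", "TNF-a").
#' @param module_size Genes per treatment signature (induced + repressed).
#' @param induced_fraction Fraction of each signature that is induced.
#' @param shared_effect_lfc Planted log2 fold-change magnitude.
#' @param noise_sd Residual sd, log2 scale (> 0).
#' @param n_samples_per_group_tissue1,n_samples_per_group_tissue2 Samples
#'   per group in each tissue.
#' @param background_de_rate Fraction of non-planted genes given
#'   tissue-private effects, in [0, 1).
#' @param disjoint Force treatment signatures to be disjoint (default
#'   FALSE: signatures are sampled independently and may overlap, as real
#'   cytokine signatures do).
#' @param baseline_mean,baseline_sd Log2-scale baseline distribution.
#' @param seed Integer seed; expanded into per-component substreams.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_treatments = 42,
                       n_driver_treatments = 2, module_size = 100,
                       induced_fraction = 0.7,
                       shared_effect_lfc = log2(3), noise_sd = 0.5,
                       n_samples_per_group_tissue1 = 13,
                       n_samples_per_group_tissue2 = 16,
                       background_de_rate = 0.05,
                       disjoint = FALSE,
                       baseline_mean = 7, baseline_sd = 2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_treatments = as.integer(n_treatments),
              n_driver_treatments = as.integer(n_driver_treatments),
              module_size = as.integer(module_size),
              induced_fraction = induced_fraction,
              shared_effect_lfc = shared_effect_lfc,
              noise_sd = noise_sd,
              n_samples_per_group_tissue1 =
                as.integer(n_samples_per_group_tissue1),
              n_samples_per_group_tissue2 =
                as.integer(n_samples_per_group_tissue2),
              background_de_rate = background_de_rate,
              disjoint = isTRUE(disjoint),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  counts <- cfg[c("n_genes", "n_treatments", "n_driver_treatments",
                  "module_size", "n_samples_per_group_tissue1",
                  "n_samples_per_group_tissue2")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, logical(1))))
    stop("all counts must be >= 1")
  if (cfg$module_size > cfg$n_genes)
    stop("module_size cannot exceed n_genes")
  if (cfg$disjoint && cfg$module_size * cfg$n_treatments > cfg$n_genes)
    stop("disjoint signatures need module_size * n_treatments <= n_genes")
  if (cfg$n_driver_treatments > cfg$n_treatments)
    stop("n_driver_treatments cannot exceed n_treatments")
  if (!(cfg$noise_sd > 0)) stop("noise_sd must be > 0")
  if (cfg$background_de_rate < 0 || cfg$background_de_rate >= 1)
    stop("background_de_rate must lie in [0, 1)")
  if (cfg$induced_fraction <= 0 || cfg$induced_fraction >= 1)
    stop("induced_fraction must lie in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# derive independent per-component substream seeds from the master seed,
# so each generator stage is reproducible on its own
substream_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

default_treatment_names <- function(n) {
  base <- c("IFN-g", "TNF-a", "IL-17A", "IL-22", "IL-19", "IL-20",
            "IL-24", "IL-1b", "IL-36g", "OSM")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("trt%02d", seq.int(length(base) + 1L, n)))
}

#' Generate a synthetic stimulation-signature compendium
#'
#' Draws, for each treatment, `module_size` signature genes without
#' replacement from the gene universe and splits them into induced and
#' repressed sets. By default signatures are sampled independently per
#' treatment and may overlap across treatments; `disjoint = TRUE`
#' partitions the universe instead.
#'
#' @param cfg A [sim_config()].
#' @param treatment_names Optional treatment names (length
#'   `n_treatments`); defaults to cytokine-style names starting
#'   "IFN-g", "TNF-a".
#' @return A [signature_compendium()]. Deterministic given `cfg$seed`.
#' @export
generate_compendium <- function(cfg,
                                treatment_names =
                                  default_treatment_names(cfg$n_treatments)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(treatment_names) != cfg$n_treatments ||
      anyDuplicated(treatment_names))
    stop("treatment_names must be ", cfg$n_treatments, " unique labels")
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  set.seed(substream_seeds(cfg$seed)[[1L]])
  n_ind <- max(1L, min(cfg$module_size - 1L,
                       round(cfg$induced_fraction * cfg$module_size)))
  if (cfg$module_size == 1L) n_ind <- 1L
  pool <- if (cfg$disjoint) sample(genes) else NULL
  entries <- list()
  for (i in seq_len(cfg$n_treatments)) {
    members <- if (cfg$disjoint)
      pool[seq.int((i - 1L) * cfg$module_size + 1L, i * cfg$module_size)]
    else sample(genes, cfg$module_size)
    entries[[treatment_names[[i]]]] <-
      list(induced = sort(members[seq_len(n_ind)]),
           repressed = sort(members[-seq_len(n_ind)]))
  }
  signature_compendium(entries)
}

#' Generate a two-tissue case/control study with planted ground truth
#'
#' Builds the complete input bundle for the concordance pipeline: two
#' log2 expression matrices (one per tissue, case vs control), the
#' stimulation compendium, a flat gene-to-term annotation, and a truth
#' record. The signature genes of the first `n_driver_treatments`
#' treatments are planted with `shared_effect_lfc` in the case group of
#' BOTH tissues, signed by their signature direction (induced +,
#' repressed -); when overlapping driver signatures disagree on a gene's
#' direction, the first-listed driver wins so the planted sign is
#' consistent across tissues. A `background_de_rate` fraction of the
#' remaining genes receives tissue-private effects (random sign,
#' magnitude uniform on log2 1.5 to 2) independently in each tissue; all
#' other genes are pure noise.
#'
#' The annotation contains 50 random 20-60-gene terms plus one planted
#' term (`"planted_up_response"`) covering the planted induced genes,
#' recorded in the truth for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_study`: `tissue1`, `tissue2`
#'   ([expression_matrix()]s), `compendium`, `annotation`, `truth`
#'   (list: `driver_ids`, `planted` data.frame of gene/direction/lfc,
#'   `planted_term`).
#' @export
generate_two_tissue_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- substream_seeds(cfg$seed)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  compendium <- generate_compendium(cfg)
  drivers <- names(compendium)[seq_len(cfg$n_driver_treatments)]

  # planted genes: union over drivers, first-listed driver decides direction
  planted_gene <- character(0); planted_dir <- character(0)
  for (trt in drivers) {
    for (dir in c("induced", "repressed")) {
      new <- setdiff(compendium[[trt]][[dir]], planted_gene)
      planted_gene <- c(planted_gene, new)
      planted_dir <- c(planted_dir, rep(dir, length(new)))
    }
  }
  planted_lfc <- ifelse(planted_dir == "induced", 1, -1) *
    cfg$shared_effect_lfc
  truth_planted <- data.frame(gene = planted_gene, direction = planted_dir,
                              lfc = planted_lfc, stringsAsFactors = FALSE)

  set.seed(seeds[[2L]])
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes

  effect_shared <- stats::setNames(numeric(cfg$n_genes), genes)
  effect_shared[planted_gene] <- planted_lfc
  free <- setdiff(genes, planted_gene)

  make_tissue <- function(n_per_group, tissue_seed, tag) {
    set.seed(tissue_seed)
    effect <- effect_shared
    if (cfg$background_de_rate > 0 && length(free)) {
      n_bg <- round(cfg$background_de_rate * length(free))
      bg <- sample(free, n_bg)
      effect[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) *
        stats::runif(n_bg, log2(1.5), 2)
    }
    n_tot <- 2L * n_per_group
    vals <- baseline +
      matrix(stats::rnorm(cfg$n_genes * n_tot, 0, cfg$noise_sd),
             cfg$n_genes, n_tot)
    groups <- rep(c("control", "case"), each = n_per_group)
    vals[, groups == "case"] <- vals[, groups == "case"] + effect
    colnames(vals) <- sprintf("%s_s%02d", tag, seq_len(n_tot))
    rownames(vals) <- genes
    expression_matrix(vals, stats::setNames(groups, colnames(vals)))
  }
  tissue1 <- make_tissue(cfg$n_samples_per_group_tissue1, seeds[[3L]], "t1")
  tissue2 <- make_tissue(cfg$n_samples_per_group_tissue2, seeds[[4L]], "t2")

  set.seed(seeds[[5L]])
  n_terms <- 50L
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    size <- sample(20:60, 1L)
    data.frame(gene = sample(genes, min(size, cfg$n_genes)),
               term = sprintf("term%03d", i), stringsAsFactors = FALSE)
  }))
  planted_up <- truth_planted$gene[truth_planted$direction == "induced"]
  planted_term <- "planted_up_response"
  if (length(planted_up))
    ann <- rbind(ann, data.frame(gene = planted_up, term = planted_term,
                                 stringsAsFactors = FALSE))

  structure(list(tissue1 = tissue1, tissue2 = tissue2,
                 compendium = compendium, annotation = ann,
                 truth = list(driver_ids = drivers,
                              planted = truth_planted,
                              planted_term = planted_term)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:\n  ")
  print(x$tissue1); cat("  "); print(x$tissue2)
  cat("  compendium:", length(x$compendium), "treatments; drivers:",
      paste(x$truth$driver_ids, collapse = ", "), "\n")
  cat("  planted genes:", nrow(x$truth$planted), "\n")
  invisible(x)
}

#' Configuration for the synthetic qPCR Ct experiment
#'
#' Plants a classic four-condition stimulation layout (control, agent A,
#' agent B, combination) in Ct space. A Ct decrease of d cycles means a
#' 2^d-fold expression increase, so `effect_a_dct` etc. are expression
#' effects in doublings; `interaction_dct` is the extra shift the
#' combination receives beyond the sum of the single agents, so the
#' downstream Bliss index recovers exactly 2^interaction_dct when
#' `replicate_sd = 0`.
#'
#' @param base_ct Target-gene Ct in the control condition (cycles).
#' @param ref_ct Reference-gene Ct, all conditions (cycles).
#' @param effect_a_dct,effect_b_dct Single-agent Ct decreases (cycles).
#' @param interaction_dct Extra Ct decrease under the combination.
#' @param replicate_sd Replicate noise sd (cycles, >= 0).
#' @param n_replicates Replicates per condition/gene (>= 2).
#' @param target_gene,reference_gene Gene labels used in the table.
#' @param seed Integer seed.
#' @return A validated `ct_sim_config` list.
#' @export
ct_sim_config <- function(base_ct = 30, ref_ct = 18,
                          effect_a_dct = log2(600),
                          effect_b_dct = log2(60),
                          interaction_dct = log2(95000 / 36000),
                          replicate_sd = 0.15, n_replicates = 3L,
                          target_gene = "CXCL10",
                          reference_gene = "RPLP0", seed = 1L) {
  cfg <- list(base_ct = base_ct, ref_ct = ref_ct,
              effect_a_dct = effect_a_dct, effect_b_dct = effect_b_dct,
              interaction_dct = interaction_dct,
              replicate_sd = replicate_sd,
              n_replicates = as.integer(n_replicates),
              target_gene = target_gene, reference_gene = reference_gene,
              seed = as.integer(seed))
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (cfg$replicate_sd < 0) stop("replicate_sd must be >= 0")
  class(cfg) <- "ct_sim_config"
  cfg
}

#' Generate a tidy synthetic qPCR Ct table
#'
#' Conditions are `control`, `A`, `B`, `A+B`, each with target and
#' reference rows times `n_replicates`. With `replicate_sd = 0` the
#' ddCt pipeline recovers the planted folds exactly: condition A yields
#' 2^effect_a_dct, B yields 2^effect_b_dct, and the combination yields
#' 2^(effect_a_dct + effect_b_dct + interaction_dct).
#'
#' @param cfg A [ct_sim_config()].
#' @return A [ct_table()]. Deterministic given `cfg$seed`.
#' @export
generate_ct_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  set.seed(substream_seeds(cfg$seed)[[6L]])
  shifts <- c(control = 0, A = cfg$effect_a_dct, B = cfg$effect_b_dct,
              `A+B` = cfg$effect_a_dct + cfg$effect_b_dct +
                cfg$interaction_dct)
  rows <- list()
  for (cond in names(shifts)) {
    for (gene in c(cfg$target_gene, cfg$reference_gene)) {
      mu <- if (gene == cfg$target_gene)
        cfg$base_ct - shifts[[cond]] else cfg$ref_ct
      ct <- mu + stats::rnorm(cfg$n_replicates, 0, cfg$replicate_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, gene = gene,
                   replicate = seq_len(cfg$n_replicates), ct = ct,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (any(tab$ct <= 0 | tab$ct >= 45))
    stop("generated Ct values fall outside (0, 45); adjust base_ct/effects")
  ct_table(tab, reference_gene = cfg$reference_gene)
}
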