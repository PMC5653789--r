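test_that("compendium generation respects counts and determinism", {
  cfg <- sim_config(n_genes = 800, n_treatments = 42, module_size = 100,
                    seed = 7)
  comp <- generate_compendium(cfg)
  expect_length(comp, 42L)
  sizes <- vapply(comp, function(e)
    length(e$induced) + length(e$repressed), integer(1))
  expect_true(all(sizes == 100L))
  expect_true(all(vapply(comp, function(e)
    length(intersect(e$induced, e$repressed)) == 0L, logical(1))))
  # default split: 70 induced / 30 repressed
  expect_true(all(vapply(comp, function(e)
    length(e$induced) == 70L, logical(1))))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(generate_compendium(cfg), f1)
  write_gmt(generate_compendium(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical GMT
  expect_length(readLines(f1), 84L)
})

test_that("a saturated single-treatment compendium covers the universe", {
  cfg <- sim_config(n_genes = 60, n_treatments = 1,
                    n_driver_treatments = 1, module_size = 60, seed = 2)
  comp <- generate_compendium(cfg)
  expect_setequal(c(comp[[1]]$induced, comp[[1]]$repressed),
                  sprintf("gene%05d", 1:60))
})

test_that("disjoint mode partitions signatures across treatments", {
  cfg <- sim_config(n_genes = 500, n_treatments = 5, module_size = 100,
                    disjoint = TRUE, seed = 3)
  comp <- generate_compendium(cfg)
  all_members <- unlist(lapply(comp, function(e) c(e$induced, e$repressed)))
  expect_false(anyDuplicated(all_members) > 0)
  expect_length(all_members, 500L)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(module_size = 0), ">= 1")
  expect_error(sim_config(n_genes = 0), ">= 1")
  expect_error(sim_config(n_driver_treatments = 50, n_treatments = 42),
               "exceed")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(background_de_rate = 1), "background_de_rate")
  expect_error(sim_config(n_genes = 100, n_treatments = 5,
                          module_size = 40, disjoint = TRUE), "disjoint")
})

test_that("study truth bookkeeping names the planted drivers", {
  cfg <- sim_config(n_genes = 300, module_size = 30,
                    n_driver_treatments = 2, seed = 9)
  study <- generate_two_tissue_study(cfg)
  expect_identical(study$truth$driver_ids, c("IFN-g", "TNF-a"))
  planted <- study$truth$planted
  expect_true(all(planted$gene %in% rownames(study$tissue1$values)))
  expect_true(all(planted$lfc[planted$direction == "induced"] > 0))
  expect_true(all(planted$lfc[planted$direction == "repressed"] < 0))
  # planted directions agree with the driver signatures
  ind <- unique(unlist(lapply(study$truth$driver_ids, function(t)
    study$compendium[[t]]$induced)))
  expect_true(all(planted$gene[planted$direction == "induced"] %in% ind))
})

test_that("planted effects are encoded at the stated magnitude", {
  cfg <- sim_config(n_genes = 400, module_size = 60, noise_sd = 0.5,
                    seed = 13)
  study <- generate_two_tissue_study(cfg)
  for (tis in c("tissue1", "tissue2")) {
    mat <- study[[tis]]
    n <- sum(mat$groups == "case")
    diff <- rowMeans(mat$values[, mat$groups == "case"]) -
      rowMeans(mat$values[, mat$groups == "control"])
    planted <- study$truth$planted
    expect_true(all(abs(diff[planted$gene] - planted$lfc) <
                      4 * 0.5 / sqrt(n)),
                label = paste("effect recovery in", tis))
  }
})

test_that("null planting yields only false-positive-level DEG calls", {
  n_deg <- vapply(1:5, function(seed) {
    study <- generate_two_tissue_study(null_config(seed, n_genes = 1000))
    d <- call_degs(welch_contrast(study$tissue1))
    length(d$up) + length(d$down)
  }, numeric(1))
  expect_lte(mean(n_deg), 1)  # BH at 0.05 over null p-values
})

test_that("study generation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 200, module_size = 20, seed = 17)
  s1 <- generate_two_tissue_study(cfg)
  s2 <- generate_two_tissue_study(cfg)
  expect_identical(s1$tissue1$values, s2$tissue1$values)
  expect_identical(s1$tissue2$values, s2$tissue2$values)
  expect_identical(unclass(s1$compendium), unclass(s2$compendium))
  expect_identical(s1$annotation, s2$annotation)
  s3 <- generate_two_tissue_study(sim_config(n_genes = 200,
                                             module_size = 20, seed = 18))
  expect_false(identical(s1$tissue1$values, s3$tissue1$values))
})

test_that("Ct generator plants exact fold-changes when noise-free", {
  cfg <- ct_sim_config(effect_a_dct = 0, effect_b_dct = 0,
                       interaction_dct = 0, replicate_sd = 0)
  ct <- generate_ct_experiment(cfg)
  for (cond in c("A", "B", "A+B"))
    expect_equal(ddct_fold(ct, "CXCL10", "RPLP0", cond, "control")$fold, 1.0)

  cfg4 <- ct_sim_config(effect_a_dct = 4, effect_b_dct = 1,
                        interaction_dct = 0, replicate_sd = 0)
  ct4 <- generate_ct_experiment(cfg4)
  expect_equal(ddct_fold(ct4, "CXCL10", "RPLP0", "A", "control")$fold, 16)

  expect_identical(generate_ct_experiment(ct_sim_config(seed = 5)),
                   generate_ct_experiment(ct_sim_config(seed = 5)))
  expect_error(ct_sim_config(n_replicates = 1), ">= 2")
  expect_error(generate_ct_experiment(
    ct_sim_config(base_ct = 40, effect_a_dct = -10, replicate_sd = 0)),
    "outside")
})
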