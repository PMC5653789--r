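make_ct <- function(target_ct, ref_ct = 15, conds = names(target_ct),
                    reps = 2) {
  rows <- do.call(rbind, lapply(conds, function(cond)
    rbind(data.frame(condition = cond, gene = "CXCL10",
                     replicate = seq_len(reps), ct = target_ct[[cond]]),
          data.frame(condition = cond, gene = "RPLP0",
                     replicate = seq_len(reps), ct = ref_ct))))
  ct_table(rows, reference_gene = "RPLP0")
}

test_that("ddCt fold is 1 for the control and 2^-ddCt otherwise", {
  ct <- make_ct(c(control = 24, treated = 20))
  expect_equal(ddct_fold(ct, "CXCL10", "RPLP0", "control", "control")$fold, 1)
  # target 20 vs ref 15 treated; target 24 vs ref 15 control: ddCt = -4
  res <- ddct_fold(ct, "CXCL10", "RPLP0", "treated", "control")
  expect_equal(res$ddct, -4)
  expect_equal(res$fold, 16)
})

test_that("ddCt is invariant to condition-wide shifts of both genes", {
  ct <- make_ct(c(control = 24, treated = 20))
  shifted <- ct
  rows <- shifted$condition == "treated"
  shifted$ct[rows] <- shifted$ct[rows] + 3.7  # e.g. input-amount artifact
  shifted <- ct_table(shifted, "RPLP0")
  expect_equal(ddct_fold(shifted, "CXCL10", "RPLP0", "treated", "control")$fold,
               ddct_fold(ct, "CXCL10", "RPLP0", "treated", "control")$fold)
})

test_that("ddCt errors name the missing gene and condition", {
  ct <- make_ct(c(control = 24, treated = 20))
  expect_error(ddct_fold(ct, "CXCL9", "RPLP0", "treated", "control"),
               "CXCL9.*treated")
})

test_that("replicate folds pair by index and geometric-mean to the fold", {
  rows <- rbind(
    data.frame(condition = "control", gene = "CXCL10", replicate = 1:3,
               ct = c(24.0, 24.4, 23.8)),
    data.frame(condition = "control", gene = "RPLP0", replicate = 1:3,
               ct = c(15.1, 15.0, 14.9)),
    data.frame(condition = "treated", gene = "CXCL10", replicate = 1:3,
               ct = c(20.2, 20.0, 19.6)),
    data.frame(condition = "treated", gene = "RPLP0", replicate = 1:3,
               ct = c(15.0, 15.2, 14.8)))
  res <- ddct_fold(ct_table(rows, "RPLP0"), "CXCL10", "RPLP0",
                   "treated", "control")
  expect_length(res$replicate_folds, 3L)
  expect_equal(exp(mean(log(res$replicate_folds))), res$fold)
})

test_that("synergy index reproduces the worked 600/60/95000 arithmetic", {
  res <- synergy_index(600, 60, 95000)
  expect_equal(res$expected, 36000)
  expect_equal(res$index, 95000 / 36000)
  expect_identical(res$classification, "synergistic")
})

test_that("synergy classification tracks the index on both models", {
  res <- synergy_index(7, 11, 77)
  expect_equal(res$index, 1.0)
  expect_identical(res$classification, "additive")
  expect_identical(synergy_index(10, 10, 50)$classification, "sub-additive")

  hsa <- synergy_index(2, 3, 3, model = "additive_hsa")
  expect_equal(hsa$expected, 3)
  expect_equal(hsa$index, 1.0)
  expect_identical(hsa$classification, "additive")

  expect_equal(synergy_index(600, 60, 95000)$index,
               synergy_index(60, 600, 95000)$index)  # Bliss symmetry
  expect_error(synergy_index(-1, 2, 3), "positive")
})

test_that("generated Ct experiments close the ddct-synergy loop exactly", {
  a <- log2(600); b <- log2(60); d <- 1.25
  cfg <- ct_sim_config(effect_a_dct = a, effect_b_dct = b,
                       interaction_dct = d, replicate_sd = 0)
  ct <- generate_ct_experiment(cfg)
  syn <- ct_synergy(ct, "CXCL10", "RPLP0", "A", "B", "A+B")
  expect_equal(syn$fold_a, 2^a)
  expect_equal(syn$fold_b, 2^b)
  expect_equal(syn$index, 2^d)
  expect_identical(syn$classification, "synergistic")
})

test_that("bootstrap CI on the index covers the noise-free value", {
  set.seed(101)
  cfg <- ct_sim_config(interaction_dct = 1.4, replicate_sd = 0.1,
                       n_replicates = 6, seed = 3)
  syn <- ct_synergy(generate_ct_experiment(cfg), "CXCL10", "RPLP0",
                    "A", "B", "A+B", n_boot = 500)
  expect_length(syn$index_ci, 2L)
  expect_lt(syn$index_ci[1], 2^1.4)
  expect_gt(syn$index_ci[2], 2^1.4 * 0.8)
})
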