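test_that("welch_contrast matches a from-scratch Welch evaluation on 3v3", {
  ctrl <- c(7.1, 7.9, 7.4); case <- c(9.0, 8.2, 8.9)
  mat <- tiny_matrix(matrix(c(ctrl, case), nrow = 1), genes = "gX")
  res <- welch_contrast(mat)

  # independent hand evaluation: t = dmean / sqrt(s1^2/n1 + s2^2/n2),
  # Satterthwaite df, two-sided p
  d <- mean(case) - mean(ctrl)
  a <- var(case) / 3; b <- var(ctrl) / 3
  t_hand <- d / sqrt(a + b)
  df_hand <- (a + b)^2 / (a^2 / 2 + b^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$log2fc, d)
  expect_equal(res$t_stat, t_hand)
  expect_equal(res$p_value, p_hand)

  # cross-check against stats::t.test
  tt <- t.test(case, ctrl)
  expect_equal(res$t_stat, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("equal group means give zero fold-change and p = 1", {
  vals <- matrix(c(5, 6, 7, 7, 6, 5), nrow = 1)  # same mean, same variance
  res <- welch_contrast(tiny_matrix(vals, genes = "g"))
  expect_equal(res$log2fc, 0)
  expect_equal(res$p_value, 1)
})

test_that("group-label swap flips log2fc sign and preserves p", {
  set.seed(21)
  vals <- matrix(rnorm(40, 8, 1), 4, 10)
  mat <- tiny_matrix(vals)
  swapped <- expression_matrix(
    mat$values,
    setNames(ifelse(mat$groups == "case", "control", "case"),
             names(mat$groups)))
  a <- welch_contrast(mat); b <- welch_contrast(swapped)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
})

test_that("groups with fewer than two samples are rejected", {
  vals <- matrix(rnorm(4), 2, 2)
  colnames(vals) <- c("s1", "s2"); rownames(vals) <- c("g1", "g2")
  mat <- expression_matrix(vals, c(s1 = "control", s2 = "case"))
  expect_error(welch_contrast(mat), "at least 2 samples")
})

test_that("bh_adjust reproduces hand-evaluated step-up values", {
  expect_equal(bh_adjust(c(0.005, 0.05, 1.0)), c(0.015, 0.075, 1.0))
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("bh_adjust matches the quadratic oracle and is permutation-stable", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_quadratic(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("call_degs applies strict thresholds and is monotone", {
  contrast <- data.frame(
    gene = c("up_clear", "fc_boundary", "fdr_boundary", "down_clear", "null"),
    log2fc = c(2.5, 1.0, 1.5, -2.5, 0.1),
    q_value = c(0.001, 0.01, 0.05, 0.001, 0.9),
    stringsAsFactors = FALSE)
  degs <- call_degs(contrast, fc_threshold = 2, fdr_threshold = 0.05)
  expect_setequal(degs$up, "up_clear")        # boundary genes excluded
  expect_setequal(degs$down, "down_clear")
  expect_setequal(degs$universe, contrast$gene)

  # tightening either threshold never adds genes
  set.seed(41)
  rnd <- data.frame(gene = sprintf("g%d", 1:200),
                    log2fc = rnorm(200, 0, 2),
                    q_value = runif(200), stringsAsFactors = FALSE)
  loose <- call_degs(rnd, 1.5, 0.2)
  for (fc in c(2, 4)) for (fdr in c(0.1, 0.01)) {
    tight <- call_degs(rnd, fc, fdr)
    expect_true(all(tight$up %in% loose$up))
    expect_true(all(tight$down %in% loose$down))
  }
})

test_that("no gene passes an impossible FDR threshold", {
  set.seed(51)
  contrast <- welch_contrast(tiny_matrix(matrix(rnorm(400, 8, 1), 20, 20)))
  degs <- call_degs(contrast, fdr_threshold = 1e-12)
  expect_length(degs$up, 0L)
  expect_length(degs$down, 0L)
})

test_that("planted threefold effects are recovered with high power", {
  # lfc = 3 at noise_sd = 0.5, n = 10/group: essentially every planted
  # induced gene should be called up
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_genes = 400, module_size = 40,
                      shared_effect_lfc = 3, noise_sd = 0.5,
                      n_samples_per_group_tissue1 = 10,
                      n_samples_per_group_tissue2 = 10, seed = seed)
    study <- generate_two_tissue_study(cfg)
    degs <- call_degs(welch_contrast(study$tissue1))
    planted_up <- study$truth$planted$gene[
      study$truth$planted$direction == "induced"]
    hits <- hits + sum(planted_up %in% degs$up)
    total <- total + length(planted_up)
  }
  expect_gte(hits / total, 0.95)
})
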