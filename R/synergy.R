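#' Relative quantification by the delta-delta-Ct method
#'
#' Classic 2^-ddCt quantification with amplification efficiency fixed at
#' 2: per condition, dCt = mean Ct(target) - mean Ct(reference); the
#' fold-change of `condition` versus `control_condition` is
#' 2^-(dCt(condition) - dCt(control)). When the four involved series
#' (target/reference in treated/control) carry identical replicate index
#' sets, per-replicate ddCt values are paired by index and returned as
#' replicate folds (their geometric mean equals the headline fold);
#' otherwise the condition-mean fold is the only replicate entry.
#'
#' @param ct A [ct_table()].
#' @param target_gene Gene being quantified.
#' @param reference_gene Housekeeping gene used for normalization
#'   (e.g. RPLP0).
#' @param condition Treated condition label.
#' @param control_condition Baseline condition label.
#' @return List of class `fold_change_set`: `condition`, `fold`,
#'   `replicate_folds`, `ddct`.
#' @export
ddct_fold <- function(ct, target_gene, reference_gene, condition,
                      control_condition) {
  pick <- function(gene, cond) {
    rows <- ct$gene == gene & ct$condition == cond
    if (!any(rows))
      stop("no Ct rows for gene '", gene, "' in condition '", cond, "'")
    ct[rows, c("replicate", "ct"), drop = FALSE]
  }
  tt <- pick(target_gene, condition)
  rt <- pick(reference_gene, condition)
  tc <- pick(target_gene, control_condition)
  rc <- pick(reference_gene, control_condition)
  ddct <- (mean(tt$ct) - mean(rt$ct)) - (mean(tc$ct) - mean(rc$ct))
  fold <- 2^(-ddct)
  reps <- sort(tt$replicate)
  aligned <- all(vapply(list(rt, tc, rc), function(d)
    identical(sort(d$replicate), reps), logical(1))) &&
    !anyDuplicated(reps)
  if (aligned && length(reps) > 1L) {
    ord <- function(d) d$ct[order(d$replicate)]
    rep_ddct <- (ord(tt) - ord(rt)) - (ord(tc) - ord(rc))
    replicate_folds <- 2^(-rep_ddct)
  } else {
    replicate_folds <- fold
  }
  structure(list(condition = condition, fold = fold,
                 replicate_folds = replicate_folds, ddct = ddct),
            class = "fold_change_set")
}

#' @export
print.fold_change_set <- function(x, ...) {
  cat(sprintf("%s: fold = %.4g (ddCt = %.3f, %d replicate fold(s))\n",
              x$condition, x$fold, x$ddct, length(x$replicate_folds)))
  invisible(x)
}

#' Two-agent synergy index on fold-changes
#'
#' Compares an observed combination fold-change with a null-model
#' expectation built from the single-agent fold-changes:
#' `bliss_multiplicative` expects `fold_a * fold_b` (independent
#' multiplicative action on the log scale), `additive_hsa` expects
#' `max(fold_a, fold_b)` (highest single agent). The index is
#' observed / expected; an index above 1 is called synergistic, exactly 1
#' additive, below 1 sub-additive.
#'
#' @param fold_a,fold_b Single-agent linear fold-changes (> 0).
#' @param fold_combo Combination fold-change (> 0).
#' @param model `"bliss_multiplicative"` (default) or `"additive_hsa"`.
#' @return List of class `synergy_result`: `fold_a`, `fold_b`,
#'   `fold_combo`, `model`, `expected`, `index`, `classification`.
#' @export
synergy_index <- function(fold_a, fold_b, fold_combo,
                          model = c("bliss_multiplicative",
                                    "additive_hsa")) {
  model <- match.arg(model)
  folds <- c(fold_a = fold_a, fold_b = fold_b, fold_combo = fold_combo)
  if (any(!is.finite(folds) | folds <= 0))
    stop("all fold-changes must be positive and finite")
  expected <- switch(model,
                     bliss_multiplicative = fold_a * fold_b,
                     additive_hsa = max(fold_a, fold_b))
  index <- fold_combo / expected
  classification <- if (isTRUE(all.equal(index, 1, tolerance = 1e-9)))
    "additive" else if (index > 1) "synergistic" else "sub-additive"
  structure(list(fold_a = fold_a, fold_b = fold_b, fold_combo = fold_combo,
                 model = model, expected = expected, index = index,
                 classification = classification),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("synergy (%s): A = %.4g, B = %.4g, combo = %.4g\n",
              x$model, x$fold_a, x$fold_b, x$fold_combo))
  cat(sprintf("  expected = %.4g, index = %.3f -> %s\n",
              x$expected, x$index, x$classification))
  invisible(x)
}

#' Synergy analysis straight from a Ct table
#'
#' Convenience closure of the ddCt -> synergy path: quantifies the two
#' single agents and the combination against the control condition, then
#' scores synergy. Optionally attaches a percentile bootstrap CI on the
#' index, resampling replicate folds (descriptive only; no hypothesis
#' test is attached to the index).
#'
#' @param ct A [ct_table()].
#' @param target_gene,reference_gene Genes, as in [ddct_fold()].
#' @param condition_a,condition_b,condition_combo,control_condition
#'   Condition labels.
#' @param model Synergy null model, see [synergy_index()].
#' @param n_boot Bootstrap resamples for the CI (0 = none).
#' @param conf Confidence level for the bootstrap interval.
#' @return A `synergy_result` with an added `folds` element (the three
#'   `fold_change_set`s) and, if bootstrapped, `index_ci`.
#' @export
ct_synergy <- function(ct, target_gene, reference_gene,
                       condition_a, condition_b, condition_combo,
                       control_condition = "control",
                       model = "bliss_multiplicative",
                       n_boot = 0, conf = 0.95) {
  fa <- ddct_fold(ct, target_gene, reference_gene, condition_a,
                  control_condition)
  fb <- ddct_fold(ct, target_gene, reference_gene, condition_b,
                  control_condition)
  fc_ <- ddct_fold(ct, target_gene, reference_gene, condition_combo,
                   control_condition)
  res <- synergy_index(fa$fold, fb$fold, fc_$fold, model = model)
  res$folds <- list(a = fa, b = fb, combo = fc_)
  if (n_boot > 0) {
    gm <- function(x) exp(mean(log(x)))
    idx <- replicate(n_boot, {
      ra <- gm(sample(fa$replicate_folds, replace = TRUE))
      rb <- gm(sample(fb$replicate_folds, replace = TRUE))
      rc <- gm(sample(fc_$replicate_folds, replace = TRUE))
      synergy_index(ra, rb, rc, model = model)$index
    })
    alpha <- (1 - conf) / 2
    res$index_ci <- unname(stats::quantile(idx, c(alpha, 1 - alpha)))
  }
  res
}
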