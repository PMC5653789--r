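#' Per-gene Welch t contrast (case vs control)
#'
#' Computes, for every gene of a log2 expression matrix, the case-minus-
#' control mean difference (log2 fold-change), the two-sided Welch t
#' statistic with Satterthwaite degrees of freedom, its p-value, and a
#' Benjamini-Hochberg q-value.
#'
#' The Welch (unequal-variance) form is the default test family for
#' unpaired two-group expression comparisons; a pooled-variance Student
#' variant is available via `var_equal = TRUE`. Genes with zero variance in
#' both groups and zero mean difference receive t = 0, p = 1.
#'
#' @param mat An [expression_matrix()].
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A data.frame of class `contrast_table` with columns `gene`,
#'   `log2fc`, `t_stat`, `p_value`, `q_value`, one row per gene.
#' @export
welch_contrast <- function(mat, var_equal = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  case <- mat$values[, mat$groups == "case", drop = FALSE]
  ctrl <- mat$values[, mat$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (case = ", n1,
         ", control = ", n2, ")")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
  lfc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(lfc))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1L) + b^2 / (n2 - 1L))
  }
  t_stat <- lfc / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  # degenerate variance: identical constant values in both groups
  zero <- se == 0
  if (any(zero)) {
    t_stat[zero & lfc == 0] <- 0
    p[zero & lfc == 0] <- 1
    t_stat[zero & lfc != 0] <- sign(lfc[zero & lfc != 0]) * Inf
    p[zero & lfc != 0] <- .Machine$double.xmin
  }
  p <- pmax(p, .Machine$double.xmin)  # p contract is (0, 1]
  out <- data.frame(gene = rownames(mat$values), log2fc = lfc,
                    t_stat = t_stat, p_value = p,
                    q_value = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps raw p-values to FDR q-values by the BH step-up procedure:
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed gene sets by fold-change and FDR
#'
#' Applies strict thresholds: up = log2fc > log2(fc_threshold) and
#' q < fdr_threshold; down symmetric. Genes sitting exactly on either
#' boundary (fold-change exactly at the threshold, or q exactly equal to
#' the FDR cut) are excluded.
#'
#' @param contrast A `contrast_table` from [welch_contrast()].
#' @param fc_threshold Linear fold-change threshold (> 0), default 2.
#' @param fdr_threshold FDR threshold in (0, 1], default 0.05.
#' @return A `deg_sets` object: list with character vectors `up`, `down`,
#'   `universe` and the thresholds used.
#' @export
call_degs <- function(contrast, fc_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(contrast),
            all(c("gene", "log2fc", "q_value") %in% names(contrast)))
  if (fc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  lt <- log2(fc_threshold)
  up <- contrast$gene[contrast$log2fc > lt & contrast$q_value < fdr_threshold]
  down <- contrast$gene[contrast$log2fc < -lt &
                          contrast$q_value < fdr_threshold]
  deg_sets(up = up, down = down, universe = contrast$gene,
           fc_threshold = fc_threshold, fdr_threshold = fdr_threshold)
}

#' Construct a deg_sets object
#'
#' @param up,down Character vectors of up-/down-regulated gene ids.
#' @param universe Character vector of all tested genes.
#' @param fc_threshold,fdr_threshold Thresholds that produced the sets.
#' @return A `deg_sets` object.
#' @export
deg_sets <- function(up, down, universe, fc_threshold = 2,
                     fdr_threshold = 0.05) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  universe <- unique(as.character(universe))
  if (length(intersect(up, down)))
    stop("up and down sets overlap")
  if (!all(c(up, down) %in% universe))
    stop("DEG sets must be subsets of the universe")
  structure(list(up = up, down = down, universe = universe,
                 fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat("deg_sets:", length(x$up), "up /", length(x$down), "down of",
      length(x$universe), "tested (FC >", x$fc_threshold, ", FDR <",
      x$fdr_threshold, ")\n")
  invisible(x)
}

#' Write a contrast table as TSV
#'
#' @param contrast A `contrast_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contrast <- function(contrast, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines("gene\tlog2fc\tt\tp\tq", con, sep = "\n")
  fmt <- function(x) format(x, digits = 15, trim = TRUE)
  writeLines(paste(contrast$gene, fmt(contrast$log2fc), fmt(contrast$t_stat),
                   fmt(contrast$p_value), fmt(contrast$q_value), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}
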