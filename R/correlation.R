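#' Per-gene fold-change profile of a case/control matrix
#'
#' Case-minus-control mean difference per gene, on the log2 scale of the
#' input matrix.
#'
#' @param mat An [expression_matrix()], both groups with >= 2 samples.
#' @param label Source label carried on the profile.
#' @return A `fold_change_profile`: named numeric vector (names = gene
#'   ids) with attribute `source_label`.
#' @export
fold_change_profile <- function(mat, label = "profile") {
  stopifnot(inherits(mat, "expression_matrix"))
  case <- mat$values[, mat$groups == "case", drop = FALSE]
  ctrl <- mat$values[, mat$groups == "control", drop = FALSE]
  if (ncol(case) < 2L || ncol(ctrl) < 2L)
    stop("each group needs at least 2 samples")
  lfc <- rowMeans(case) - rowMeans(ctrl)
  structure(lfc, source_label = label, class = "fold_change_profile")
}

#' Spearman rank correlation of two fold-change profiles
#'
#' Correlates two profiles over the genes they share (matched by exact
#' identifier). rho is the Pearson correlation of mid-ranks (average
#' ranks on ties). The default p-value uses the two-sided t
#' approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees
#' of freedom, which is accurate for the large profiles this is meant
#' for and increasingly rough below n = 10; for n <= 8 an exact
#' permutation p over all n! rank orderings is available with
#' `exact = TRUE`. rho of exactly +/-1 yields the smallest representable
#' positive p under the t approximation.
#'
#' @param a,b `fold_change_profile` objects (or named numeric vectors).
#' @param exact Compute the exact permutation p (requires n <= 8).
#' @return List of class `spearman_result`: `rho`, `n_genes`, `p_value`.
#' @export
spearman_correlation <- function(a, b, exact = FALSE) {
  shared <- intersect(names(a), names(b))
  n <- length(shared)
  if (n < 4L)
    stop("need at least 4 shared genes; found ", n)
  x <- rank(unname(a[shared])); y <- rank(unname(b[shared]))
  rho <- stats::cor(x, y)
  if (exact) {
    if (n > 8L) stop("exact permutation p only for n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    rhos <- apply(perms, 1L, function(idx) stats::cor(x, y[idx]))
    p <- mean(abs(rhos) >= obs - 1e-12)
  } else if (abs(rho) >= 1 - 1e-15) {
    p <- .Machine$double.xmin
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(t), n - 2), .Machine$double.xmin)
  }
  structure(list(rho = rho, n_genes = n, p_value = p),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.3g)\n",
              x$rho, x$n_genes, x$p_value))
  invisible(x)
}

# all permutations of 1..n as rows (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Write a fold-change profile as two-column TSV
#'
#' @param profile A `fold_change_profile` (named numeric vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(names(profile),
                   format(unclass(profile), digits = 15, trim = TRUE),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a fold-change profile from two-column TSV
#'
#' @param path Path to a two-column (gene, log2fc) TSV, no header.
#' @param label Source label.
#' @return A `fold_change_profile`.
#' @export
read_profile <- function(path, label = "profile") {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  lfc <- as.numeric(tab[[2L]])
  names(lfc) <- as.character(tab[[1L]])
  if (anyDuplicated(names(lfc))) stop("duplicate gene ids in profile")
  if (any(!is.finite(lfc))) stop("non-finite fold-change in profile")
  structure(lfc, source_label = label, class = "fold_change_profile")
}
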