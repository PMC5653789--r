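#' Upper-tail hypergeometric probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least `k` marked items when drawing `n` items without replacement
#' from a universe of `N` items containing `K` marked ones. This is the
#' one-sided Fisher exact / gene-set overlap p-value. The tail is computed
#' by `phyper`, which accumulates in log space and remains accurate at
#' extreme tails.
#'
#' @param N Universe size.
#' @param K Number of marked items in the universe.
#' @param n Draw size.
#' @param k Observed overlap.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
            length(k) == 1L)
  if (N < 0) stop("constraint violated: N >= 0")
  if (K < 0 || K > N) stop("constraint violated: 0 <= K <= N")
  if (n < 0 || n > N) stop("constraint violated: 0 <= n <= N")
  if (k < 0 || k > min(n, K)) stop("constraint violated: 0 <= k <= min(n, K)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Directional overlap of two DEG set pairs
#'
#' Computes up/up and down/down overlap between two studies' DEG sets on
#' the intersection of their tested universes, with upper-tail
#' hypergeometric significance. The overlap percentage is reported
#' relative to study A's (restricted) set, matching the usual phrasing
#' "x% of the study-A-increased genes were also increased in study B".
#'
#' @param degs_a,degs_b `deg_sets` objects (see [call_degs()]).
#' @return A list of class `overlap_report`: `up` and `down` (each with
#'   `n_universe`, `n_setA`, `n_setB`, `n_overlap`, `pct_of_A`, `p_value`),
#'   plus `shared_up` and `shared_down` gene vectors and `n_universe`.
#' @export
directional_overlap <- function(degs_a, degs_b) {
  stopifnot(inherits(degs_a, "deg_sets"), inherits(degs_b, "deg_sets"))
  universe <- intersect(degs_a$universe, degs_b$universe)
  if (!length(universe))
    stop("empty intersection universe between the two studies")
  one <- function(a, b) {
    a <- intersect(a, universe); b <- intersect(b, universe)
    k <- length(intersect(a, b))
    list(n_universe = length(universe), n_setA = length(a),
         n_setB = length(b), n_overlap = k,
         pct_of_A = if (length(a)) 100 * k / length(a) else 0,
         p_value = hypergeom_upper_tail(length(universe), length(b),
                                        length(a), k))
  }
  up <- one(degs_a$up, degs_b$up)
  down <- one(degs_a$down, degs_b$down)
  structure(list(up = up, down = down,
                 shared_up = intersect(intersect(degs_a$up, degs_b$up),
                                       universe),
                 shared_down = intersect(intersect(degs_a$down, degs_b$down),
                                         universe),
                 n_universe = length(universe)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap (universe %d):\n", x$n_universe))
  for (dir in c("up", "down")) {
    o <- x[[dir]]
    cat(sprintf("  %-4s k = %d of |A| = %d (%.1f%%), |B| = %d, p = %.3g\n",
                dir, o$n_overlap, o$n_setA, o$pct_of_A, o$n_setB, o$p_value))
  }
  invisible(x)
}
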