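#' Flat-annotation term enrichment of a gene set
#'
#' Hypergeometric over-representation of each annotation term within a
#' gene set, against a stated universe. Annotation is a flat gene-to-term
#' table (no ontology propagation; pre-propagate if using a real DAG).
#' Terms are flagged `enriched` at a raw p-value threshold — no multiple-
#' testing correction at this stage, by design.
#'
#' @param gene_set Character vector of genes, a subset of `universe`.
#' @param universe Character vector of all eligible genes.
#' @param annotation Data frame with columns `gene`, `term`.
#' @param p_threshold Raw p-value threshold for the `enriched` flag
#'   (default 0.001).
#' @return Data frame sorted by ascending p, one row per term with at
#'   least one annotated gene in the universe: `term`,
#'   `n_annotated_in_universe`, `n_annotated_in_set`, `p_value`, `enriched`.
#' @export
enrich_terms <- function(gene_set, universe, annotation,
                         p_threshold = 0.001) {
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  extra <- setdiff(gene_set, universe)
  if (length(extra))
    stop("gene_set contains gene(s) outside the universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  ann <- unique(ann[c("gene", "term")])
  if (!nrow(ann)) {
    out <- data.frame(term = character(0),
                      n_annotated_in_universe = integer(0),
                      n_annotated_in_set = integer(0),
                      p_value = numeric(0), enriched = logical(0))
    return(out)
  }
  in_set <- ann$gene %in% gene_set
  K <- tapply(ann$gene, ann$term, length)
  k <- tapply(in_set, ann$term, sum)
  terms <- names(K)
  N <- length(universe); n <- length(gene_set)
  p <- vapply(seq_along(terms), function(i)
    hypergeom_upper_tail(N, as.integer(K[[i]]), n, as.integer(k[[i]])),
    numeric(1))
  out <- data.frame(term = terms,
                    n_annotated_in_universe = as.integer(K),
                    n_annotated_in_set = as.integer(k),
                    p_value = p,
                    enriched = p < p_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Signed enrichment of a shared gene set against one treatment signature
#'
#' Tests the shared set against a treatment's induced and repressed
#' signature sets separately (upper-tail hypergeometric on the stated
#' universe), then combines them into a single signed statistic:
#' magnitude -log10 of the smaller p, sign positive when the induced side
#' is the stronger match (ties go to the induced side), negative when the
#' repressed side is. The two-direction p is the Bonferroni doubling
#' `min(1, 2 * min(p_induced, p_repressed))`.
#'
#' If both signature sets are empty after restriction to the universe the
#' result is flagged `degenerate` with statistic 0 and p_two 1.
#'
#' @param shared_set Character vector of genes, subset of `universe`.
#' @param universe Character vector of eligible genes.
#' @param signature_entry List with `induced` and `repressed` gene
#'   vectors (one element of a [signature_compendium()]).
#' @param treatment_id Label carried into the result.
#' @return A one-row data.frame: `treatment_id`, `p_induced`,
#'   `p_repressed`, `statistic`, `p_two`, `degenerate`.
#' @export
signed_signature_stat <- function(shared_set, universe, signature_entry,
                                  treatment_id = NA_character_) {
  shared_set <- unique(as.character(shared_set))
  universe <- unique(as.character(universe))
  extra <- setdiff(shared_set, universe)
  if (length(extra))
    stop("shared_set contains gene(s) outside the universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  ind <- intersect(signature_entry$induced, universe)
  rep_ <- intersect(signature_entry$repressed, universe)
  N <- length(universe); n <- length(shared_set)
  if (!length(ind) && !length(rep_)) {
    return(data.frame(treatment_id = treatment_id, p_induced = 1,
                      p_repressed = 1, statistic = 0, p_two = 1,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  p_ind <- hypergeom_upper_tail(N, length(ind), n,
                                length(intersect(shared_set, ind)))
  p_rep <- hypergeom_upper_tail(N, length(rep_), n,
                                length(intersect(shared_set, rep_)))
  sgn <- if (p_ind <= p_rep) 1 else -1
  data.frame(treatment_id = treatment_id, p_induced = p_ind,
             p_repressed = p_rep,
             statistic = sgn * -log10(min(p_ind, p_rep)),
             p_two = min(1, 2 * min(p_ind, p_rep)),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Attribute a shared gene set to compendium treatments
#'
#' Runs [signed_signature_stat()] for every treatment of a compendium and
#' ranks treatments by BH-adjusted two-direction p-value.
#'
#' @param shared_set Character vector of genes, subset of `universe`.
#' @param universe Character vector of eligible genes.
#' @param compendium A [signature_compendium()].
#' @return A ranked data.frame (see [rank_treatments()]).
#' @export
attribute_signatures <- function(shared_set, universe, compendium) {
  stopifnot(inherits(compendium, "signature_compendium"))
  rows <- lapply(names(compendium), function(trt)
    signed_signature_stat(shared_set, universe, compendium[[trt]],
                          treatment_id = trt))
  rank_treatments(do.call(rbind, rows))
}

#' Rank treatments by BH-adjusted signed enrichment
#'
#' Adds `q_value` (BH over `p_two` across treatments) and sorts by q, then
#' p_two, then |statistic| descending, with a final lexicographic
#' treatment-id tie-break, giving a deterministic total order that does
#' not depend on input order.
#'
#' @param results Data frame of [signed_signature_stat()] rows.
#' @return The same rows, ranked, with columns `rank` and `q_value` added.
#' @export
rank_treatments <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("treatment_id", "p_two", "statistic") %in% names(results)))
  results$q_value <- bh_adjust(results$p_two)
  ord <- order(results$q_value, results$p_two, -abs(results$statistic),
               results$treatment_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("rank", setdiff(names(out), "rank"))]
}
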