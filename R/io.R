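#' Read a log2 expression matrix with sample group labels
#'
#' Loads a tab-separated expression table (first column gene identifiers,
#' header row sample identifiers, values on the log2 scale) together with a
#' two-column sample-to-group map, and returns a validated
#' `expression_matrix` object.
#'
#' Genes carrying any missing value are dropped with a message giving the
#' count; imputation is deliberately not offered, since it is an analysis
#' choice that would silently alter downstream set sizes. Gene and sample
#' identifiers are matched as exact, case-sensitive strings throughout the
#' package.
#'
#' @param path Path to the expression TSV.
#' @param group_map_path Path to a two-column TSV (sample, group) with no
#'   header, where group is `"case"` or `"control"`. Every sample in the
#'   matrix must appear.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes x samples) and `groups` (named character vector,
#'   values `"case"`/`"control"`).
#' @seealso [write_expression()], [expression_matrix()]
#' @export
read_expression <- function(path, group_map_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression table needs a gene column plus at least one sample")
  gene_ids <- as.character(tab[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene identifier(s) in expression table: ",
         paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  sample_ids <- colnames(values)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier(s) in expression header")

  gm <- utils::read.delim(group_map_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(gm) < 2L) stop("group map must have two columns: sample, group")
  groups <- as.character(gm[[2L]])
  names(groups) <- as.character(gm[[1L]])
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing))
    stop("sample(s) missing from group map: ", paste(missing, collapse = ", "))
  groups <- groups[sample_ids]

  incomplete <- !stats::complete.cases(values)
  if (any(incomplete)) {
    message(sum(incomplete), " gene(s) dropped for missing values")
    values <- values[!incomplete, , drop = FALSE]
  }
  expression_matrix(values, groups)
}

#' Construct an expression_matrix object
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param groups Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("case", "control"))
  if (length(bad))
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples (",
      sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control )\n")
  invisible(x)
}

#' Write an expression matrix and its group map as TSV
#'
#' @param mat An `expression_matrix`.
#' @param path Output path for the expression TSV.
#' @param group_map_path Output path for the two-column sample/group TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path, group_map_path) {
  stopifnot(inherits(mat, "expression_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene_id", colnames(mat$values)), collapse = "\t"),
             con, sep = "\n")
  body <- apply(format(mat$values, digits = 15, trim = TRUE,
                       scientific = FALSE), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(mat$values), body, sep = "\t"), con, sep = "\n")
  gm <- file(group_map_path, open = "wb")
  on.exit(close(gm), add = TRUE)
  writeLines(paste(names(mat$groups), mat$groups, sep = "\t"), gm, sep = "\n")
  invisible(path)
}

#' Read a stimulation-signature compendium from a GMT file
#'
#' Each treatment contributes two GMT lines, `<treatment>_induced` and
#' `<treatment>_repressed`; a missing partner yields an empty set for that
#' direction. Fields are tab-separated: name, description, then member genes.
#'
#' @param path Path to the GMT file.
#' @return A `signature_compendium`: named list, one element per treatment,
#'   each a list with `induced` and `repressed` character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop("malformed GMT line ", i, ": fewer than 2 fields")
    name <- fields[[1L]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (grepl("_induced$", name)) {
      stem <- sub("_induced$", "", name); dir <- "induced"
    } else if (grepl("_repressed$", name)) {
      stem <- sub("_repressed$", "", name); dir <- "repressed"
    } else {
      stop("GMT set name lacks an _induced/_repressed suffix: ", name)
    }
    if (is.null(entries[[stem]]))
      entries[[stem]] <- list(induced = character(0), repressed = character(0))
    entries[[stem]][[dir]] <- unique(genes)
  }
  signature_compendium(entries)
}

#' Construct a signature_compendium object
#'
#' @param entries Named list; each element a list with character vectors
#'   `induced` and `repressed`. Within a treatment the two sets must be
#'   disjoint and not both empty.
#' @return A `signature_compendium`.
#' @export
signature_compendium <- function(entries) {
  if (!length(entries) || is.null(names(entries)) ||
      anyDuplicated(names(entries)))
    stop("compendium needs uniquely named treatment entries")
  for (trt in names(entries)) {
    e <- entries[[trt]]
    both <- intersect(e$induced, e$repressed)
    if (length(both))
      stop("gene(s) in both directions of treatment '", trt, "': ",
           paste(both, collapse = ", "))
    if (!length(e$induced) && !length(e$repressed))
      stop("treatment '", trt, "' has empty induced and repressed sets")
  }
  structure(entries, class = "signature_compendium")
}

#' @export
print.signature_compendium <- function(x, ...) {
  cat("signature_compendium:", length(x), "treatments\n")
  invisible(x)
}

#' Write a signature compendium as GMT
#'
#' Emits two lines per treatment (`<name>_induced`, `<name>_repressed`) in
#' the order of the compendium, so identical compendia serialize
#' byte-identically.
#'
#' @param compendium A `signature_compendium`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(compendium, path) {
  stopifnot(inherits(compendium, "signature_compendium"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  for (trt in names(compendium)) {
    e <- compendium[[trt]]
    writeLines(paste(c(paste0(trt, "_induced"), "synthetic", e$induced),
                     collapse = "\t"), con, sep = "\n")
    writeLines(paste(c(paste0(trt, "_repressed"), "synthetic", e$repressed),
                     collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a tidy qPCR Ct table
#'
#' Expects a header row and the columns `condition`, `gene`, `replicate`,
#' `ct` (cycles). Validates that every Ct lies in (0, 45) and that the
#' designated reference gene is measured in every condition.
#'
#' @param path Path to the tidy TSV.
#' @param reference_gene Identifier of the reference (housekeeping) gene,
#'   e.g. `"RPLP0"`.
#' @return A `ct_table` (data.frame subclass).
#' @export
read_ct <- function(path, reference_gene) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("condition", "gene", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  ct_table(tab[need], reference_gene = reference_gene)
}

#' Construct a validated ct_table
#'
#' @param df Data frame with columns condition, gene, replicate, ct.
#' @param reference_gene Reference gene that must appear in every condition.
#' @return A `ct_table`.
#' @export
ct_table <- function(df, reference_gene) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$ct <- as.numeric(df$ct)
  bad <- !is.finite(df$ct) | df$ct <= 0 | df$ct >= 45
  if (any(bad))
    stop("Ct value(s) outside (0, 45): ",
         paste(utils::head(df$ct[bad], 5L), collapse = ", "))
  conds <- unique(df$condition)
  for (cond in conds) {
    if (!any(df$gene == reference_gene & df$condition == cond))
      stop("reference gene '", reference_gene,
           "' absent in condition '", cond, "'")
  }
  attr(df, "reference_gene") <- reference_gene
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a Ct table as tidy TSV
#'
#' @param ct A `ct_table` (or compatible data frame).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct <- function(ct, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines("condition\tgene\treplicate\tct", con, sep = "\n")
  writeLines(paste(ct$condition, ct$gene, ct$replicate,
                   format(ct$ct, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a flat gene-to-term annotation table
#'
#' Two tab-separated columns (gene, term), no header, one row per
#' gene/term pairing. This is a flat stand-in for pre-propagated GO
#' biological-process annotation.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `gene` and `term`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation must have two columns: gene, term")
  data.frame(gene = as.character(tab[[1L]]),
             term = as.character(tab[[2L]]),
             stringsAsFactors = FALSE)
}

#' Write a gene-to-term annotation table
#'
#' @param annotation Data frame with columns `gene`, `term`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(annotation$gene, annotation$term, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}
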