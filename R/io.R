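# Readers/writers for the plain-text interchange formats used throughout:
# expression TSV (first column gene id), sample-annotation TSV, DEG-table
# TSV, two-column edge-list TSV, and GMT gene-set libraries.

#' Write / read a study's expression matrix and sample annotation
#'
#' `write_study()` emits two TSV files: `<prefix>_expr.tsv` (first column
#' `gene`, one column per sample) and `<prefix>_annot.tsv` (columns
#' `sample`, `group`, and optionally `batch`, `tissue`). `read_study()`
#' reads them back into an `expression_study`.
#'
#' @param study an `expression_study` (see [generate_study()]).
#' @param prefix file path prefix.
#' @return `write_study()` returns the two paths invisibly; `read_study()`
#'   returns an `expression_study`.
#' @export
write_study <- function(study, prefix) {
  stopifnot(inherits(study, "expression_study"))
  expr_path <- paste0(prefix, "_expr.tsv")
  annot_path <- paste0(prefix, "_annot.tsv")
  expr <- data.frame(gene = rownames(study$matrix), study$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  annot <- data.frame(sample = colnames(study$matrix), group = study$group,
                      stringsAsFactors = FALSE)
  if (!is.null(study$batch)) annot$batch <- study$batch
  if (!is.null(study$tissue)) annot$tissue <- study$tissue
  utils::write.table(annot, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr = expr_path, annot = annot_path))
}

#' @rdname write_study
#' @param expr_path,annot_path paths to the expression and annotation TSVs.
#' @param study_id study identifier attached to the result.
#' @export
read_study <- function(expr_path, annot_path, study_id = basename(expr_path)) {
  expr <- utils::read.delim(expr_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (colnames(expr)[1] != "gene")
    stop("expression TSV must have 'gene' as its first column")
  x <- as.matrix(expr[, -1, drop = FALSE])
  rownames(x) <- toupper(expr$gene)
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(annot)))
    stop("annotation TSV must have 'sample' and 'group' columns")
  idx <- match(colnames(x), annot$sample)
  if (anyNA(idx)) stop("samples in expression matrix missing from annotation")
  study <- list(
    study_id = study_id,
    gene_ids = rownames(x),
    matrix = x,
    group = annot$group[idx],
    batch = if ("batch" %in% colnames(annot)) annot$batch[idx] else NULL,
    tissue = if ("tissue" %in% colnames(annot)) annot$tissue[idx][1] else NULL
  )
  class(study) <- "expression_study"
  study
}

#' Write / read a per-study DEG table
#'
#' Tables carry the columns `gene`, `log2FC`, `CI.L`, `CI.R`, `t`,
#' `P.Value`, `adj.P.Val`, `status` produced by [run_dex()].
#'
#' @param table DEG-table data frame.
#' @param path file path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read an undirected edge list
#'
#' Two-column TSV with header `from`/`to`.
#'
#' @param edges data frame with columns `from` and `to`.
#' @param path file path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    warning("empty edge-list file: ", path)
    return(data.frame(from = character(0), to = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2)
  if (length(bad) > 0)
    stop("malformed edge-list line ", bad[1], " in ", path)
  df <- data.frame(from = vapply(fields, `[[`, "", 1),
                   to = vapply(fields, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$from[1]), "from")) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}
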