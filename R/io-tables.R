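#' Read a count matrix and its sample-group map
#'
#' The counts file is a TSV with a header row of sample ids and feature ids
#' in the first column; the group map is a two-column TSV (`sample`,
#' `group`). Validation is strict: negative or non-integer values and any
#' mismatch between the matrix samples and the group map are errors.
#'
#' @param path Counts TSV path.
#' @param groups_path Group map TSV path.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, groups_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("counts table needs >= 1 sample column", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (any(m != round(m)))
    stop("counts must be integer-valued", call. = FALSE)
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g)))
    stop("group map needs columns 'sample' and 'group'", call. = FALSE)
  if (!setequal(colnames(m), g$sample))
    stop("sample set mismatch between counts header and group map", call. = FALSE)
  expression_matrix(m, stats::setNames(g$group, g$sample))
}

#' Write a count matrix and its group map
#'
#' @param em An [expression_matrix()].
#' @param path Counts TSV path.
#' @param groups_path Group map TSV path (skipped if `NULL`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path, groups_path = NULL) {
  tab <- data.frame(feature_id = rownames(em$counts), em$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    g <- data.frame(sample = names(em$groups), group = as.character(em$groups))
    utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# Format numeric columns at 6 significant digits for deterministic TSV output.
format_num_cols <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.6g", df[[j]])
  df
}

#' Write co-expression edges / ceRNA triplets to TSV
#'
#' One record per row, header included, floats at 6 significant digits, rows
#' sorted by ids so equal inputs give byte-identical files.
#'
#' @param edges,triplets A `data.frame` of edges ([coexpression_edges()]) or
#'   triplets ([assemble_triplets()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  if (nrow(edges)) edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  utils::write.table(format_num_cols(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
write_triplets <- function(triplets, path) {
  if (nrow(triplets))
    triplets <- triplets[order(triplets$mrna_id, triplets$mirna_id,
                               triplets$lncrna_id), , drop = FALSE]
  utils::write.table(format_num_cols(triplets), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a coding-potential verdict table
#'
#' TSV with columns `transcript_id`, `cpc2`, `cnci`, `plek`, `pfam`; verdict
#' values are 0/1 with 1 = predicted non-coding.
#'
#' @param path TSV path.
#' @return `read_verdicts`: data.frame with logical verdict columns.
#' @export
read_verdicts <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cpc2", "cnci", "plek", "pfam")
  if (!all(need %in% names(v)))
    stop("verdict table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (tool in need[-1]) v[[tool]] <- as.logical(v[[tool]])
  v[need]
}

#' @rdname read_verdicts
#' @param verdicts Verdict data.frame (logical or 0/1 columns).
#' @export
write_verdicts <- function(verdicts, path) {
  v <- verdicts
  for (tool in c("cpc2", "cnci", "plek", "pfam"))
    v[[tool]] <- as.integer(v[[tool]])
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
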