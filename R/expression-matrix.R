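#' Expression matrix with a two-group sample design
#'
#' Lightweight container coupling a non-negative numeric matrix
#' (features x samples) with a per-sample group label. All differential
#' expression and co-expression functions in the package take this class.
#'
#' @param counts Numeric matrix, features in rows, samples in columns, with
#'   unique non-empty dimnames. Values must be non-negative and finite.
#' @param groups Named character vector (or factor) mapping every sample id
#'   in `colnames(counts)` to a group label.
#' @return An object of class `expr_matrix`: a list with elements `counts`
#'   (the validated matrix) and `groups` (factor named by sample id, in
#'   column order).
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, c(s1 = "A", s2 = "A", s3 = "B"))
#' @export
expression_matrix <- function(counts, groups) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  fid <- rownames(counts); sid <- colnames(counts)
  if (is.null(fid) || is.null(sid))
    stop("`counts` must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(fid)) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(sid)) stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  groups <- stats::setNames(as.character(groups), names(groups))
  missing <- setdiff(sid, names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  groups <- factor(groups[sid])
  structure(list(counts = counts, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s(n=%d)", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

# Internal: require exactly two groups, return their labels (level order).
two_group_labels <- function(em) {
  lv <- levels(em$groups)
  if (length(lv) != 2L)
    stop("exactly two groups are required, got: ", paste(lv, collapse = ", "),
         call. = FALSE)
  lv
}
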