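#' Pearson correlation with a t-based two-sided p-value
#'
#' Product-moment correlation, with significance from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' `|r| = 1` gives p = 0 exactly. Zero variance in either vector is an
#' error, not an NaN.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `r` and `p`.
#' @examples
#' pearson_cor(c(1, 2, 3), c(2, 4, 6))
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, n))
}

# Two-sided p for a Pearson r at sample size n; +-1 maps to 0.
# pmax/pmin keep `r` first so matrix dims survive.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1, 0, {
    t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(t), df = n - 2)
  })
  pmin(p, 1)
}

#' Sign-constrained co-expression edges between two feature sets
#'
#' Tests every cross-set feature pair by Pearson correlation over all
#' samples pooled, and emits an edge iff `|r| > r_threshold` (strict),
#' `p < p_threshold` (strict), and the sign of r matches `required_sign`.
#' Matrices must share the exact same sample order; mismatches are an
#' error, never silently realigned.
#'
#' @param mat_a,mat_b Numeric matrices (features x samples) of expression
#'   values on the scale correlations should be computed on.
#' @param class_pair Label for the pair class (e.g. `"miRNA-mRNA"`).
#' @param required_sign `"positive"` or `"negative"`.
#' @param r_threshold,p_threshold Thresholds (defaults 0.8 and 0.05, both
#'   strict).
#' @return data.frame: `id_a`, `id_b`, `class_pair`, `r`, `p`,
#'   `required_sign` (id_a from `mat_a`).
#' @export
coexpression_edges <- function(mat_a, mat_b, class_pair,
                               required_sign = c("negative", "positive"),
                               r_threshold = 0.8, p_threshold = 0.05) {
  required_sign <- match.arg(required_sign)
  if (is.null(colnames(mat_a)) || !identical(colnames(mat_a), colnames(mat_b)))
    stop("sample order mismatch between matrices", call. = FALSE)
  n <- ncol(mat_a)
  if (n < 3L) stop("need n >= 3 samples", call. = FALSE)
  ok_a <- apply(mat_a, 1, stats::sd) > 0
  ok_b <- apply(mat_b, 1, stats::sd) > 0
  mat_a <- mat_a[ok_a, , drop = FALSE]
  mat_b <- mat_b[ok_b, , drop = FALSE]
  if (!nrow(mat_a) || !nrow(mat_b)) return(empty_edge_frame())
  r <- stats::cor(t(mat_a), t(mat_b))
  p <- cor_pvalue(r, n)
  sign_ok <- if (required_sign == "positive") r > 0 else r < 0
  hit <- which(abs(r) > r_threshold & p < p_threshold & sign_ok,
               arr.ind = TRUE)
  if (!nrow(hit)) return(empty_edge_frame())
  out <- data.frame(
    id_a = rownames(mat_a)[hit[, 1]], id_b = rownames(mat_b)[hit[, 2]],
    class_pair = class_pair, r = r[hit], p = p[hit],
    required_sign = required_sign, stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_edge_frame <- function() {
  data.frame(id_a = character(), id_b = character(), class_pair = character(),
             r = numeric(), p = numeric(), required_sign = character(),
             stringsAsFactors = FALSE)
}

#' Cis lncRNA-gene pairs within a genomic window
#'
#' A lncRNA cis-regulates a gene when the two features lie on the same
#' chromosome within `window_bp` (inclusive at the boundary; "within 100 kb"
#' read as a closed interval) and are significantly co-expressed. Distance
#' is 0 for overlapping intervals, otherwise the gap between the closest
#' interval boundaries, strand-agnostic. The signed distance reported for
#' display is negative when the lncRNA lies 5'-ward (lower coordinate) of
#' the gene start.
#'
#' @param lncrnas,genes Transcript data.frames for the lncRNAs and genes.
#' @param expr_edges mRNA-lncRNA co-expression edges ([coexpression_edges()]
#'   with `id_a` = mRNA/gene id, `id_b` = lncRNA id), already thresholded.
#' @param window_bp Window (default 100000, inclusive).
#' @return data.frame: `lncrna_id`, `gene_id`, `distance`,
#'   `signed_distance`, `r`.
#' @export
cis_pairs <- function(lncrnas, genes, expr_edges, window_bp = 100000) {
  out <- list()
  edge_key <- paste(expr_edges$id_b, expr_edges$id_a)
  for (i in seq_len(nrow(lncrnas))) {
    l <- lncrnas[i, ]
    same <- genes[genes$chrom == l$chrom, , drop = FALSE]
    for (j in seq_len(nrow(same))) {
      g <- same[j, ]
      d <- max(0L, max(l$start, g$start) - min(l$end, g$end))
      if (d > window_bp) next
      k <- match(paste(l$transcript_id, g$transcript_id), edge_key)
      if (is.na(k)) next
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = l$transcript_id, gene_id = g$transcript_id,
        distance = d,
        signed_distance = if (l$start <= g$start) -d else d,
        r = expr_edges$r[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = integer(), signed_distance = integer(),
                      r = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$lncrna_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Trans lncRNA-mRNA pairs: duplex hit plus co-expression
#'
#' A trans pair requires both a sequence-level duplex hit
#' ([trans_duplex_scan()]) and a qualifying co-expression edge.
#'
#' @param duplex_hits Duplex hit data.frame.
#' @param expr_edges mRNA-lncRNA edges (`id_a` = mRNA, `id_b` = lncRNA).
#' @return data.frame: `lncrna_id`, `mrna_id`, `stretch_len`, `energy`, `r`.
#' @export
trans_pairs <- function(duplex_hits, expr_edges) {
  if (!nrow(duplex_hits))
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      stretch_len = integer(), energy = numeric(),
                      r = numeric(), stringsAsFactors = FALSE))
  edge_key <- paste(expr_edges$id_b, expr_edges$id_a)
  k <- match(paste(duplex_hits$lncrna_id, duplex_hits$mrna_id), edge_key)
  keep <- !is.na(k)
  hits <- duplex_hits[keep, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      stretch_len = integer(), energy = numeric(),
                      r = numeric(), stringsAsFactors = FALSE))
  res <- data.frame(lncrna_id = hits$lncrna_id, mrna_id = hits$mrna_id,
                    stretch_len = hits$stretch_len, energy = hits$energy,
                    r = expr_edges$r[k[keep]], stringsAsFactors = FALSE)
  # one row per pair: keep the lowest-energy hit
  res <- res[order(res$lncrna_id, res$mrna_id, res$energy), , drop = FALSE]
  res <- res[!duplicated(res[c("lncrna_id", "mrna_id")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep negatively correlated miRNA-target edges with binding support
#'
#' An expression edge survives iff at least one predicted binding site
#' links the same (miRNA, target) pair -- the "negative correlation plus
#' target site" rule for miRNA-mRNA and miRNA-lncRNA interactions.
#'
#' @param expr_edges Negative-sign edges with `id_a` = miRNA id, `id_b` =
#'   target id.
#' @param sites Binding-site data.frame ([mirna_scan()]).
#' @return The supported subset of `expr_edges`, with the best site's
#'   `align_score` and `delta_g` appended.
#' @export
mirna_target_edges <- function(expr_edges, sites) {
  if (!nrow(expr_edges)) return(cbind(expr_edges, align_score = numeric(0),
                                      delta_g = numeric(0)))
  if (nrow(sites)) {
    sites <- sites[order(-sites$align_score, sites$delta_g), , drop = FALSE]
    best <- sites[!duplicated(sites[c("mirna_id", "target_id")]), ,
                  drop = FALSE]
    k <- match(paste(expr_edges$id_a, expr_edges$id_b),
               paste(best$mirna_id, best$target_id))
  } else {
    k <- rep(NA_integer_, nrow(expr_edges))
  }
  keep <- !is.na(k)
  out <- expr_edges[keep, , drop = FALSE]
  out$align_score <- if (any(keep)) best$align_score[k[keep]] else numeric(0)
  out$delta_g <- if (any(keep)) best$delta_g[k[keep]] else numeric(0)
  rownames(out) <- NULL
  out
}

#' Assemble mRNA-miRNA-lncRNA ceRNA triplets
#'
#' Emits a triplet (m, mi, l) iff the miRNA represses both partners
#' (supported negative edges mi-m and mi-l, each with a binding site) and
#' the mRNA and lncRNA are positively co-expressed. The ceRNA score is the
#' mRNA-lncRNA correlation; output is sorted by score descending with
#' deterministic id tie-breaks.
#'
#' @param mirna_mrna_edges,mirna_lncrna_edges Site-supported negative edge
#'   data.frames ([mirna_target_edges()]; `id_a` = miRNA).
#' @param mrna_lncrna_edges Positive edge data.frame (`id_a` = mRNA,
#'   `id_b` = lncRNA).
#' @param score_min Optional floor on the ceRNA score (default none).
#' @return data.frame: `mrna_id`, `mirna_id`, `lncrna_id`,
#'   `r_mrna_lncrna`, `r_mirna_mrna`, `r_mirna_lncrna`, `cerna_score`.
#' @export
assemble_triplets <- function(mirna_mrna_edges, mirna_lncrna_edges,
                              mrna_lncrna_edges, score_min = -Inf) {
  if (!nrow(mirna_mrna_edges) || !nrow(mirna_lncrna_edges) ||
      !nrow(mrna_lncrna_edges)) return(empty_triplet_frame())
  mm <- mirna_mrna_edges; ml <- mirna_lncrna_edges; pl <- mrna_lncrna_edges
  # join on the shared miRNA, then require the positive mRNA-lncRNA edge
  j <- merge(data.frame(mirna_id = mm$id_a, mrna_id = mm$id_b,
                        r_mirna_mrna = mm$r, stringsAsFactors = FALSE),
             data.frame(mirna_id = ml$id_a, lncrna_id = ml$id_b,
                        r_mirna_lncrna = ml$r, stringsAsFactors = FALSE),
             by = "mirna_id")
  if (!nrow(j)) return(empty_triplet_frame())
  k <- match(paste(j$mrna_id, j$lncrna_id), paste(pl$id_a, pl$id_b))
  j <- j[!is.na(k), , drop = FALSE]
  if (!nrow(j)) return(empty_triplet_frame())
  j$r_mrna_lncrna <- pl$r[k[!is.na(k)]]
  j$cerna_score <- j$r_mrna_lncrna
  j <- j[j$cerna_score >= score_min, , drop = FALSE]
  j <- j[order(-j$cerna_score, j$mrna_id, j$mirna_id, j$lncrna_id), ,
         drop = FALSE]
  out <- j[c("mrna_id", "mirna_id", "lncrna_id", "r_mrna_lncrna",
             "r_mirna_mrna", "r_mirna_lncrna", "cerna_score")]
  rownames(out) <- NULL
  out
}

empty_triplet_frame <- function() {
  data.frame(mrna_id = character(), mirna_id = character(),
             lncrna_id = character(), r_mrna_lncrna = numeric(),
             r_mirna_mrna = numeric(), r_mirna_lncrna = numeric(),
             cerna_score = numeric(), stringsAsFactors = FALSE)
}
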