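#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median, across
#' features with positive counts in every sample, of the ratio of the
#' sample's count to the feature's geometric mean. This is the
#' median-of-ratios estimator commonly used for RNA-seq library-size
#' normalization.
#'
#' @param em An [expression_matrix()].
#' @return Named numeric vector of positive factors, one per sample.
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' size_factors(expression_matrix(m, c(s1 = "A", s2 = "B")))
#' @export
size_factors <- function(em) {
  m <- em$counts
  ref <- m[rowSums(m > 0) == ncol(m), , drop = FALSE]
  if (!nrow(ref))
    stop(paste("no feature has positive counts in every sample;",
               "consider a pseudo-reference fallback"), call. = FALSE)
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, stats::median)
  stats::setNames(as.numeric(sf), colnames(m))
}

# Counts scaled by estimated size factors.
normalized_counts <- function(em, sf = size_factors(em)) {
  sweep(em$counts, 2, sf[colnames(em$counts)], `/`)
}

#' FPKM from counts and feature lengths
#'
#' `fpkm = count * 1e9 / (length_nt * library_size)` where `library_size` is
#' the sample's total count.
#'
#' @param em An [expression_matrix()] of raw counts.
#' @param lengths Named numeric vector, feature id -> length in nt.
#' @return Numeric matrix of FPKM values, same dimnames as the counts.
#' @export
fpkm <- function(em, lengths) {
  m <- em$counts
  len <- lengths[rownames(m)]
  if (any(is.na(len))) stop("missing length for some features", call. = FALSE)
  if (any(len <= 0)) stop("feature lengths must be positive", call. = FALSE)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("zero library size", call. = FALSE)
  m * 1e9 / outer(as.numeric(len), as.numeric(lib))
}

#' Two-group differential expression with fold-change and p thresholds
#'
#' Counts are normalized by median-of-ratios size factors; the fold change
#' is `log2((mean_A + 1) / (mean_B + 1))` on normalized means (pseudocount 1
#' keeps it bounded with zeros); the p-value is a two-sided Welch t-test on
#' `log2(normalized + 1)`. A feature is called `up` when
#' `log2fc > lfc_threshold` and `p < p_threshold` (both strict), `down`
#' symmetrically, otherwise `ns`. Raw p-values are used for calling;
#' multiplicity correction is left to enrichment, where it belongs in this
#' pipeline.
#'
#' @param em An [expression_matrix()] with exactly two groups and at least
#'   two replicates per group.
#' @param p_threshold,lfc_threshold DE calling thresholds (strict
#'   inequalities). Defaults `0.05` and `1`.
#' @param orientation Which group plays "A" in `log2(A/B)`; default the
#'   first factor level.
#' @return data.frame: `feature_id`, `mean_A`, `mean_B`, `log2fc`, `p`,
#'   `direction`.
#' @export
de_test <- function(em, p_threshold = 0.05, lfc_threshold = 1,
                    orientation = levels(em$groups)[1]) {
  lv <- two_group_labels(em)
  if (!orientation %in% lv) stop("unknown orientation group", call. = FALSE)
  a <- orientation; b <- setdiff(lv, a)
  ia <- which(em$groups == a); ib <- which(em$groups == b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 replicates (variance undefined)", call. = FALSE)
  norm <- normalized_counts(em)
  la <- log2(norm[, ia, drop = FALSE] + 1)
  lb <- log2(norm[, ib, drop = FALSE] + 1)
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_a + 1) / (mean_b + 1))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      stats::t.test(xa, xb)$p.value
    }
  }, 0)
  direction <- rep("ns", length(p))
  direction[p < p_threshold & log2fc > lfc_threshold] <- "up"
  direction[p < p_threshold & log2fc < -lfc_threshold] <- "down"
  data.frame(feature_id = rownames(norm), mean_A = mean_a, mean_B = mean_b,
             log2fc = log2fc, p = p, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((cq_target_case - cq_ref_case) - (cq_target_ctrl - cq_ref_ctrl))`,
#' the standard qPCR quantification relative to a reference gene and a
#' control condition.
#'
#' @param cq_target_case,cq_ref_case,cq_target_ctrl,cq_ref_ctrl Cq (cycle
#'   threshold) values; must be finite.
#' @return Relative expression (positive scalar, vectorized).
#' @examples
#' ddct(20, 15, 22, 15) # ddCt = -2 -> 4
#' @export
ddct <- function(cq_target_case, cq_ref_case, cq_target_ctrl, cq_ref_ctrl) {
  vals <- c(cq_target_case, cq_ref_case, cq_target_ctrl, cq_ref_ctrl)
  if (any(!is.finite(vals))) stop("non-finite Cq value", call. = FALSE)
  2^-((cq_target_case - cq_ref_case) - (cq_target_ctrl - cq_ref_ctrl))
}
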