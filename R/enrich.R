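#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn from a background of `N` containing `K` annotated ones:
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k Hits in the query.
#' @param K Term size in the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)))
    stop("hypergeometric bounds violated", call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @rdname hypergeom_upper
#' @details `hypergeom_pmf` exposes the point mass `P(X = k)` (used by the
#'   conservation property tests).
#' @export
hypergeom_pmf <- function(k, K, n, N) {
  stats::dhyper(k, K, N - K, n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `fdr_i = min_{j >= rank(i)} (p_(j) * m / j)`,
#' clipped to 1, with the input order preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order and length.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a term-to-gene map for over-representation of a query
#' gene set against a background, with BH correction across all tested
#' terms. Terms are intersected with the background first; terms left empty
#' (`K = 0`) are dropped before correction.
#'
#' @param query Character vector of query gene ids (must be a subset of the
#'   background).
#' @param background Character vector of background gene ids (the universe).
#' @param term_map data.frame with columns `term_id`, `term_name`,
#'   `gene_id`, one row per term membership.
#' @return data.frame sorted by p ascending: `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr`, `enrichment_score` (`-log10(p)`).
#' @export
enrich <- function(query, background, term_map) {
  query <- unique(query); background <- unique(background)
  bad <- setdiff(query, background)
  if (length(bad))
    stop("query genes absent from background: ", paste(bad, collapse = ", "),
         call. = FALSE)
  need <- c("term_id", "term_name", "gene_id")
  if (!all(need %in% names(term_map)))
    stop("term map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  if (!nrow(term_map))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      enrichment_score = numeric(), stringsAsFactors = FALSE))
  sets <- split(unique(term_map[c("term_id", "gene_id")])$gene_id,
                unique(term_map[c("term_id", "gene_id")])$term_id)
  names_map <- term_map$term_name[match(names(sets), term_map$term_id)]
  N <- length(background); n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(g) length(intersect(g, query)), 0L)
  p <- hypergeom_upper(k, K, n, N)
  out <- data.frame(term_id = names(sets), term_name = names_map,
                    k = as.integer(k), K = as.integer(K), n = n, N = N,
                    p = as.numeric(p), fdr = bh_adjust(as.numeric(p)),
                    enrichment_score = -log10(pmax(p, .Machine$double.xmin)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
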