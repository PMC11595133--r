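#' Run the full ceRNA inference pipeline on a dataset
#'
#' End-to-end analysis over the three RNA classes: lncRNA identification
#' (structural filter + coding-potential verdict intersection),
#' differential expression per class, sign-constrained co-expression on the
#' DE sets, binding-site and duplex scanning for the correlated pairs,
#' cis/trans lncRNA target assignment, and ceRNA triplet assembly. Networks
#' are built on DE features only (the usual design for a two-group ceRNA
#' study); correlations are computed on `log2(normalized count + 1)` across
#' all samples pooled.
#'
#' @param dataset A list as returned by [simulate_dataset()]: `annotation`,
#'   `sequences` (`mrna`/`lncrna`/`mirna`), `counts` (three
#'   [expression_matrix()]).
#' @param p_threshold,lfc_threshold DE thresholds (defaults 0.05, 1).
#' @param r_threshold,cor_p_threshold Co-expression thresholds (defaults
#'   0.8, 0.05).
#' @param s_min,dg_max,strict_seed miRNA scanner thresholds ([mirna_scan()]).
#' @param min_stretch,energy_cutoff Trans duplex thresholds
#'   ([trans_duplex_scan()]).
#' @param window_bp Cis window (default 100 kb, inclusive).
#' @param verdicts Optional coding-potential verdict table; defaults to the
#'   ORF heuristic filling all four predictor slots.
#' @return List: `lncrna_ids`, `de` (per-class DE tables), `de_ids`,
#'   `edges` (`mirna_mrna`, `mirna_lncrna`, `mrna_lncrna`; the miRNA edges
#'   site-supported), `sites`, `duplex_hits`, `cis`, `trans`, `triplets`.
#' @export
run_cerna_pipeline <- function(dataset,
                               p_threshold = 0.05, lfc_threshold = 1,
                               r_threshold = 0.8, cor_p_threshold = 0.05,
                               s_min = 150, dg_max = -30, strict_seed = TRUE,
                               min_stretch = 10, energy_cutoff = -100,
                               window_bp = 100000, verdicts = NULL) {
  ann <- dataset$annotation
  seqs <- dataset$sequences
  counts <- dataset$counts

  ann_l <- ann[ann$biotype %in% c("lncRNA", "lncRNA_candidate"), ,
               drop = FALSE]
  lnc <- identify_lncrnas(ann_l, seqs$lncrna, verdicts)

  de <- list(
    mrna = de_test(counts$mrna, p_threshold, lfc_threshold),
    mirna = de_test(counts$mirna, p_threshold, lfc_threshold),
    lncrna = de_test(counts$lncrna, p_threshold, lfc_threshold))
  de_ids <- list(
    mrna = de$mrna$feature_id[de$mrna$direction != "ns"],
    mirna = de$mirna$feature_id[de$mirna$direction != "ns"],
    lncrna = intersect(de$lncrna$feature_id[de$lncrna$direction != "ns"],
                       lnc$lncrna_ids))

  log_expr <- function(em, ids) {
    m <- log2(normalized_counts(em) + 1)
    m[intersect(ids, rownames(m)), , drop = FALSE]
  }
  ex_m <- log_expr(counts$mrna, de_ids$mrna)
  ex_mi <- log_expr(counts$mirna, de_ids$mirna)
  ex_l <- log_expr(counts$lncrna, de_ids$lncrna)

  mi_m <- coexpression_edges(ex_mi, ex_m, "miRNA-mRNA", "negative",
                             r_threshold, cor_p_threshold)
  mi_l <- coexpression_edges(ex_mi, ex_l, "miRNA-lncRNA", "negative",
                             r_threshold, cor_p_threshold)
  m_l <- coexpression_edges(ex_m, ex_l, "mRNA-lncRNA", "positive",
                            r_threshold, cor_p_threshold)

  scan_pairs <- function(edges, queries, targets) {
    out <- list()
    for (i in seq_len(nrow(edges)))
      out[[i]] <- mirna_scan(queries[[edges$id_a[i]]],
                             targets[[edges$id_b[i]]],
                             s_min = s_min, dg_max = dg_max,
                             strict_seed = strict_seed,
                             mirna_id = edges$id_a[i],
                             target_id = edges$id_b[i])
    if (!length(out)) return(empty_site_frame())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
  sites_m <- scan_pairs(mi_m, seqs$mirna, seqs$mrna)
  sites_l <- scan_pairs(mi_l, seqs$mirna, seqs$lncrna)
  mm <- mirna_target_edges(mi_m, sites_m)
  ml <- mirna_target_edges(mi_l, sites_l)

  hits <- list()
  for (i in seq_len(nrow(m_l)))
    hits[[i]] <- trans_duplex_scan(seqs$lncrna[[m_l$id_b[i]]],
                                   seqs$mrna[[m_l$id_a[i]]],
                                   min_stretch = min_stretch,
                                   energy_cutoff = energy_cutoff,
                                   lncrna_id = m_l$id_b[i],
                                   mrna_id = m_l$id_a[i])
  duplex_hits <- if (length(hits)) do.call(rbind, hits) else
    empty_duplex_frame()
  rownames(duplex_hits) <- NULL

  cis <- cis_pairs(ann_l[ann_l$transcript_id %in% de_ids$lncrna, ,
                         drop = FALSE],
                   ann[ann$biotype == "mRNA" &
                         ann$transcript_id %in% de_ids$mrna, , drop = FALSE],
                   m_l, window_bp)
  trans <- trans_pairs(duplex_hits, m_l)
  triplets <- assemble_triplets(mm, ml, m_l)

  list(lncrna_ids = lnc$lncrna_ids, de = de, de_ids = de_ids,
       edges = list(mirna_mrna = mm, mirna_lncrna = ml, mrna_lncrna = m_l),
       sites = rbind(sites_m, sites_l), duplex_hits = duplex_hits,
       cis = cis, trans = trans, triplets = triplets)
}

#' Score pipeline output against the planted truth
#'
#' @param dataset Simulated dataset ([simulate_dataset()]).
#' @param result Pipeline output ([run_cerna_pipeline()]).
#' @return List of recovery metrics: `de_sensitivity` (planted DE features
#'   called DE, all classes pooled), `triplet_precision`, `triplet_recall`,
#'   `trans_recall` (planted trans pairs recovered), `cis_recovered`
#'   (engineered cis pairs within the window that were reported) and the
#'   underlying counts.
#' @export
evaluate_recovery <- function(dataset, result) {
  truth <- dataset$truth
  de_all <- do.call(rbind, result$de)
  called <- de_all$feature_id[de_all$direction != "ns"]
  planted <- truth$de_features$feature_id
  de_sens <- if (length(planted)) mean(planted %in% called) else NA_real_

  key <- function(df, cols) do.call(paste, c(df[cols], sep = "|"))
  tcols <- c("mrna_id", "mirna_id", "lncrna_id")
  found <- key(result$triplets, tcols)
  want <- key(truth$planted_triplets, tcols)
  precision <- if (length(found)) mean(found %in% want) else NA_real_
  recall <- if (length(want)) mean(want %in% found) else NA_real_

  tp_found <- key(result$trans, c("lncrna_id", "mrna_id"))
  tp_want <- key(truth$planted_trans_pairs, c("lncrna_id", "mrna_id"))
  trans_recall <- if (length(tp_want)) mean(tp_want %in% tp_found) else
    NA_real_

  cis_found <- key(result$cis, c("lncrna_id", "gene_id"))
  in_window <- truth$cis_pair_truth[truth$cis_pair_truth$distance <= 100000, ,
                                    drop = FALSE]
  cis_rec <- if (nrow(in_window))
    mean(key(in_window, c("lncrna_id", "gene_id")) %in% cis_found) else
      NA_real_

  list(de_sensitivity = de_sens, triplet_precision = precision,
       triplet_recall = recall, trans_recall = trans_recall,
       cis_recovered = cis_rec,
       n_triplets_found = nrow(result$triplets),
       n_triplets_planted = nrow(truth$planted_triplets),
       n_de_called = length(unique(called)),
       n_de_planted = length(planted))
}

#' Binding-site scanner sensitivity on planted sites
#'
#' Scans every planted (miRNA, target) pair at the given thresholds and
#' checks that a reported site overlaps the planted position.
#'
#' @param dataset Simulated dataset.
#' @param ... Scanner arguments passed to [mirna_scan()].
#' @return Fraction of planted sites recovered.
#' @export
site_sensitivity <- function(dataset, ...) {
  truth <- dataset$truth
  seqs <- dataset$sequences
  hit <- logical(nrow(truth$planted_sites))
  for (i in seq_len(nrow(truth$planted_sites))) {
    s <- truth$planted_sites[i, ]
    target <- if (!is.na(seqs$mrna[s$target_id])) seqs$mrna[[s$target_id]]
      else seqs$lncrna[[s$target_id]]
    len <- nchar(seqs$mirna[[s$mirna_id]])
    found <- mirna_scan(seqs$mirna[[s$mirna_id]], target,
                        mirna_id = s$mirna_id, target_id = s$target_id, ...)
    hit[i] <- any(found$target_start <= s$position + len - 1L &
                    found$target_end >= s$position)
  }
  mean(hit)
}
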