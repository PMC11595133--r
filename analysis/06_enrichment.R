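#!/usr/bin/env Rscript
# Hypergeometric over-representation of the DE mRNA set against a synthetic
# term map, and the final scoring of the inferred network against the
# planted truth. The term map contains one module built from the planted DE
# genes plus random modules; a calibrated test must rank the planted module
# first.

suppressMessages(library(cernet))

truth <- read_truth("results/simdata/truth.json")
de_m <- utils::read.delim("results/de_mrna.tsv")
called <- de_m$feature_id[de_m$direction != "ns"]
bg <- de_m$feature_id

set.seed(60)
planted_m <- intersect(truth$de_features$feature_id, bg)
term_map <- rbind(
  data.frame(term_id = "MOD0001", term_name = "planted DE module",
             gene_id = planted_m),
  data.frame(term_id = sprintf("MOD%04d", rep(2:21, each = 20)),
             term_name = "random module",
             gene_id = sample(bg, 400, replace = TRUE)))
term_map <- unique(term_map)

res <- enrich(called, bg, term_map)
utils::write.table(format(res, digits = 6), "results/enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
top <- res[1, ]
message(sprintf(
  "Top term: %s (%s), k/K = %d/%d, p = %.3g, FDR = %.3g, score = %.1f",
  top$term_id, top$term_name, top$k, top$K, top$p, top$fdr,
  top$enrichment_score))

# ---- recovery scorecard against the planted truth -----------------------
triplets <- utils::read.delim("results/triplets.tsv")
key3 <- function(d) paste(d$mrna_id, d$mirna_id, d$lncrna_id)
found <- key3(triplets); want <- key3(truth$planted_triplets)
trans <- utils::read.delim("results/trans_pairs.tsv")
cis <- utils::read.delim("results/cis_pairs.tsv")
in_win <- truth$cis_pair_truth[truth$cis_pair_truth$distance <= 100000, ]

scorecard <- data.frame(
  metric = c("de_sensitivity", "triplet_precision", "triplet_recall",
             "trans_recall", "cis_recovery"),
  value = c(
    mean(truth$de_features$feature_id %in%
           unlist(lapply(c("mrna", "mirna", "lncrna"), function(cls) {
             de <- utils::read.delim(sprintf("results/de_%s.tsv", cls))
             de$feature_id[de$direction != "ns"]
           }))),
    mean(found %in% want), mean(want %in% found),
    mean(paste(truth$planted_trans_pairs$lncrna_id,
               truth$planted_trans_pairs$mrna_id) %in%
           paste(trans$lncrna_id, trans$mrna_id)),
    mean(paste(in_win$lncrna_id, in_win$gene_id) %in%
           paste(cis$lncrna_id, cis$gene_id))))
utils::write.table(format(scorecard, digits = 4), "results/scorecard.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("Recovery vs planted truth:")
for (i in seq_len(nrow(scorecard)))
  message(sprintf("  %-18s %.3f", scorecard$metric[i], scorecard$value[i]))
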