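#!/usr/bin/env Rscript
# Sign-constrained co-expression networks over the DE sets (|r| > 0.8,
# p < 0.05 on log2 normalized counts, all samples pooled), intersected with
# the sequence-level evidence:
#  - miRNA-mRNA and miRNA-lncRNA: negative correlation + binding site;
#  - mRNA-lncRNA: positive correlation (ceRNA principle);
#  - cis pairs within +-100 kb, trans pairs with a duplex hit;
#  - mRNA-miRNA-lncRNA triplets from the three edge sets.

suppressMessages(library(cernet))

indir <- "results/simdata"
lnc_ok <- readLines("results/lncrna_ids.txt")
de_ids <- function(cls) {
  de <- utils::read.delim(file.path("results", paste0("de_", cls, ".tsv")))
  de$feature_id[de$direction != "ns"]
}
log_expr <- function(cls, ids) {
  em <- read_counts(file.path(indir, paste0("counts_", cls, ".tsv")),
                    file.path(indir, "groups.tsv"))
  m <- log2(sweep(em$counts, 2, size_factors(em), `/`) + 1)
  m[intersect(ids, rownames(m)), , drop = FALSE]
}
ex_m <- log_expr("mrna", de_ids("mrna"))
ex_mi <- log_expr("mirna", de_ids("mirna"))
ex_l <- log_expr("lncrna", intersect(de_ids("lncrna"), lnc_ok))

mi_m <- coexpression_edges(ex_mi, ex_m, "miRNA-mRNA", "negative")
mi_l <- coexpression_edges(ex_mi, ex_l, "miRNA-lncRNA", "negative")
m_l <- coexpression_edges(ex_m, ex_l, "mRNA-lncRNA", "positive")

sites <- utils::read.delim("results/sites.tsv")
duplex <- utils::read.delim("results/duplex.tsv")
mm <- mirna_target_edges(mi_m, sites)
ml <- mirna_target_edges(mi_l, sites)

message(sprintf("miRNA-mRNA:   %d site-supported of %d negative pairs",
                nrow(mm), nrow(mi_m)))
message(sprintf("miRNA-lncRNA: %d site-supported of %d negative pairs",
                nrow(ml), nrow(mi_l)))
message(sprintf("mRNA-lncRNA:  %d positively co-expressed pairs", nrow(m_l)))

ann <- read_gtf("results/simdata/annotation.gtf")
cis <- cis_pairs(ann[ann$biotype == "lncRNA" &
                       ann$transcript_id %in% rownames(ex_l), ],
                 ann[ann$biotype == "mRNA" &
                       ann$transcript_id %in% rownames(ex_m), ], m_l)
trans <- trans_pairs(duplex, m_l)
triplets <- assemble_triplets(mm, ml, m_l)

write_edges(mm, "results/edges_mirna_mrna.tsv")
write_edges(ml, "results/edges_mirna_lncrna.tsv")
write_edges(m_l, "results/edges_mrna_lncrna.tsv")
utils::write.table(cis, "results/cis_pairs.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(trans, "results/trans_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_triplets(triplets, "results/triplets.tsv")

message(sprintf("cis pairs: %d   trans pairs: %d", nrow(cis), nrow(trans)))
message(sprintf("ceRNA triplets: %d (top score r = %.3f)", nrow(triplets),
                if (nrow(triplets)) max(triplets$cerna_score) else NA))
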