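#!/usr/bin/env Rscript
# Sequence-level interaction prediction restricted to the DE sets:
#  - miRNA target sites (miranda-style: S >= 150, dG <= -30 kcal/mol,
#    strict 5' seed) on DE mRNAs and identified DE lncRNAs;
#  - lncRNA-mRNA trans duplexes (>= 10 bp exact complementarity, energy
#    <= -100 under the Turner nearest-neighbor table).
# Writes results/sites.tsv and results/duplex.tsv.

suppressMessages(library(cernet))

de_ids <- function(cls) {
  de <- utils::read.delim(file.path("results", paste0("de_", cls, ".tsv")))
  de$feature_id[de$direction != "ns"]
}
lnc_ok <- readLines("results/lncrna_ids.txt")

mirnas <- read_fasta("results/simdata/mirna.fa")[de_ids("mirna")]
mrnas <- read_fasta("results/simdata/mrna.fa")[de_ids("mrna")]
lncs <- read_fasta("results/simdata/lncrna.fa")[
  intersect(de_ids("lncrna"), lnc_ok)]

sites <- rbind(scan_mirna_set(mirnas, mrnas),
               scan_mirna_set(mirnas, lncs))
utils::write.table(sites, "results/sites.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("%d binding sites for %d DE miRNAs on %d DE mRNAs + %d DE lncRNAs",
                nrow(sites), length(mirnas), length(mrnas), length(lncs)))

duplex <- scan_trans_set(lncs, mrnas)
utils::write.table(duplex, "results/duplex.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("%d trans duplex hits (>= 10 bp, energy <= -100)",
                nrow(duplex)))
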