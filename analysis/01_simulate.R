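#!/usr/bin/env Rscript
# Generate the synthetic two-group ceRNA dataset used by the rest of the
# analysis: annotation (GTF), sequences (FASTA), NB counts (TSV) and the
# planted truth (JSON), all under results/simdata/.

suppressMessages(library(cernet))

cfg <- sim_config(seed = 20L)
sim <- simulate_dataset(cfg, "results/simdata")

message(sprintf(
  "Simulated %d mRNAs, %d lncRNAs, %d miRNAs over %d + %d replicates",
  cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna, cfg$reps_per_group,
  cfg$reps_per_group))
message(sprintf(
  "Planted: %d DE features (|log2FC| = %g), %d ceRNA triplets, %d trans pairs, %d cis placements",
  nrow(sim$truth$de_features), cfg$planted_lfc,
  nrow(sim$truth$planted_triplets), nrow(sim$truth$planted_trans_pairs),
  nrow(sim$truth$cis_pair_truth)))
message("Cis lncRNA-gene distances (bp): ",
        paste(sim$truth$cis_pair_truth$distance, collapse = ", "))
message("Outputs in results/simdata/")
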