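test_that("annotation places features and engineered cis pairs by construction", {
  cfg <- sim_config(n_mrna = 5, n_lncrna = 3, n_mirna = 2, n_triplets = 1,
                    n_trans_pairs = 1, cis_pair_distances = c(100000L),
                    seed = 5)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 10L)
  expect_equal(table(ann$biotype)[["mRNA"]], 5L)
  cis <- attr(ann, "cis_truth")
  expect_equal(nrow(cis), 1L)
  expect_equal(cis$distance, 100000L)
  l <- ann[ann$transcript_id == cis$lncrna_id, ]
  g <- ann[ann$transcript_id == cis$gene_id, ]
  expect_equal(l$chrom, g$chrom)
  expect_equal(max(l$start, g$start) - min(l$end, g$end), 100000L)
  # structural guarantees for downstream filtering
  lncs <- ann[ann$biotype == "lncRNA", ]
  expect_true(all(lncs$length > 200L & lncs$n_exons >= 2L))
  expect_true(all(ann$start <= ann$end))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("planted sequence content is where the truth says it is", {
  sim <- cached_sim("tiny", tiny_config())
  truth <- sim$truth; seqs <- sim$sequences
  for (i in seq_len(nrow(truth$planted_sites))) {
    s <- truth$planted_sites[i, ]
    mi <- seqs$mirna[[s$mirna_id]]
    target <- if (s$target_id %in% names(seqs$mrna))
      seqs$mrna[[s$target_id]] else seqs$lncrna[[s$target_id]]
    expect_identical(substring(target, s$position,
                               s$position + nchar(mi) - 1L),
                     dna_revcomp(mi))
  }
  for (i in seq_len(nrow(truth$planted_trans_pairs))) {
    tp <- truth$planted_trans_pairs[i, ]
    lnc <- seqs$lncrna[[tp$lncrna_id]]
    mrna <- seqs$mrna[[tp$mrna_id]]
    stretch <- substring(lnc, tp$lnc_start,
                         tp$lnc_start + tp$stretch_len - 1L)
    expect_true(grepl(dna_revcomp(stretch), mrna, fixed = TRUE))
  }
  # every planted triplet has sites on both of its targets
  tt <- truth$planted_triplets
  skey <- paste(truth$planted_sites$mirna_id, truth$planted_sites$target_id)
  expect_true(all(paste(tt$mirna_id, tt$mrna_id) %in% skey))
  expect_true(all(paste(tt$mirna_id, tt$lncrna_id) %in% skey))
})

test_that("counts have the planted design: dims, integrality, group ratio", {
  sim <- cached_sim("tiny", tiny_config())
  cfg <- sim$config
  for (cls in c("mrna", "mirna", "lncrna")) {
    m <- sim$counts[[cls]]$counts
    expect_equal(ncol(m), 2L * cfg$reps_per_group)
    expect_true(all(m >= 0 & m == round(m)))
  }
  expect_equal(nrow(sim$counts$mrna$counts), cfg$n_mrna)
})

test_that("zero-dispersion mode is exactly degenerate", {
  sim0 <- cached_sim("noiseless", noiseless_config())
  m <- sim0$counts$mrna$counts
  norm <- sweep(m, 2, size_factors(sim0$counts$mrna), `/`)
  expect_identical(norm[, 1], norm[, 2])
  expect_identical(norm[, 4], norm[, 5])
  # planted triplet pairwise correlations are exactly +-1
  for (i in seq_len(nrow(sim0$truth$planted_triplets))) {
    t3 <- sim0$truth$planted_triplets[i, ]
    xm <- sim0$counts$mrna$counts[t3$mrna_id, ]
    xl <- sim0$counts$lncrna$counts[t3$lncrna_id, ]
    xi <- sim0$counts$mirna$counts[t3$mirna_id, ]
    expect_equal(cor(xm, xl), 1)
    expect_equal(cor(xi, xm), -1)
    expect_equal(cor(xi, xl), -1)
  }
})

test_that("planted log2 fold changes are recovered in the noiseless limit", {
  sim0 <- cached_sim("noiseless", noiseless_config())
  for (cls in c("mrna", "mirna", "lncrna")) {
    de <- de_test(sim0$counts[[cls]])
    planted <- de[de$feature_id %in% sim0$truth$de_features$feature_id, ]
    if (!nrow(planted)) next
    expect_lt(max(abs(abs(planted$log2fc) - sim0$config$planted_lfc)), 0.1)
  }
})

test_that("truth file round-trips losslessly, including the empty truth", {
  sim <- cached_sim("tiny", tiny_config())
  p <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, p)
  expect_equal(read_truth(p), sim$truth)
  empty <- sim$truth
  for (part in names(empty)) empty[[part]] <- empty[[part]][0, , drop = FALSE]
  write_truth(empty, p)
  back <- read_truth(p)
  expect_equal(vapply(back, nrow, 0L), vapply(empty, nrow, 0L))
})

test_that("truth counts match the configuration", {
  sim <- cached_sim("tiny", tiny_config())
  expect_equal(nrow(sim$truth$planted_triplets), sim$config$n_triplets)
  expect_equal(nrow(sim$truth$planted_sites), 2L * sim$config$n_triplets)
  expect_equal(nrow(sim$truth$planted_trans_pairs), sim$config$n_trans_pairs)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(reps_per_group = 1), "reps_per_group")
  expect_error(sim_config(nb_dispersion = -0.1), "dispersion")
  expect_error(sim_config(planted_de_fraction = 1.5), "planted_de_fraction")
  expect_error(sim_config(n_triplets = 999), "n_triplets")
  expect_error(generate_annotation(sim_config(chrom_length = 1e6)),
               "too short")
})
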