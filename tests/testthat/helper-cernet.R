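# Shared fixtures: small configurations so each test file stays fast.

tiny_config <- function(...) {
  sim_config(n_mrna = 60, n_lncrna = 25, n_mirna = 15, n_triplets = 8,
             n_trans_pairs = 4, seed = 101, ...)
}

# Exact degenerate mode: deterministic means, no latent factor.
noiseless_config <- function(...) {
  tiny_config(nb_dispersion = 0, latent_sd = 0, ...)
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_dataset(cfg)
  .sim_cache[[key]]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dna_revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "", fixed = TRUE)[[1]])),
        collapse = "")
}

# Integer vectors with Pearson r exactly 4/5 (x sums 0, y = 4x + 3z with z
# orthogonal to x and ||z|| = ||x||).
r08_pair <- function() list(x = c(-2, -1, 0, 1, 2), y = c(-5, -10, 0, 10, 5))
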