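# Closed-form maximal score for a perfect full-length complement:
# every position is a Watson-Crick match (+5), seed positions 2-8 doubled
# by the default weight 4 -> 5*(L-7) + 20*7.
perfect_score <- function(L, match = 5, seed_w = 4) {
  match * (L - 7) + match * seed_w * 7
}

test_that("a planted perfect complement yields exactly one maximal site", {
  set.seed(11)
  mi <- random_dna(22)
  flank1 <- random_dna(120); flank2 <- random_dna(160)
  target <- paste0(flank1, dna_revcomp(mi), flank2)
  sites <- mirna_scan(mi, target)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$target_start, 121L)
  expect_equal(sites$target_end, 142L)
  expect_true(sites$seed_perfect)
  expect_equal(sites$align_score, perfect_score(22))
  # energy equals the full-duplex nearest-neighbor sum
  pair_list <- paste0(strsplit(mi, "")[[1]],
                      rev(strsplit(dna_revcomp(mi), "")[[1]]))
  expect_equal(sites$delta_g, duplex_energy(pair_list))
  expect_lt(sites$delta_g, -30)
})

test_that("the target equal to the miRNA itself is not a site", {
  set.seed(12)
  mi <- random_dna(22)
  expect_equal(nrow(mirna_scan(mi, paste0(random_dna(100), mi,
                                          random_dna(100)))), 0L)
})

test_that("strict seed rejects a GU wobble forced at miRNA position 4", {
  set.seed(13)
  mi <- random_dna(22)
  substr(mi, 4, 4) <- "G"  # ensure a G at seed position 4
  rc <- strsplit(dna_revcomp(mi), "")[[1]]
  # miRNA position 4 pairs target base at rc index 22 - 4 + 1 = 19;
  # replacing the complementary C by T makes a G:U wobble there
  rc[19] <- "T"
  target <- paste0(random_dna(80), paste(rc, collapse = ""), random_dna(80))
  expect_equal(nrow(mirna_scan(mi, target)), 0L)
  relaxed <- mirna_scan(mi, target, strict_seed = FALSE, dg_max = -20,
                        s_min = 100)
  expect_gte(nrow(relaxed), 1L)
  expect_false(any(relaxed$seed_perfect))
})

test_that("tightening thresholds never adds sites", {
  set.seed(14)
  mi <- random_dna(22)
  target <- paste0(random_dna(50), dna_revcomp(mi), random_dna(50))
  base <- mirna_scan(mi, target, s_min = 100, dg_max = -20,
                     strict_seed = FALSE)
  tighter_s <- mirna_scan(mi, target, s_min = 180, dg_max = -20,
                          strict_seed = FALSE)
  tighter_g <- mirna_scan(mi, target, s_min = 100, dg_max = -40,
                          strict_seed = FALSE)
  key <- function(s) paste(s$target_start, s$target_end)
  expect_true(all(key(tighter_s) %in% key(base)))
  expect_true(all(key(tighter_g) %in% key(base)))
  expect_lte(nrow(tighter_s), nrow(base))
  expect_lte(nrow(tighter_g), nrow(base))
})

test_that("a minus-strand site appears at reflected coordinates", {
  set.seed(15)
  mi <- random_dna(22)
  # plant the miRNA sequence itself: no site on the plus strand, but the
  # reverse complement of the target carries a perfect complement at the
  # reflected position n - x + 1
  target <- paste0(random_dna(70), mi, random_dna(30))
  n <- nchar(target)
  expect_equal(nrow(mirna_scan(mi, target)), 0L)
  minus <- mirna_scan(mi, dna_revcomp(target))
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$target_start, n - (70L + 22L) + 1L)
  expect_equal(minus$target_end, n - 71L + 1L)
  expect_equal(minus$align_score, perfect_score(22))
})

test_that("miRNA length contract is enforced", {
  expect_error(mirna_scan("ACGT", random_dna(50, seed = 1)), "seed span")
  expect_error(mirna_scan(random_dna(30, seed = 2), random_dna(50, seed = 3)),
               "18-26")
  expect_error(mirna_scan(random_dna(22, seed = 4), ""), "empty")
})

test_that("trans scan finds planted stretches and honors the 10-bp minimum", {
  set.seed(16)
  mrna <- random_dna(200)
  window <- substring(mrna, 101, 115)  # 15 nt
  lnc <- paste0(random_dna(60), dna_revcomp(window), random_dna(60))
  hits <- trans_duplex_scan(lnc, mrna, energy_cutoff = 0)
  expect_gte(nrow(hits), 1L)
  expect_gte(max(hits$stretch_len), 15L)
  # a 9-bp perfect stretch is below the minimum -> no hit (the bare
  # stretch cannot extend by chance pairing into flanking sequence)
  w9 <- substring(mrna, 101, 109)
  expect_equal(nrow(trans_duplex_scan(dna_revcomp(w9), mrna,
                                      energy_cutoff = 0)), 0L)
  expect_error(trans_duplex_scan("", mrna), "empty")
})

test_that("trans stretches equal a brute-force substring-complement oracle", {
  brute_force_stretches <- function(a, b, min_len) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    pairs_ok <- outer(ac, bc, function(x, y) comp[x] == y)
    hits <- NULL
    # a[i..] pairs antiparallel with b[..j]: walk (i+1, j-1) diagonals
    for (i in seq_along(ac)) for (j in seq_along(bc)) {
      if (!pairs_ok[i, j]) next
      prev_ok <- i > 1 && j < length(bc) && pairs_ok[i - 1, j + 1]
      if (prev_ok) next  # not maximal at the left end
      len <- 0
      while (i + len <= length(ac) && j - len >= 1 &&
             pairs_ok[i + len, j - len]) len <- len + 1
      if (len >= min_len)
        hits <- rbind(hits, data.frame(lnc_start = i, lnc_end = i + len - 1,
                                       mrna_start = j - len + 1,
                                       mrna_end = j, stretch_len = len))
    }
    hits
  }
  set.seed(17)
  for (rep in 1:5) {
    a <- random_dna(150); b <- random_dna(200)
    # implant one 12-mer complement so there is something to find
    w <- substring(b, 50, 61)
    a <- paste0(substring(a, 1, 40), dna_revcomp(w), substring(a, 53, 150))
    got <- trans_duplex_scan(a, b, min_stretch = 8, energy_cutoff = 0)
    want <- brute_force_stretches(a, b, 8)
    key <- function(d) sort(paste(d$lnc_start, d$lnc_end, d$mrna_start,
                                  d$mrna_end))
    expect_equal(key(got), key(want))
  }
})

test_that("trans energies follow the duplex model and the cutoff filters", {
  set.seed(18)
  mrna <- random_dna(400)
  w60 <- substring(mrna, 200, 259)
  lnc <- paste0(random_dna(40), dna_revcomp(w60), random_dna(40))
  strict <- trans_duplex_scan(lnc, mrna, energy_cutoff = -100)
  expect_equal(nrow(strict), 1L)
  expect_gte(strict$stretch_len, 60L)  # chance pairing may extend the ends
  # the 15-mer from above cannot reach -100 under the Turner table
  w15 <- substring(mrna, 101, 115)
  lnc15 <- paste0(random_dna(60), dna_revcomp(w15), random_dna(60))
  expect_equal(nrow(trans_duplex_scan(lnc15, mrna, energy_cutoff = -100)), 0L)
})

test_that("scanner sensitivity is 1 on planted sites of a simulated dataset", {
  sim <- cached_sim("tiny", tiny_config())
  expect_equal(site_sensitivity(sim), 1)
})
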