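#' miRNA target-site scan (miranda-style)
#'
#' Local complementarity alignment of a miRNA (5'->3') against a target
#' transcript, scored in duplex space: Watson-Crick pair `match`, G:U wobble
#' `gu`, mismatch `mismatch`, affine gaps (`gap_open` for the first gapped
#' base, `gap_ext` after). Substitution scores over miRNA positions
#' `seed_range[1]..seed_range[2]` (the 5' seed, default 2-8) are multiplied
#' by `seed_weight` (default 4, the miranda default scale). Site free energy
#' comes from the nearest-neighbor model over the aligned pairs (gaps and
#' mismatches break stacks). A site is reported iff `S >= s_min` and
#' `delta_g <= dg_max`; with `strict_seed` the seed positions must all be
#' Watson-Crick paired with no gaps. Overlapping candidates are resolved by
#' higher S, then lower energy, then leftmost position.
#'
#' @param mirna_seq miRNA sequence, 5'->3', 18-26 nt (T and U equivalent).
#' @param target_seq Target transcript sequence, 5'->3'.
#' @param model An [nn_energy_model()].
#' @param s_min,dg_max Score and energy thresholds (defaults 150 and -30
#'   kcal/mol).
#' @param strict_seed Require perfect Watson-Crick, ungapped pairing over
#'   the seed (default TRUE).
#' @param match,gu,mismatch,gap_open,gap_ext Alignment scores.
#' @param seed_weight,seed_range 5' weighting factor and the (1-based,
#'   inclusive) miRNA positions it covers.
#' @param mirna_id,target_id Ids copied into the output.
#' @return data.frame of binding sites: `mirna_id`, `target_id`,
#'   `target_start`, `target_end` (1-based closed, on the target),
#'   `align_score`, `delta_g`, `seed_perfect`.
#' @export
mirna_scan <- function(mirna_seq, target_seq, model = nn_energy_model(),
                       s_min = 150, dg_max = -30, strict_seed = TRUE,
                       match = 5, gu = 1, mismatch = -3,
                       gap_open = -9, gap_ext = -4,
                       seed_weight = 4, seed_range = c(2L, 8L),
                       mirna_id = "mirna", target_id = "target") {
  q <- chartr("U", "T", toupper(mirna_seq))
  tg <- chartr("U", "T", toupper(target_seq))
  if (nchar(q) < seed_range[2])
    stop("miRNA shorter than the seed span", call. = FALSE)
  if (nchar(q) < 18L || nchar(q) > 26L)
    stop("miRNA length must be 18-26 nt", call. = FALSE)
  if (!nzchar(tg)) stop("empty target sequence", call. = FALSE)
  n <- nchar(tg)
  t_rev <- paste(rev(strsplit(tg, "", fixed = TRUE)[[1]]), collapse = "")
  cand <- sw_scan_cpp(q, t_rev, match, gu, mismatch, gap_open, gap_ext,
                      seed_range[1], seed_range[2], seed_weight, s_min)
  k <- length(cand$score)
  if (!k) return(empty_site_frame())
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    qa <- strsplit(cand$query_aln[[i]], "", fixed = TRUE)[[1]]
    ta <- strsplit(cand$target_aln[[i]], "", fixed = TRUE)[[1]]
    qpos <- cumsum(qa != "-") + cand$q_start[[i]] - 1L
    in_seed <- qa != "-" & qpos >= seed_range[1] & qpos <= seed_range[2]
    seed_cols_ok <- ta[in_seed] != "-" &
      pair_class(qa[in_seed], ta[in_seed]) %in% "wc"
    seed_perfect <- cand$q_start[[i]] <= seed_range[1] &&
      cand$q_end[[i]] >= seed_range[2] && all(seed_cols_ok)
    dg <- aligned_duplex_energy(cand$query_aln[[i]], cand$target_aln[[i]],
                                model)
    rows[[i]] <- data.frame(
      mirna_id = mirna_id, target_id = target_id,
      target_start = n - cand$j_end[[i]] + 1L,
      target_end = n - cand$j_start[[i]] + 1L,
      align_score = cand$score[[i]], delta_g = dg,
      seed_perfect = seed_perfect, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  sites <- sites[sites$align_score >= s_min & sites$delta_g <= dg_max, ,
                 drop = FALSE]
  if (strict_seed) sites <- sites[sites$seed_perfect, , drop = FALSE]
  if (!nrow(sites)) return(empty_site_frame())
  # overlap resolution: higher S, then lower energy, then leftmost
  sites <- sites[order(-sites$align_score, sites$delta_g,
                       sites$target_start), , drop = FALSE]
  keep <- logical(nrow(sites))
  covered_lo <- integer(0); covered_hi <- integer(0)
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$target_start[i]; e0 <- sites$target_end[i]
    if (!any(s0 <= covered_hi & e0 >= covered_lo)) {
      keep[i] <- TRUE
      covered_lo <- c(covered_lo, s0); covered_hi <- c(covered_hi, e0)
    }
  }
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$target_start), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_site_frame <- function() {
  data.frame(mirna_id = character(), target_id = character(),
             target_start = integer(), target_end = integer(),
             align_score = numeric(), delta_g = numeric(),
             seed_perfect = logical(), stringsAsFactors = FALSE)
}

#' Scan a set of miRNAs against a set of targets
#'
#' Convenience wrapper running [mirna_scan()] over every miRNA x target
#' combination and binding the per-pair site tables.
#'
#' @param mirnas,targets Named character vectors of sequences.
#' @param ... Passed to [mirna_scan()].
#' @return Combined binding-site data.frame.
#' @export
scan_mirna_set <- function(mirnas, targets, ...) {
  out <- list()
  for (mi in names(mirnas))
    for (tg in names(targets))
      out[[length(out) + 1L]] <-
        mirna_scan(mirnas[[mi]], targets[[tg]], mirna_id = mi,
                   target_id = tg, ...)
  if (!length(out)) return(empty_site_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' lncRNA-mRNA trans duplex scan
#'
#' Finds maximal exactly-complementary stretches between a lncRNA and an
#' mRNA (Watson-Crick pairs; G:U optionally with `allow_gu`) by diagonal
#' scanning against the reverse complement. Stretches shorter than
#' `min_stretch` are discarded; each remaining stretch's free energy is the
#' nearest-neighbor [duplex_energy()] of its base pairs, and a hit is
#' reported iff that energy is at most `energy_cutoff`. Hits are sorted by
#' energy ascending.
#'
#' @param lnc_seq,mrna_seq Sequences, 5'->3'.
#' @param model An [nn_energy_model()].
#' @param min_stretch Minimum number of consecutive base pairs (default 10).
#' @param energy_cutoff Maximum free energy for a hit (default -100; units
#'   follow the energy model, kcal/mol here).
#' @param allow_gu Allow G:U wobbles inside stretches (default FALSE).
#' @param lncrna_id,mrna_id Ids copied into the output.
#' @return data.frame: `lncrna_id`, `mrna_id`, `lnc_start`, `lnc_end`,
#'   `mrna_start`, `mrna_end`, `stretch_len`, `energy`.
#' @export
trans_duplex_scan <- function(lnc_seq, mrna_seq, model = nn_energy_model(),
                              min_stretch = 10, energy_cutoff = -100,
                              allow_gu = FALSE,
                              lncrna_id = "lncrna", mrna_id = "mrna") {
  a <- chartr("U", "T", toupper(lnc_seq))
  b <- chartr("U", "T", toupper(mrna_seq))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  b_rc <- revcomp(b)
  runs <- diag_runs_cpp(a, b_rc, allow_gu, as.integer(min_stretch))
  k <- length(runs$len)
  if (!k) return(empty_duplex_frame())
  m <- nchar(b)
  out <- data.frame(
    lncrna_id = lncrna_id, mrna_id = mrna_id,
    lnc_start = runs$a_start, lnc_end = runs$a_start + runs$len - 1L,
    mrna_start = m - (runs$b_rc_start + runs$len - 1L) + 1L,
    mrna_end = m - runs$b_rc_start + 1L,
    stretch_len = runs$len, energy = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    top <- substring(a, out$lnc_start[i], out$lnc_end[i])
    bot_rc <- substring(b_rc, runs$b_rc_start[i],
                        runs$b_rc_start[i] + runs$len[i] - 1L)
    tt <- strsplit(top, "", fixed = TRUE)[[1]]
    bb <- chartr("ACGT", "TGCA", strsplit(bot_rc, "", fixed = TRUE)[[1]])
    out$energy[i] <- duplex_energy(paste0(tt, bb), model)
  }
  out <- out[out$energy <= energy_cutoff, , drop = FALSE]
  out <- out[order(out$energy, out$lnc_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_duplex_frame <- function() {
  data.frame(lncrna_id = character(), mrna_id = character(),
             lnc_start = integer(), lnc_end = integer(),
             mrna_start = integer(), mrna_end = integer(),
             stretch_len = integer(), energy = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname trans_duplex_scan
#' @param lncrnas,mrnas Named character vectors of sequences for the set
#'   version, which scans every lncRNA x mRNA combination.
#' @param ... Passed to `trans_duplex_scan`.
#' @export
scan_trans_set <- function(lncrnas, mrnas, ...) {
  out <- list()
  for (ln in names(lncrnas))
    for (mr in names(mrnas))
      out[[length(out) + 1L]] <-
        trans_duplex_scan(lncrnas[[ln]], mrnas[[mr]], lncrna_id = ln,
                          mrna_id = mr, ...)
  if (!length(out)) return(empty_duplex_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
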