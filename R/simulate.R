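#' Simulation configuration for a planted ceRNA dataset
#'
#' Defines the study conditions the generator emulates: a two-group design
#' with `reps_per_group` replicates per group, negative-binomial counts for
#' three RNA classes, planted differential expression at a stated log2 fold
#' change, planted miRNA->(mRNA, lncRNA) repression triplets with implanted
#' binding sites and positive mRNA-lncRNA co-expression, implanted
#' lncRNA-mRNA complementary stretches for trans tests, and lncRNA loci at
#' controlled genomic distances from genes for cis tests.
#'
#' @param n_mrna,n_lncrna,n_mirna Feature counts per class (defaults 600,
#'   150, 80).
#' @param reps_per_group Replicates per group (default 3, as in a typical
#'   n = 3 vs n = 3 RNA-seq contrast).
#' @param planted_de_fraction Fraction of each class planted as DE beyond
#'   the triplet members (default 0.1).
#' @param planted_lfc Magnitude of the planted log2 fold change (default 3).
#' @param n_triplets Planted ceRNA triplets (default 30).
#' @param n_trans_pairs Planted lncRNA-mRNA trans stretches, taken from the
#'   first triplets (default 10; must be <= `n_triplets`).
#' @param trans_stretch_len Length of each planted complementary stretch in
#'   bp (default 60: long enough that its nearest-neighbor free energy
#'   clears the -100 trans threshold).
#' @param nb_dispersion NB dispersion alpha in `var = mu + alpha mu^2`
#'   (default 0.05). Zero selects an exact degenerate mode: deterministic
#'   means, no library-size variation.
#' @param latent_sd SD (log2 scale) of the per-triplet latent factor shared
#'   by each triplet's mRNA and lncRNA (default 0.25; set 0 for exact
#'   zero-noise tests).
#' @param mean_count_log_range Range (log2) of baseline mean counts
#'   (default `c(5, 11)`, i.e. means 32-2048).
#' @param depth_range Per-sample relative depth factors (default
#'   `c(0.7, 1.3)`; ignored in the zero-dispersion mode).
#' @param genome_n_chroms Number of synthetic chromosomes (default 3).
#' @param chrom_length Chromosome length in bp; a sizing error is raised if
#'   the requested features do not fit (default 2e8).
#' @param cis_pair_distances Base-pair offsets at which one lncRNA each is
#'   placed from a gene boundary (default straddles the 100 kb window:
#'   `c(0, 50000, 100000, 100001, 150000)`).
#' @param mrna_len,lncrna_len Transcript lengths in nt (defaults 1000, 600).
#' @param mirna_len_range Mature miRNA length range (default 21-23 nt, the
#'   dominant mature-length class).
#' @param mirna_gc_range GC-fraction range for miRNA sequences (default
#'   `c(0.45, 0.65)`, typical of mature miRNAs; keeps perfect-complement
#'   duplex energies clear of the -30 kcal/mol threshold).
#' @param group_labels Labels of the two groups (default `c("A", "B")`;
#'   fold changes are A relative to B).
#' @param seed Integer seed; the generator derives per-stage seeds from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_mrna = 600L, n_lncrna = 150L, n_mirna = 80L,
                       reps_per_group = 3L, planted_de_fraction = 0.1,
                       planted_lfc = 3, n_triplets = 30L,
                       n_trans_pairs = 10L, trans_stretch_len = 60L,
                       nb_dispersion = 0.05, latent_sd = 0.25,
                       mean_count_log_range = c(5, 11),
                       depth_range = c(0.7, 1.3),
                       genome_n_chroms = 3L, chrom_length = 2e8,
                       cis_pair_distances = c(0L, 50000L, 100000L, 100001L,
                                              150000L),
                       mrna_len = 1000L, lncrna_len = 600L,
                       mirna_len_range = c(21L, 23L),
                       mirna_gc_range = c(0.45, 0.65),
                       group_labels = c("A", "B"), seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              reps_per_group = as.integer(reps_per_group),
              planted_de_fraction = planted_de_fraction,
              planted_lfc = planted_lfc, n_triplets = as.integer(n_triplets),
              n_trans_pairs = as.integer(n_trans_pairs),
              trans_stretch_len = as.integer(trans_stretch_len),
              nb_dispersion = nb_dispersion, latent_sd = latent_sd,
              mean_count_log_range = mean_count_log_range,
              depth_range = depth_range,
              genome_n_chroms = as.integer(genome_n_chroms),
              chrom_length = chrom_length,
              cis_pair_distances = as.integer(cis_pair_distances),
              mrna_len = as.integer(mrna_len),
              lncrna_len = as.integer(lncrna_len),
              mirna_len_range = as.integer(mirna_len_range),
              mirna_gc_range = mirna_gc_range,
              group_labels = group_labels, seed = as.integer(seed))
  stopifnot(cfg$n_mrna >= 1, cfg$n_lncrna >= 1, cfg$n_mirna >= 1)
  if (cfg$reps_per_group < 2L)
    stop("reps_per_group must be >= 2 (group variance undefined below that)",
         call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$planted_de_fraction < 0 || cfg$planted_de_fraction > 1)
    stop("planted_de_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$n_triplets > min(cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna))
    stop("n_triplets exceeds a feature class", call. = FALSE)
  if (cfg$n_trans_pairs > cfg$n_triplets)
    stop("n_trans_pairs must be <= n_triplets", call. = FALSE)
  if (length(cfg$group_labels) != 2L || anyDuplicated(cfg$group_labels))
    stop("group_labels must be two distinct labels", call. = FALSE)
  if (cfg$seed < 0 || cfg$seed > 2^31 - 10)
    stop("seed out of range", call. = FALSE)
  if (cfg$n_lncrna < length(cfg$cis_pair_distances) ||
      cfg$n_mrna < length(cfg$cis_pair_distances))
    stop("not enough features to host the requested cis pairs", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

feature_ids <- function(cfg) {
  list(mrna = sprintf("m%04d", seq_len(cfg$n_mrna)),
       lncrna = sprintf("l%04d", seq_len(cfg$n_lncrna)),
       mirna = sprintf("mi%03d", seq_len(cfg$n_mirna)))
}

#' Generate the synthetic annotation
#'
#' Places mRNA genes, lncRNA loci and miRNA loci on synthetic chromosomes.
#' Genes are spaced widely (300 kb) so only the engineered pairs are close;
#' for each entry `d` of `cis_pair_distances` one lncRNA is placed exactly
#' `d` bp from a gene boundary (d = 0 overlaps the gene). All mRNAs have
#' two exons summing to `mrna_len`; all lncRNAs have two exons summing to
#' `lncrna_len` (> 200 nt), so every lncRNA passes structural candidate
#' filtering by construction.
#'
#' @param config A [sim_config()].
#' @return Transcript data.frame (as from [read_gtf()]) with an attribute
#'   `cis_truth`: data.frame (`lncrna_id`, `gene_id`, `distance`).
#' @export
generate_annotation <- function(config) {
  cfg <- config
  ids <- feature_ids(cfg)
  gene_spacing <- 300000L
  per_chrom <- ceiling(cfg$n_mrna / cfg$genome_n_chroms)
  if (per_chrom * gene_spacing + 1500000 > cfg$chrom_length)
    stop("chromosome too short to host the requested features", call. = FALSE)

  two_exons <- function(start, total_len, intron = 200L) {
    e1 <- total_len %/% 2L
    cbind(start = c(start, start + e1 + intron),
          end = c(start + e1 - 1L, start + total_len + intron - 1L))
  }
  rec <- list()
  gene_pos <- data.frame(id = ids$mrna, chrom = "", start = 0L, end = 0L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_mrna)) {
    chrom <- paste0("chr", ((i - 1L) %% cfg$genome_n_chroms) + 1L)
    slot <- (i - 1L) %/% cfg$genome_n_chroms
    start <- slot * gene_spacing + 100000L
    ex <- two_exons(start, cfg$mrna_len)
    rec[[length(rec) + 1L]] <- list(
      transcript_id = ids$mrna[i], gene_id = paste0("g", ids$mrna[i]),
      biotype = "mRNA", chrom = chrom, strand = "+",
      start = min(ex), end = max(ex), n_exons = nrow(ex),
      length = sum(ex[, "end"] - ex[, "start"] + 1L), exons = ex)
    gene_pos$chrom[i] <- chrom
    gene_pos$start[i] <- min(ex); gene_pos$end[i] <- max(ex)
  }

  lnc_span <- cfg$lncrna_len + 200L  # two exons + intron
  n_cis <- length(cfg$cis_pair_distances)
  cis_truth <- data.frame(lncrna_id = character(), gene_id = character(),
                          distance = integer(), stringsAsFactors = FALSE)
  for (j in seq_len(cfg$n_lncrna)) {
    id <- ids$lncrna[j]
    if (j <= n_cis) {
      d <- cfg$cis_pair_distances[j]
      g <- gene_pos[j, ]
      if (d == 0L) {
        start <- g$start + 10L           # overlap the gene
      } else {
        start <- g$end + d               # boundary gap of exactly d bp
        if (start + lnc_span > cfg$chrom_length)
          stop("chromosome too short for cis distance ", d, call. = FALSE)
      }
      chrom <- g$chrom
      cis_truth <- rbind(cis_truth, data.frame(
        lncrna_id = id, gene_id = ids$mrna[j], distance = d,
        stringsAsFactors = FALSE))
    } else {
      # far from every gene: beyond the gene region by >= 500 kb
      chrom <- paste0("chr", ((j - 1L) %% cfg$genome_n_chroms) + 1L)
      start <- per_chrom * gene_spacing + 600000L +
        ((j - 1L) %/% cfg$genome_n_chroms) * 250000L
      if (start + lnc_span > cfg$chrom_length)
        stop("chromosome too short to host the requested features",
             call. = FALSE)
    }
    ex <- two_exons(start, cfg$lncrna_len)
    rec[[length(rec) + 1L]] <- list(
      transcript_id = id, gene_id = paste0("g", id), biotype = "lncRNA",
      chrom = chrom, strand = "+", start = min(ex), end = max(ex),
      n_exons = nrow(ex), length = sum(ex[, "end"] - ex[, "start"] + 1L),
      exons = ex)
  }

  mir_base <- per_chrom * gene_spacing + 600000L +
    ceiling(cfg$n_lncrna / cfg$genome_n_chroms) * 250000L + 500000L
  mir_len <- cfg$mirna_len_range[2]
  for (k in seq_len(cfg$n_mirna)) {
    chrom <- paste0("chr", ((k - 1L) %% cfg$genome_n_chroms) + 1L)
    start <- mir_base + ((k - 1L) %/% cfg$genome_n_chroms) * 5000L
    if (start + mir_len > cfg$chrom_length)
      stop("chromosome too short to host the requested features",
           call. = FALSE)
    ex <- cbind(start = start, end = start + mir_len - 1L)
    rec[[length(rec) + 1L]] <- list(
      transcript_id = ids$mirna[k], gene_id = paste0("g", ids$mirna[k]),
      biotype = "miRNA", chrom = chrom, strand = "+", start = start,
      end = start + mir_len - 1L, n_exons = 1L, length = mir_len, exons = ex)
  }
  ann <- transcript_frame(rec)
  attr(ann, "cis_truth") <- cis_truth
  ann
}

#' Plan the planted ground truth
#'
#' Chooses the DE features, ceRNA triplets, binding-site positions and
#' trans stretches, consistent with a generated annotation. Cis-engineered
#' lncRNA/gene pairs are planted DE with a shared direction so that their
#' co-expression qualifies; triplet members are drawn from the remaining
#' features, the miRNA DE in one direction and both targets in the other;
#' background DE features fill up to `planted_de_fraction` per class.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The [sim_config()].
#' @return A `cerna_truth` list: `de_features` (feature_id, lfc),
#'   `planted_triplets`, `planted_sites` (with target positions),
#'   `planted_trans_pairs` (with lncRNA/mRNA window starts) and
#'   `cis_pair_truth`.
#' @export
make_truth <- function(annotation, config) {
  cfg <- config
  set.seed(cfg$seed)
  ids <- feature_ids(cfg)
  cis <- attr(annotation, "cis_truth")
  de <- list()
  add_de <- function(de, id, lfc) { de[[id]] <- lfc; de }

  for (i in seq_len(nrow(cis))) {
    s <- sample(c(-1, 1), 1)
    de <- add_de(de, cis$lncrna_id[i], s * cfg$planted_lfc)
    de <- add_de(de, cis$gene_id[i], s * cfg$planted_lfc)
  }

  free_m <- setdiff(ids$mrna, names(de))
  free_l <- setdiff(ids$lncrna, names(de))
  trip_m <- sample(free_m, cfg$n_triplets)
  trip_l <- sample(free_l, cfg$n_triplets)
  trip_mi <- sample(ids$mirna, cfg$n_triplets)
  trip_sign <- sample(c(-1, 1), cfg$n_triplets, replace = TRUE)
  for (t in seq_len(cfg$n_triplets)) {
    de <- add_de(de, trip_mi[t], trip_sign[t] * cfg$planted_lfc)
    de <- add_de(de, trip_m[t], -trip_sign[t] * cfg$planted_lfc)
    de <- add_de(de, trip_l[t], -trip_sign[t] * cfg$planted_lfc)
  }

  for (class_ids in ids) {
    free <- setdiff(class_ids, names(de))
    n_extra <- max(0L, round(cfg$planted_de_fraction * length(class_ids)) -
                     sum(names(de) %in% setdiff(class_ids, free)))
    n_extra <- min(n_extra, length(free))
    if (n_extra > 0)
      for (id in sample(free, n_extra))
        de <- add_de(de, id, sample(c(-1, 1), 1) * cfg$planted_lfc)
  }

  # binding-site positions: first half of the target, away from the ends
  site_pos <- function(target_len, site_len) {
    lo <- 30L; hi <- max(lo, target_len %/% 2L - site_len)
    sample(lo:hi, 1L)
  }
  mir_len <- cfg$mirna_len_range[2]  # upper bound; trimmed at planting
  sites <- data.frame(
    mirna_id = rep(trip_mi, 2L),
    target_id = c(trip_m, trip_l),
    position = c(vapply(seq_len(cfg$n_triplets),
                        function(i) site_pos(cfg$mrna_len, mir_len + 3L), 0L),
                 vapply(seq_len(cfg$n_triplets),
                        function(i) site_pos(cfg$lncrna_len, mir_len + 3L), 0L)),
    stringsAsFactors = FALSE)

  # trans stretches live in the second half of both sequences
  n_tp <- cfg$n_trans_pairs
  trans <- data.frame(
    lncrna_id = trip_l[seq_len(n_tp)], mrna_id = trip_m[seq_len(n_tp)],
    stretch_len = rep(cfg$trans_stretch_len, n_tp),
    lnc_start = rep(cfg$lncrna_len %/% 2L + 20L, n_tp),
    mrna_start = rep(cfg$mrna_len %/% 2L + 20L, n_tp),
    stringsAsFactors = FALSE)
  if (n_tp > 0 &&
      (cfg$lncrna_len %/% 2L + 20L + cfg$trans_stretch_len > cfg$lncrna_len ||
       cfg$mrna_len %/% 2L + 20L + cfg$trans_stretch_len > cfg$mrna_len))
    stop("planted trans stretch longer than its host sequence", call. = FALSE)

  truth <- list(
    de_features = data.frame(feature_id = names(de),
                             lfc = as.numeric(unlist(de)),
                             stringsAsFactors = FALSE),
    planted_triplets = data.frame(mrna_id = trip_m, mirna_id = trip_mi,
                                  lncrna_id = trip_l,
                                  stringsAsFactors = FALSE),
    planted_sites = sites,
    planted_trans_pairs = trans,
    cis_pair_truth = cis)
  class(truth) <- "cerna_truth"
  truth
}

#' Generate transcript and miRNA sequences with planted sites
#'
#' Sequences are uniform random over A/C/G/T except for the engineered
#' content: each planted site region of a target carries the exact reverse
#' complement of the full miRNA (a strict-seed, maximal-score,
#' low-free-energy site by construction) and each planted trans pair shares
#' an exact `trans_stretch_len` reverse-complement stretch. miRNAs are
#' 21-23 nt with GC fraction inside `mirna_gc_range`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [make_truth()].
#' @param config The [sim_config()].
#' @return List of named character vectors: `mrna`, `lncrna`, `mirna`.
#' @export
generate_sequences <- function(annotation, truth, config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  ids <- feature_ids(cfg)
  mirna <- vapply(ids$mirna, function(id) {
    len <- sample(seq(cfg$mirna_len_range[1], cfg$mirna_len_range[2]), 1L)
    n_gc <- round(len * stats::runif(1, cfg$mirna_gc_range[1],
                                     cfg$mirna_gc_range[2]))
    paste(sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
                   sample(c("A", "T"), len - n_gc, replace = TRUE))),
          collapse = "")
  }, "")

  lens <- stats::setNames(annotation$length, annotation$transcript_id)
  mrna <- vapply(ids$mrna, function(id) rand_seq(lens[[id]]), "")
  lncrna <- vapply(ids$lncrna, function(id) rand_seq(lens[[id]]), "")

  splice_in <- function(seq, at, piece) {
    if (at + nchar(piece) - 1L > nchar(seq))
      stop("planted segment longer than its target", call. = FALSE)
    paste0(substring(seq, 1L, at - 1L), piece,
           substring(seq, at + nchar(piece), nchar(seq)))
  }
  for (i in seq_len(nrow(truth$planted_sites))) {
    s <- truth$planted_sites[i, ]
    piece <- revcomp(mirna[[s$mirna_id]])
    if (s$target_id %in% ids$mrna) {
      mrna[[s$target_id]] <- splice_in(mrna[[s$target_id]], s$position, piece)
    } else {
      lncrna[[s$target_id]] <- splice_in(lncrna[[s$target_id]], s$position,
                                         piece)
    }
  }
  for (i in seq_len(nrow(truth$planted_trans_pairs))) {
    tp <- truth$planted_trans_pairs[i, ]
    window <- substring(mrna[[tp$mrna_id]], tp$mrna_start,
                        tp$mrna_start + tp$stretch_len - 1L)
    lncrna[[tp$lncrna_id]] <- splice_in(lncrna[[tp$lncrna_id]], tp$lnc_start,
                                        revcomp(window))
  }
  list(mrna = mrna, lncrna = lncrna, mirna = mirna)
}

#' Generate negative-binomial count matrices with the planted structure
#'
#' Counts follow `NB(mu, alpha)` with `var = mu + alpha mu^2`. Baseline
#' log2 means are uniform over `mean_count_log_range`; a planted DE feature
#' with signed log2 fold change `s` has its group-A mean multiplied by
#' `2^s` (group-mean ratio exactly `2^planted_lfc`). Each planted triplet
#' shares a per-sample Gaussian latent factor (SD `latent_sd`, log2 scale)
#' added to the means of its mRNA and lncRNA, inducing positive
#' mRNA-lncRNA correlation on top of the group separation, while the miRNA
#' moves oppositely with the groups. With `nb_dispersion = 0` the generator
#' degenerates to deterministic rounded means with no library-size
#' variation, so replicate columns within a group are identical.
#'
#' @param config The [sim_config()].
#' @param truth Output of [make_truth()].
#' @return List of three [expression_matrix()] objects: `mrna`, `mirna`,
#'   `lncrna`. Samples are `<group><rep>` for the two group labels.
#' @export
generate_counts <- function(config, truth) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  reps <- cfg$reps_per_group
  n_s <- 2L * reps
  samples <- paste0(rep(cfg$group_labels, each = reps), seq_len(reps))
  groups <- stats::setNames(rep(cfg$group_labels, each = reps), samples)
  is_a <- rep(c(1, 0), each = reps)  # group A indicator per sample

  exact <- cfg$nb_dispersion == 0
  depth <- if (exact) rep(1, n_s) else
    stats::runif(n_s, cfg$depth_range[1], cfg$depth_range[2])

  lfc_of <- stats::setNames(truth$de_features$lfc,
                            truth$de_features$feature_id)
  ids <- feature_ids(cfg)

  # per-triplet latent factor, shared by the triplet's mRNA and lncRNA
  latent <- matrix(0, nrow = max(1L, nrow(truth$planted_triplets)),
                   ncol = n_s)
  if (cfg$latent_sd > 0 && nrow(truth$planted_triplets) > 0)
    latent <- matrix(stats::rnorm(nrow(truth$planted_triplets) * n_s,
                                  sd = cfg$latent_sd),
                     nrow = nrow(truth$planted_triplets))
  latent_row <- function(id) {
    tp <- truth$planted_triplets
    hit <- which(tp$mrna_id == id | tp$lncrna_id == id)
    if (length(hit)) latent[hit[1], ] else rep(0, n_s)
  }

  one_class <- function(class_ids) {
    base <- stats::runif(length(class_ids), cfg$mean_count_log_range[1],
                         cfg$mean_count_log_range[2])
    m <- matrix(0, nrow = length(class_ids), ncol = n_s,
                dimnames = list(class_ids, samples))
    for (i in seq_along(class_ids)) {
      id <- class_ids[i]
      s <- if (id %in% names(lfc_of)) lfc_of[[id]] else 0
      # baseline is always the low-expression group, so the minor mean stays
      # inside mean_count_log_range and the +1 pseudocount bias is negligible
      shift <- if (s >= 0) s * is_a else -s * (1 - is_a)
      log_mu <- base[i] + shift + latent_row(id)
      mu <- 2^log_mu * depth
      m[i, ] <- if (exact) round(mu) else
        stats::rnbinom(n_s, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    expression_matrix(m, groups)
  }
  list(mrna = one_class(ids$mrna), mirna = one_class(ids$mirna),
       lncrna = one_class(ids$lncrna))
}

#' Simulate a complete planted ceRNA dataset
#'
#' Runs [generate_annotation()], [make_truth()], [generate_sequences()] and
#' [generate_counts()] in order, each stage seeded deterministically from
#' `config$seed`, and optionally writes everything to an output directory
#' (GTF, three FASTA files, three count TSVs plus a group map, the truth
#' JSON and a config echo JSON).
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @return List: `config`, `annotation`, `truth`, `sequences`, `counts`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  ann <- generate_annotation(config)
  truth <- make_truth(ann, config)
  seqs <- generate_sequences(ann, truth, config)
  counts <- generate_counts(config, truth)
  out <- list(config = config, annotation = ann, truth = truth,
              sequences = seqs, counts = counts)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(ann, file.path(outdir, "annotation.gtf"))
    write_fasta(seqs$mrna, file.path(outdir, "mrna.fa"))
    write_fasta(seqs$lncrna, file.path(outdir, "lncrna.fa"))
    write_fasta(seqs$mirna, file.path(outdir, "mirna.fa"))
    for (cls in c("mrna", "mirna", "lncrna"))
      write_counts(counts[[cls]],
                   file.path(outdir, paste0("counts_", cls, ".tsv")),
                   if (cls == "mrna") file.path(outdir, "groups.tsv"))
    write_truth(truth, file.path(outdir, "truth.json"))
    cfg_plain <- unclass(config)
    jsonlite::write_json(cfg_plain, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Write / read the planted ground truth (JSON)
#'
#' Lossless round trip: `read_truth(write_truth(t)) == t`.
#'
#' @param truth A `cerna_truth` list ([make_truth()]).
#' @param path JSON file path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- list(
    de_features = c(feature_id = "character", lfc = "numeric"),
    planted_triplets = c(mrna_id = "character", mirna_id = "character",
                         lncrna_id = "character"),
    planted_sites = c(mirna_id = "character", target_id = "character",
                      position = "integer"),
    planted_trans_pairs = c(lncrna_id = "character", mrna_id = "character",
                            stretch_len = "integer", lnc_start = "integer",
                            mrna_start = "integer"),
    cis_pair_truth = c(lncrna_id = "character", gene_id = "character",
                       distance = "integer"))
  truth <- lapply(names(schema), function(part) {
    cols <- schema[[part]]
    got <- raw[[part]]
    df <- as.data.frame(lapply(names(cols), function(cn) {
      v <- if (is.list(got) || is.data.frame(got)) got[[cn]] else NULL
      if (is.null(v)) v <- vector(cols[[cn]], 0L)
      if (cols[[cn]] == "integer") as.integer(v)
      else if (cols[[cn]] == "numeric") as.numeric(v)
      else as.character(v)
    }), optional = TRUE, stringsAsFactors = FALSE)
    names(df) <- names(cols)
    df
  })
  names(truth) <- names(schema)
  class(truth) <- "cerna_truth"
  truth
}
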