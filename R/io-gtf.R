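#' Read transcript models from a GTF file
#'
#' Parses `exon` features, aggregates them per transcript, and returns one
#' row per transcript. Coordinates follow the GTF convention throughout:
#' 1-based, closed intervals. Malformed lines are rejected with the line
#' number rather than coerced.
#'
#' @param path Path to a GTF file. Lines whose feature column is not `exon`
#'   are ignored; `#` comment lines are skipped.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`, `biotype`,
#'   `chrom`, `strand`, `start`, `end`, `n_exons`, `length` (sum of exon
#'   lengths, `end - start + 1` per exon) and a list-column `exons` of
#'   two-column matrices (start, end) sorted by start.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  rec <- vector("list", length(keep))
  n <- 0L
  for (ln in keep) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields", ln),
           call. = FALSE)
    if (f[3] != "exon") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || end < start)
      stop(sprintf("GTF parse error at line %d: bad coordinates (end < start?)", ln),
           call. = FALSE)
    if (!f[7] %in% c("+", "-"))
      stop(sprintf("GTF parse error at line %d: unknown strand '%s'", ln, f[7]),
           call. = FALSE)
    attrs <- gtf_attributes(f[9])
    if (is.na(attrs["transcript_id"]))
      stop(sprintf("GTF parse error at line %d: missing transcript_id attribute", ln),
           call. = FALSE)
    n <- n + 1L
    rec[[n]] <- list(tid = attrs[["transcript_id"]],
                     gid = if (is.na(attrs["gene_id"])) attrs[["transcript_id"]] else attrs[["gene_id"]],
                     biotype = if (is.na(attrs["biotype"])) "mRNA" else attrs[["biotype"]],
                     chrom = f[1], strand = f[7], start = start, end = end)
  }
  rec <- rec[seq_len(n)]
  if (!n) return(empty_transcript_frame())
  tid <- vapply(rec, `[[`, "", "tid")
  ord <- split(seq_len(n), factor(tid, levels = unique(tid)))
  out <- lapply(ord, function(idx) {
    r1 <- rec[[idx[1]]]
    ex <- cbind(start = vapply(rec[idx], `[[`, 0L, "start"),
                end = vapply(rec[idx], `[[`, 0L, "end"))
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, "start"] <= ex[-nrow(ex), "end"]))
      stop("overlapping exons in transcript ", r1$tid, call. = FALSE)
    list(transcript_id = r1$tid, gene_id = r1$gid, biotype = r1$biotype,
         chrom = r1$chrom, strand = r1$strand,
         start = min(ex[, "start"]), end = max(ex[, "end"]),
         n_exons = nrow(ex), length = sum(ex[, "end"] - ex[, "start"] + 1L),
         exons = ex)
  })
  transcript_frame(out)
}

gtf_attributes <- function(s) {
  m <- regmatches(s, gregexpr('(\\w+) "([^"]*)"', s))[[1]]
  keys <- sub('^(\\w+) .*$', "\\1", m)
  vals <- sub('^\\w+ "([^"]*)".*$', "\\1", m)
  stats::setNames(vals, keys)[c("transcript_id", "gene_id", "biotype")]
}

empty_transcript_frame <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             biotype = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), n_exons = integer(),
             length = integer(), exons = I(list()))
}

transcript_frame <- function(lst) {
  df <- data.frame(
    transcript_id = vapply(lst, `[[`, "", "transcript_id"),
    gene_id = vapply(lst, `[[`, "", "gene_id"),
    biotype = vapply(lst, `[[`, "", "biotype"),
    chrom = vapply(lst, `[[`, "", "chrom"),
    strand = vapply(lst, `[[`, "", "strand"),
    start = vapply(lst, function(x) as.integer(x$start), 0L),
    end = vapply(lst, function(x) as.integer(x$end), 0L),
    n_exons = vapply(lst, function(x) as.integer(x$n_exons), 0L),
    length = vapply(lst, function(x) as.integer(x$length), 0L),
    row.names = NULL)
  df$exons <- I(lapply(lst, `[[`, "exons"))
  df
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` line per exon with `gene_id`,
#' `transcript_id` and `biotype` attributes. Output is deterministic for
#' equal input (rows in input order, no timestamps).
#'
#' @param transcripts Transcript `data.frame` as returned by [read_gtf()] or
#'   [generate_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    ex <- tr$exons[[1]]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                     tr$gene_id, tr$transcript_id, tr$biotype)
    lines <- c(lines, sprintf("%s\tcernet\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom, ex[, "start"], ex[, "end"],
                              tr$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
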