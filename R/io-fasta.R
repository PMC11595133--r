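#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and RNA `U` is normalized to `T` at parse time,
#' so downstream scanners are alphabet-agnostic (they treat T as U).
#' Duplicate headers, empty sequences and non-IUPAC characters are errors.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector id -> sequence (DNA alphabet). Empty file
#'   gives an empty vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ", paste(ids[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad))
    stop("non-IUPAC characters in: ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector id -> sequence.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# Internal sequence helpers (DNA alphabet, T == U).
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)),
               use.names = FALSE)
}
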