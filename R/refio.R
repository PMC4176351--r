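#' Load a single-record reference sequence with a terminal T-tract
#'
#' Reads one FASTA record and annotates the genomically encoded terminator:
#' the run of `terminator_len` T residues at the 3' end of the coding strand
#' (the RNA's terminal U-tract).  For yeast *SCR1* the pol III termination
#' signal is T6, so the default `terminator_len` is 6.
#'
#' All coordinates in this package are 1-based and inclusive, so "nucleotide
#' 453" names the 453rd base of the reference.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param terminator_len Length of the encoded terminal T-tract (nt).
#' @return An object of class `ReferenceSeq`: a list with elements `name`,
#'   `seq` (uppercase DNA string), `length`, `terminator_start` (1-based
#'   position of the first terminator T) and `terminator_len`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "ACGTACGATTTTTT"), fa)
#' ref <- load_reference(fa, terminator_len = 6)
#' ref$terminator_start  # 9
#' @export
load_reference <- function(path, terminator_len = 6L) {
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(recs))
  seq <- normalize_seq(as.character(recs[[1L]]))
  if (grepl("[^ACGT]", seq))
    stop("reference sequence contains non-ACGT characters")
  L <- nchar(seq)
  terminator_len <- as.integer(terminator_len)
  if (terminator_len < 1L || terminator_len > L)
    stop("terminator_len must be in 1..reference length")
  tail_bases <- substring(seq, L - terminator_len + 1L, L)
  bad <- which(strsplit(tail_bases, "")[[1L]] != "T")
  if (length(bad))
    stop("terminal ", terminator_len, " bases must all be T; position ",
         L - terminator_len + bad[1L], " is ",
         substring(seq, L - terminator_len + bad[1L],
                   L - terminator_len + bad[1L]))
  structure(
    list(name = names(recs)[1L], seq = seq, length = L,
         terminator_start = L - terminator_len + 1L,
         terminator_len = terminator_len),
    class = "ReferenceSeq")
}

#' @export
print.ReferenceSeq <- function(x, ...) {
  cat("ReferenceSeq ", x$name, ": ", x$length, " nt, terminator T",
      x$terminator_len, " at ", x$terminator_start, "-", x$length, "\n",
      sep = "")
  invisible(x)
}

#' Extract reference bases by 1-based inclusive coordinates
#'
#' @param ref A `ReferenceSeq`.
#' @param start,end 1-based inclusive positions.
#' @return Character string of bases `start..end`.
#' @export
ref_segment <- function(ref, start, end) {
  stopifnot(start >= 1L, end <= ref$length, start <= end)
  substring(ref$seq, start, end)
}

# uppercase, RNA U -> DNA T
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character of the file (`>` for
#' FASTA, `@` for FASTQ).  Lowercase is uppercased and RNA U is converted to
#' T; the internal alphabet is \{A,C,G,T,N\}.  N is legal in reads: it never
#' matches any reference base and counts as non-A in tail statistics.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return A data.frame with columns `id`, `seq`, and `qual` (NA for FASTA).
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readChar(path, 1L, useBytes = TRUE)
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty input file: ", path)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (first == ">") {
    recs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                     error = function(e) stop("malformed FASTA record in ",
                                              path, ": ", conditionMessage(e)))
    qual <- rep(NA_character_, length(recs))
  } else if (first == "@") {
    recs <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("truncated or malformed FASTQ record in ",
                               path, ": ", conditionMessage(e)))
    qual <- as.character(S4Vectors::mcols(recs)$qualities)
    if (is.null(qual)) qual <- rep(NA_character_, length(recs))
  } else {
    stop("cannot auto-detect format of ", path,
         ": first character is neither '>' nor '@'")
  }
  seqs <- normalize_seq(as.character(recs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("read ", names(recs)[which(bad)[1L]],
         " contains characters outside {A,C,G,T,N,U}")
  if (any(!nzchar(seqs)))
    stop("empty sequence for record ", which(!nzchar(seqs))[1L])
  data.frame(id = sub("\\s.*$", "", names(recs)), seq = unname(seqs),
             qual = unname(qual), stringsAsFactors = FALSE)
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads A data.frame as returned by [read_fastx()].
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`; default chosen by whether qualities
#'   are present.
#' @return Invisibly, `path`.
#' @export
write_fastx <- function(reads, path,
                        format = if (all(is.na(reads$qual))) "fasta" else "fastq") {
  x <- Biostrings::BStringSet(reads$seq)
  names(x) <- reads$id
  if (format == "fastq") {
    qual <- reads$qual
    qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                                function(n) strrep("I", n), character(1))
    S4Vectors::mcols(x)$qualities <- Biostrings::BStringSet(qual)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = S4Vectors::mcols(x)$qualities)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

# reverse complement on plain character strings; N maps to N
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
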