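#' Classify a non-encoded tail as oligo(A)
#'
#' A tail is called oligo(A) when it contains at least `min_a` adenosines and
#' not more than `max_non_a_frac` non-A nucleotides.  With the defaults this
#' is the standard rule for calling TRAMP-added oligo(A) marks on
#' surveillance targets: >= 2 A's and <= 20% non-A.
#'
#' The threshold comparison is exact rational arithmetic, with no
#' floating-point rounding at the boundary: for the default 20% the verdict
#' rejects iff `(tail_len - a_count) * 5 > tail_len`.  N counts as non-A.
#'
#' @param tail Character vector of tail strings over \{A,C,G,T,N\} (may be
#'   empty strings).
#' @param min_a Minimum number of A residues (default 2).
#' @param max_non_a_frac Maximum tolerated fraction of non-A bases
#'   (default 0.20, compared as an exact rational bound).
#' @return A data.frame with one row per tail: `tail`, `tail_len`, `a_count`,
#'   `non_a_frac`, `is_oligoA`.  Empty tails have `non_a_frac = 0` and are
#'   never oligo(A).
#' @examples
#' classify_tail(c("AA", "AAG", "AAAAG", "A", ""))
#' @export
classify_tail <- function(tail, min_a = 2L, max_non_a_frac = 0.20) {
  tail <- toupper(tail)
  tail_len <- nchar(tail)
  a_count <- tail_len - nchar(gsub("A", "", tail, fixed = TRUE))
  non_a <- tail_len - a_count
  non_a_frac <- ifelse(tail_len == 0L, 0, non_a / tail_len)
  # exact rational comparison: non_a / len <= f  <=>  non_a <= f * len with
  # f expressed as a ratio; for arbitrary f use a tiny epsilon-free form via
  # rational approximation of the default, else fall back to >= comparison
  # on integers scaled by the fraction's denominator when f = p/q.
  frac_ok <- exact_frac_le(non_a, tail_len, max_non_a_frac)
  is_oligoA <- tail_len > 0L & a_count >= min_a & frac_ok
  data.frame(tail = tail, tail_len = tail_len, a_count = a_count,
             non_a_frac = non_a_frac, is_oligoA = is_oligoA,
             stringsAsFactors = FALSE)
}

# non_a / len <= frac, exactly, for frac given as a decimal with <= 6 places
exact_frac_le <- function(non_a, len, frac) {
  q <- 10L^6L
  p <- round(frac * q)
  ifelse(len == 0L, TRUE, as.numeric(non_a) * q <= as.numeric(len) * p)
}

#' Count templated terminal U residues of an alignment
#'
#' Returns the length of the maximal run of T in the reference ending exactly
#' at the alignment's genomic 3' end (`ref_end`), i.e. how many templated
#' 3'-terminal U's of the transcript the fragment retains.  Zero when
#' `ref_end` is not inside a T run.
#'
#' @param ref_end Integer vector of 1-based alignment 3' end positions.
#' @param ref A [ReferenceSeq][load_reference].
#' @return Integer vector of terminal U counts.
#' @export
count_terminal_u <- function(ref_end, ref) {
  bases <- strsplit(ref$seq, "")[[1L]]
  vapply(ref_end, function(e) {
    if (is.na(e)) return(NA_integer_)
    n <- 0L
    while (e - n >= 1L && bases[e - n] == "T") n <- n + 1L
    n
  }, integer(1))
}

#' Per-read tail calls for an alignment table
#'
#' Joins [classify_tail()] and [count_terminal_u()] over a table of
#' alignments.  Antisense and unaligned rows get `NA` calls (their tails are
#' not interpreted).
#'
#' @param alignments Alignment table from [align_reads()].
#' @param ref A [ReferenceSeq][load_reference].
#' @inheritParams classify_tail
#' @return A data.frame, one row per read: `read_id`, `tail`, `tail_len`,
#'   `a_count`, `non_a_frac`, `is_oligoA`, `terminal_u_count`.
#' @export
call_tails <- function(alignments, ref, min_a = 2L, max_non_a_frac = 0.20) {
  sense <- alignments$aligned & !is.na(alignments$strand) &
    alignments$strand == "+"
  calls <- classify_tail(ifelse(sense, alignments$tail, ""),
                         min_a = min_a, max_non_a_frac = max_non_a_frac)
  calls$terminal_u_count <- ifelse(
    sense, count_terminal_u(alignments$ref_end, ref), NA_integer_)
  calls[!sense, c("tail", "tail_len", "a_count", "non_a_frac",
                  "is_oligoA")] <- NA
  cbind(data.frame(read_id = alignments$read_id, stringsAsFactors = FALSE),
        calls)
}

#' Summarize tail calls for a read set
#'
#' @param calls Tail-call table from [call_tails()] (rows with `NA` verdicts,
#'   i.e. antisense/unaligned reads, are excluded from the tallies).
#' @return A list with elements:
#'   \describe{
#'     \item{n_aligned}{sense reads with a tail call}
#'     \item{n_with_tail}{reads with a non-empty non-encoded tail}
#'     \item{n_oligoA}{reads whose tail is called oligo(A)}
#'     \item{pct_oligoA}{percentage oligo(A) among aligned (NA when empty)}
#'     \item{u_by_oligoA}{cross-tabulation terminal U count (0..6+) by
#'       oligo(A) verdict}
#'     \item{pct_u45_among_oligoA}{percentage of oligo(A) fragments retaining
#'       4 or 5 templated terminal U's (NA when no oligo(A) fragments)}
#'   }
#' @export
tail_summary <- function(calls) {
  ok <- !is.na(calls$is_oligoA)
  calls <- calls[ok, , drop = FALSE]
  n <- nrow(calls)
  n_tail <- sum(calls$tail_len > 0L)
  n_oa <- sum(calls$is_oligoA)
  u <- pmin(calls$terminal_u_count, 6L)
  u_by <- table(factor(u, levels = 0:6),
                factor(calls$is_oligoA, levels = c(FALSE, TRUE)))
  dimnames(u_by) <- list(terminal_u = 0:6, oligoA = c("no", "yes"))
  u45_oa <- sum(calls$is_oligoA & calls$terminal_u_count %in% c(4L, 5L))
  list(
    n_aligned = n,
    n_with_tail = n_tail,
    n_oligoA = n_oa,
    pct_oligoA = if (n > 0L) 100 * n_oa / n else NA_real_,
    u_by_oligoA = u_by,
    pct_u45_among_oligoA = if (n_oa > 0L) 100 * u45_oa / n_oa else NA_real_)
}

#' Write tail calls and summary
#'
#' @param calls Tail-call table from [call_tails()].
#' @param path Output TSV path for the per-read table.
#' @param summary_path Optional JSON path for [tail_summary()] output.
#' @return Invisibly, `path`.
#' @export
write_tails <- function(calls, path, summary_path = NULL) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- tail_summary(calls)
    s$u_by_oligoA <- as.data.frame.matrix(unclass(s$u_by_oligoA))
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  }
  invisible(path)
}
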