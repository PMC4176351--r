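#' Per-nucleotide hit-density profile
#'
#' Builds the read-density track over the reference: for every position, the
#' number of aligned reads whose matched segment covers it (span counting,
#' not 5'-end counting), both for all reads and for the oligoadenylated
#' subset, with densities expressed as hits per million aligned reads.
#' Reference positions deleted from a read (crosslink-induced deletions) are
#' not covered by that read.
#'
#' The denominator is explicit because the conventional normalization is by
#' reads aligned genome-wide, which a single-reference analysis cannot see.
#' The default uses the number of reads aligned to this reference; supply the
#' genome-wide total to reproduce the conventional scale.
#'
#' @param alignments Alignment table from [align_reads()].
#' @param calls Tail-call table from [call_tails()], keyed to `alignments` by
#'   `read_id` order.
#' @param ref A [ReferenceSeq][load_reference].
#' @param n_aligned_denominator Denominator for the per-million scaling; must
#'   be at least the number of profiled reads.
#' @return A data.frame with one row per reference position: `position`,
#'   `count_total`, `count_oligoA`, `density_total`, `density_oligoA`.
#' @export
build_profile <- function(alignments, calls, ref,
                          n_aligned_denominator = NULL) {
  al <- alignments[alignments$aligned, , drop = FALSE]
  cl <- calls[match(al$read_id, calls$read_id), , drop = FALSE]
  n_prof <- nrow(al)
  if (is.null(n_aligned_denominator)) n_aligned_denominator <- n_prof
  if (n_prof > 0L && n_aligned_denominator < n_prof)
    stop("denominator (", n_aligned_denominator,
         ") is smaller than the number of profiled reads (", n_prof, ")")
  L <- ref$length
  if (n_prof > 0L && any(al$ref_end > L | al$ref_start < 1L))
    stop("alignment outside reference 1..", L)
  count_total <- integer(L)
  count_oligoA <- integer(L)
  dels <- parse_deletions(al$deletions)
  for (i in seq_len(n_prof)) {
    cov <- setdiff(seq.int(al$ref_start[i], al$ref_end[i]), dels[[i]])
    count_total[cov] <- count_total[cov] + 1L
    if (isTRUE(cl$is_oligoA[i]))
      count_oligoA[cov] <- count_oligoA[cov] + 1L
  }
  denom <- max(n_aligned_denominator, 1L)
  data.frame(position = seq_len(L),
             count_total = count_total,
             count_oligoA = count_oligoA,
             density_total = count_total / denom * 1e6,
             density_oligoA = count_oligoA / denom * 1e6)
}

#' Histogram of alignment 3' end positions
#'
#' Tabulates sense-strand alignment ends and reports the modal internal end
#' position — the most frequent 3' end lying upstream of the encoded
#' terminator, i.e. the dominant truncation point (for scR1 in surveillance
#' mutants, nucleotide 453).  Ties are broken toward the smallest position.
#'
#' @param alignments Alignment table from [align_reads()].
#' @param ref A [ReferenceSeq][load_reference].
#' @return A list: `ends` (data.frame `ref_end`, `count`) and
#'   `modal_internal_end` (integer, NA when every end lies in the
#'   terminator).
#' @export
truncation_end_histogram <- function(alignments, ref) {
  al <- alignments[alignments$aligned & alignments$strand == "+", ,
                   drop = FALSE]
  tab <- table(al$ref_end)
  ends <- data.frame(ref_end = as.integer(names(tab)),
                     count = as.integer(tab))
  internal <- ends[ends$ref_end < ref$terminator_start, , drop = FALSE]
  modal <- if (nrow(internal) == 0L) NA_integer_ else
    internal$ref_end[which.max(internal$count)]
  list(ends = ends, modal_internal_end = modal)
}

#' Write a profile as TSV and bedGraph
#'
#' bedGraph output converts the package's 1-based inclusive positions to the
#' format's 0-based half-open intervals; two tracks are written (total and
#' oligo(A) subset densities).
#'
#' @param profile Profile table from [build_profile()].
#' @param ref A [ReferenceSeq][load_reference].
#' @param path Output TSV path.
#' @param bedgraph_path Optional bedGraph output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, ref, path, bedgraph_path = NULL) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedgraph_path)) {
    lines <- c(
      sprintf("track type=bedGraph name=\"%s_density_total\"", ref$name),
      sprintf("%s\t%d\t%d\t%g", ref$name, profile$position - 1L,
              profile$position, profile$density_total),
      sprintf("track type=bedGraph name=\"%s_density_oligoA\"", ref$name),
      sprintf("%s\t%d\t%d\t%g", ref$name, profile$position - 1L,
              profile$position, profile$density_oligoA))
    writeLines(lines, bedgraph_path)
  }
  invisible(path)
}
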