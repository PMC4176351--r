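#' Adapter set for ligation-mediated RT-PCR clones
#'
#' Defaults are the two 3' cordycepin-blocked ligation oligos used for scR1
#' 3' end mapping, plus the reference interval of the gene-specific forward
#' primer (for *SCR1*, positions 233-250), used to sanity-check that clone
#' inserts start within or downstream of the primer.
#'
#' @param adapters Character vector of adapter sequences (each >= 12 nt).
#' @param anchor_primer_region Integer length-2 vector, 1-based inclusive
#'   reference interval of the forward primer.
#' @return A list of class `AdapterSet`.
#' @export
adapter_set <- function(
    adapters = c("GAACATTTTTTGGTTTAAACTAATTAACCGTCCC",
                 "GATCTAGAGGATGGATATGGTGTTCAGG"),
    anchor_primer_region = c(233L, 250L)) {
  adapters <- normalize_seq(adapters)
  stopifnot(length(adapters) >= 1L, all(nchar(adapters) >= 12L))
  structure(list(adapters = adapters,
                 anchor_primer_region = as.integer(anchor_primer_region)),
            class = "AdapterSet")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Strip the ligated 3' adapter from a clone sequence
#'
#' Locates the best adapter match nearest the clone's 3' end: an occurrence
#' of an adapter prefix of length >= 12 with at most `max_mismatch`
#' substitutions.  The insert is everything 5' of the match.
#'
#' @param clone_seq Clone sequence (insert orientation, 5'->3' of the RNA).
#' @param adapters An [adapter_set()].
#' @param max_mismatch Maximum substitutions tolerated in the adapter match.
#' @param min_overlap Minimum matched adapter prefix length.
#' @return A list: `found` (logical), `insert`, `adapter_used` (index),
#'   `adapter_start` (1-based position in the clone), `n_mismatch`, and
#'   `reason` when not found.
#' @export
strip_adapter <- function(clone_seq, adapters = adapter_set(),
                          max_mismatch = 2L, min_overlap = 12L) {
  seq <- normalize_seq(clone_seq)
  nc <- nchar(seq)
  best <- NULL
  for (ai in seq_along(adapters$adapters)) {
    ad <- adapters$adapters[ai]
    na <- nchar(ad)
    for (p in seq_len(max(nc - min_overlap + 1L, 0L))) {
      ov <- min(na, nc - p + 1L)
      if (ov < min_overlap) next
      mm <- hamming(substring(seq, p, p + ov - 1L), substring(ad, 1L, ov))
      if (mm > max_mismatch) next
      cand <- list(found = TRUE, insert = substring(seq, 1L, p - 1L),
                   adapter_used = ai, adapter_start = p, n_mismatch = mm)
      if (is.null(best) || cand$adapter_start > best$adapter_start ||
          (cand$adapter_start == best$adapter_start &&
           cand$n_mismatch < best$n_mismatch))
        best <- cand
    }
  }
  if (is.null(best))
    return(list(found = FALSE, insert = NA_character_,
                adapter_used = NA_integer_, adapter_start = NA_integer_,
                n_mismatch = NA_integer_,
                reason = "no adapter match (>= 12 nt, <= 2 mismatches)"))
  best
}

classify_end <- function(ref_end, ref) {
  L <- ref$length
  if (is.na(ref_end)) return("unmapped")
  if (ref_end < ref$terminator_start) return("truncated")
  if (ref_end == L) return("extended")
  if (ref_end >= L - 2L) return("mature")   # trim of 1-2 nt: U4-U5 on T6
  "trimmed"
}

#' Annotate the 3' end of one clone insert
#'
#' Aligns the insert to the reference with the tail-extraction aligner (so
#' the maximal-genomic-extension boundary rule applies: a non-templated A is
#' only called where the next reference base is not A — always true at a
#' T-tract end), then reads off the templated 3' end, the retained terminal
#' U-tract, and the non-templated tail.
#'
#' End classes on a T6 terminator: `mature` = trimmed by 1-2 nt (U4-U5),
#' `extended` = full terminator retained (U6), `trimmed` = end within the
#' terminator with <= 3 U's, `truncated` = end upstream of the terminator,
#' `unmapped` = unalignable.  U5 ends are classed mature; the raw U-length
#' distribution is reported alongside so the stricter convention can be read
#' off.
#'
#' @param insert Insert sequence (adapter already stripped).
#' @param ref A [ReferenceSeq][load_reference].
#' @param adapters An [adapter_set()] (for the anchor-primer check).
#' @param params [align_params()] for the insert alignment.
#' @param strict_anchor If `TRUE`, an insert whose 5' end maps upstream of
#'   the anchor primer is an error; by default it is a warning (toy
#'   references are shorter than the real primer coordinates).
#' @return A one-row data.frame: `ref_end`, `terminal_u_count`,
#'   `nontemplated_tail`, `nontemplated_a_count`, `tail_impure`,
#'   `adenylated`, `end_class`.
#' @export
annotate_clone <- function(insert, ref, adapters = adapter_set(),
                           params = align_params(), strict_anchor = FALSE) {
  insert <- normalize_seq(insert)
  if (is.na(insert) || nchar(insert) < 20L) {
    return(data.frame(ref_end = NA_integer_, terminal_u_count = NA_integer_,
                      nontemplated_tail = NA_character_,
                      nontemplated_a_count = NA_integer_,
                      tail_impure = NA, adenylated = NA,
                      end_class = "unmapped", stringsAsFactors = FALSE))
  }
  al <- align_read(list(id = "clone", seq = insert), ref, params)
  if (!al$aligned || al$strand != "+") {
    return(data.frame(ref_end = NA_integer_, terminal_u_count = NA_integer_,
                      nontemplated_tail = NA_character_,
                      nontemplated_a_count = NA_integer_,
                      tail_impure = NA, adenylated = NA,
                      end_class = "unmapped", stringsAsFactors = FALSE))
  }
  anchor <- adapters$anchor_primer_region
  if (anchor[1L] <= ref$length && al$ref_start < anchor[1L]) {
    msg <- paste0("insert 5' end (", al$ref_start,
                  ") maps upstream of the anchor primer region ",
                  anchor[1L], "-", anchor[2L])
    if (strict_anchor) stop(msg) else warning(msg)
  }
  tail <- al$tail
  a_count <- nchar(tail) - nchar(gsub("A", "", tail, fixed = TRUE))
  data.frame(
    ref_end = al$ref_end,
    terminal_u_count = count_terminal_u(al$ref_end, ref),
    nontemplated_tail = tail,
    nontemplated_a_count = a_count,
    tail_impure = nchar(tail) > a_count,
    adenylated = a_count >= 1L,
    end_class = classify_end(al$ref_end, ref),
    stringsAsFactors = FALSE)
}

#' Annotate a FASTA of clone sequences
#'
#' Runs [strip_adapter()] then [annotate_clone()] on every clone.
#'
#' @param clones A data.frame with `id` and `seq` (as from [read_fastx()]).
#' @inheritParams annotate_clone
#' @return A data.frame, one row per clone, with `clone_id`, the adapter
#'   fields, and the [annotate_clone()] columns.
#' @export
annotate_clones <- function(clones, ref, adapters = adapter_set(),
                            params = align_params(), strict_anchor = FALSE) {
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    st <- strip_adapter(clones$seq[i], adapters)
    ann <- if (st$found)
      annotate_clone(st$insert, ref, adapters, params, strict_anchor)
    else
      data.frame(ref_end = NA_integer_, terminal_u_count = NA_integer_,
                 nontemplated_tail = NA_character_,
                 nontemplated_a_count = NA_integer_, tail_impure = NA,
                 adenylated = NA, end_class = "unmapped",
                 stringsAsFactors = FALSE)
    cbind(data.frame(clone_id = clones$id[i], adapter_found = st$found,
                     adapter_used = st$adapter_used,
                     insert_len = ifelse(st$found, nchar(st$insert),
                                         NA_integer_),
                     stringsAsFactors = FALSE),
          ann)
  })
  do.call(rbind, rows)
}

#' Summarize a set of clone annotations
#'
#' @param annotations Table from [annotate_clones()].
#' @param label Optional label for the clone set (e.g. the genotype).
#' @return A list: `label`, `n`, `class_counts` (named integer vector over
#'   mature/extended/trimmed/truncated/unmapped), `n_adenylated`, `n_u45`
#'   (clones retaining 4 or 5 terminal U's), `a_count_dist` (0,1,2,3,4+) and
#'   `u_count_dist` (0..6) distributions over mapped clones.
#' @export
summarize_clone_set <- function(annotations, label = NA_character_) {
  classes <- c("mature", "extended", "trimmed", "truncated", "unmapped")
  cls <- table(factor(annotations$end_class, levels = classes))
  mapped <- annotations[annotations$end_class != "unmapped", , drop = FALSE]
  a <- pmin(mapped$nontemplated_a_count, 4L)
  a_dist <- table(factor(a, levels = 0:4))
  names(a_dist) <- c("0", "1", "2", "3", "4+")
  u_dist <- table(factor(pmin(mapped$terminal_u_count, 6L), levels = 0:6))
  list(label = label,
       n = nrow(annotations),
       class_counts = stats::setNames(as.integer(cls), classes),
       n_adenylated = sum(mapped$adenylated, na.rm = TRUE),
       n_u45 = sum(mapped$terminal_u_count %in% c(4L, 5L)),
       a_count_dist = stats::setNames(as.integer(a_dist), names(a_dist)),
       u_count_dist = stats::setNames(as.integer(u_dist), 0:6))
}
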