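# Shared fixtures and independent oracles for the test suite.

# write a one-record FASTA and load it as a ReferenceSeq
make_reference <- function(seq, terminator_len = 6L, name = "toy") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), fa)
  load_reference(fa, terminator_len)
}

# a ReferenceSeq-shaped object for aligner tests that do not need a valid
# terminator (the aligner only reads $seq and $length)
bare_reference <- function(seq, terminator_len = 1L) {
  structure(list(name = "bare", seq = seq, length = nchar(seq),
                 terminator_start = nchar(seq) - terminator_len + 1L,
                 terminator_len = terminator_len),
            class = "ReferenceSeq")
}

toy_ref <- function() make_reference("ACGTACGATTTTTT", 6L)

# designed clone-test reference: 40 nt body ending in C, then the T6
# terminator.  Position 25 is an internal truncation analogue whose next
# base (G) is not A, so an appended A-tail is always distinguishable from
# the genome under maximal genomic extension.
CLONE_REF_SEQ <- paste0("ATGCCGTAGCTTAGCGTACCAGTTCGATCGGATACGCTAC",
                        "TTTTTT")
clone_ref <- function() make_reference(CLONE_REF_SEQ, 6L, "cloneref")

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random reference ending in a T-tract, loadable by load_reference; the
# base before the tract is fixed non-T so the encoded U-tract length is
# exactly terminator_len
rand_tref <- function(L, terminator_len = 6L) {
  make_reference(paste0(rand_seq(L - terminator_len - 1L), "C",
                        strrep("T", terminator_len)),
                 terminator_len, name = "rand")
}

# ---- independent oligo(A) oracle: direct counting, integer rule ----------
oracle_classify <- function(tail) {
  ch <- strsplit(tail, "")[[1L]]
  a <- sum(ch == "A")
  non_a <- length(ch) - a
  # >= 2 A's and not more than 20% non-A, as pure integer arithmetic
  a >= 2 && non_a * 5 <= length(ch)
}

# ---- independent aligner oracle: exhaustive path enumeration -------------
# Enumerates every (5' clip, reference start, aligned length, deletion
# multiset of size <= 2) path, scores it directly base by base, applies the
# feasibility constraints, and picks the winner under the documented total
# order.  No prefix-sum or DP machinery shared with the implementation.
oracle_align_one <- function(seq, refseq, p) {
  m <- nchar(seq)
  n <- nchar(refseq)
  rb <- strsplit(seq, "")[[1L]]
  fb <- strsplit(refseq, "")[[1L]]
  fracnum <- round(p$max_mismatch_frac * 1e6)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$score != b$score) return(a$score > b$score)
    if (a$read_end != b$read_end) return(a$read_end > b$read_end)
    if (a$ref_end != b$ref_end) return(a$ref_end < b$ref_end)
    if (a$ndel != b$ndel) return(a$ndel < b$ndel)
    if (a$ref_start != b$ref_start) return(a$ref_start < b$ref_start)
    a$clip < b$clip
  }
  best <- NULL
  for (cl in 0:min(p$max_clip5, m - 1L)) {
    tmax_all <- m - cl
    # deletion multisets: {} , {k}, {k1<=k2}; k <= t-1 checked per t
    dsets <- list(integer(0))
    if (tmax_all >= 2L) {
      for (k in 1:(tmax_all - 1L)) dsets[[length(dsets) + 1L]] <- k
      for (k1 in 1:(tmax_all - 1L)) for (k2 in k1:(tmax_all - 1L))
        dsets[[length(dsets) + 1L]] <- c(k1, k2)
    }
    for (s in 1:n) {
      for (D in dsets) {
        d <- length(D)
        tmin <- if (d > 0L) max(D) + 1L else 1L
        tmax <- min(tmax_all, n - s + 1L - d)
        if (tmax < tmin) next
        # score every aligned read base along this path
        u <- seq_len(tmax)
        shift <- if (d == 0L) 0L else
          if (d == 1L) as.integer(u > D) else
          as.integer(u > D[1L]) + as.integer(u > D[2L])
        refpos <- s + u - 1L + shift
        is_match <- rb[cl + u] == fb[refpos] & rb[cl + u] != "N"
        persc <- ifelse(is_match, p$match, p$mismatch)
        csc <- cumsum(persc)
        cx <- cumsum(!is_match)
        for (t in tmin:tmax) {
          tail_len <- m - cl - t
          if (tail_len > p$max_tail_len) next
          span <- t + d
          if (span < p$min_match_len) next
          x <- cx[t]
          if (x * 1e6 > span * fracnum) next
          cand <- list(score = csc[t] + d * p$gap_open,
                       read_end = cl + t, ref_end = s + t - 1L + d,
                       ndel = d, ref_start = s, clip = cl,
                       n_mismatch = x, dels = if (d) s + D + seq_len(d) - 1L
                                              else integer(0))
          if (better(cand, best)) best <- cand
        }
      }
    }
  }
  best
}

# strand-aware oracle mirroring align_read's outer logic
oracle_align <- function(seq, refseq, p) {
  fwd <- oracle_align_one(seq, refseq, p)
  rev <- oracle_align_one(revcomp_chr(seq), refseq, p)
  if (!is.null(fwd) && (is.null(rev) || fwd$score >= rev$score)) {
    fwd$strand <- "+"
    fwd$tail <- substring(seq, fwd$read_end + 1L)
    return(fwd)
  }
  if (!is.null(rev)) {
    rev$strand <- "-"
    rev$tail <- ""
    return(rev)
  }
  NULL
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# draw one random aligner test instance: a reference and a read that is
# either a mutated fragment (tail/substitutions/deletion) or pure noise
rand_align_instance <- function() {
  L <- sample(12:20, 1)
  refseq <- rand_seq(L)
  kind <- sample(3, 1)
  if (kind == 1L) {
    read <- rand_seq(sample(8:15, 1), c("A", "C", "G", "T", "N"))
  } else {
    len <- sample(8:13, 1)
    s <- sample(seq_len(max(1, L - len + 1)), 1)
    frag <- substring(refseq, s, min(L, s + len - 1L))
    ch <- strsplit(frag, "")[[1L]]
    if (kind == 3L && length(ch) >= 10L) {
      drop <- sample(2:(length(ch) - 1L), 1)   # interior deletion
      ch <- ch[-drop]
    }
    nmut <- sample(0:1, 1)
    if (nmut && length(ch) > 2L) {
      i <- sample(seq_along(ch), 1)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    tail <- if (runif(1) < 0.6) strrep("A", sample(0:4, 1)) else
      rand_seq(sample(0:3, 1))
    read <- paste0(paste(ch, collapse = ""), tail)
    if (nchar(read) > 15L) read <- substring(read, 1L, 15L)
    if (nchar(read) < 8L) read <- paste0(read, rand_seq(8L - nchar(read)))
  }
  list(refseq = refseq, read = read)
}
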