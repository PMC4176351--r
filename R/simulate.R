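#' Generative model of 3' end states
#'
#' Parameterizes the 3' end states of a pol III transcript ending in an
#' encoded T-tract: the primary transcript ends at the last (U6) or
#' second-to-last (U5) terminator position, is either internally truncated
#' or exonucleolytically trimmed from its 3' end, and may then receive a
#' non-templated oligo(A) tail.  Reads derived from molecules additionally
#' carry fragmentation (with a 5' start bias), crosslink-induced single-base
#' deletions, and substitution errors.
#'
#' @param p_trim Numeric vector of probabilities over trim depths
#'   `0..length(p_trim)-1` (terminal U's removed from the primary end).
#' @param p_primary_u6 Probability the primary transcript extends to the full
#'   terminator (U6) rather than stopping one short (U5).
#' @param p_adenylate Probability a molecule receives a non-templated tail.
#' @param tail_len_dist Probabilities over tail lengths `1..length(...)`.
#' @param tail_purity Per-base probability a tail base is A (1 = pure
#'   oligo(A); < 1 exercises the 20% non-A tolerance of the caller).
#' @param p_truncate Probability of internal truncation (overrides trimming).
#' @param truncation_sites,truncation_site_probs Internal truncation end
#'   positions and their probabilities.  `NULL` defaults to a point mass at
#'   the reference's analogue of scR1 nucleotide 453 (position
#'   `round(453/522 * L)`, clamped upstream of the terminator).
#' @param read_len_dist Probabilities over read lengths
#'   `read_len_min..read_len_min+length(...)-1`.
#' @param read_len_min Shortest read length.
#' @param fragment_start_bias Multiplicative weight on fragment start
#'   positions in the 5' third of the molecule (> 1 reproduces the 5'
#'   dominance of crosslinking libraries).
#' @param p_crosslink_del Per-read probability of one single-base deletion at
#'   a random interior templated position.
#' @param p_subst Per-base substitution error probability.
#' @return A list of class `EndStateModel`.
#' @export
end_state_model <- function(p_trim = c(0.05, 0.75, 0.20),
                            p_primary_u6 = 0.5,
                            p_adenylate = 0.05,
                            tail_len_dist = c(0.5, 0.5),
                            tail_purity = 1.0,
                            p_truncate = 0,
                            truncation_sites = NULL,
                            truncation_site_probs = NULL,
                            read_len_dist = rep(1 / 31, 31),
                            read_len_min = 20L,
                            fragment_start_bias = 3,
                            p_crosslink_del = 0.1,
                            p_subst = 0.001) {
  stopifnot(abs(sum(p_trim) - 1) < 1e-9, abs(sum(tail_len_dist) - 1) < 1e-9,
            abs(sum(read_len_dist) - 1) < 1e-9,
            p_adenylate >= 0, p_adenylate <= 1, p_truncate >= 0,
            p_truncate <= 1, tail_purity >= 0, tail_purity <= 1,
            p_primary_u6 >= 0, p_primary_u6 <= 1,
            fragment_start_bias > 0, p_crosslink_del >= 0,
            p_crosslink_del <= 1, p_subst >= 0, p_subst <= 1)
  if (!is.null(truncation_sites))
    stopifnot(length(truncation_sites) == length(truncation_site_probs),
              abs(sum(truncation_site_probs) - 1) < 1e-9)
  structure(list(p_trim = p_trim, p_primary_u6 = p_primary_u6,
                 p_adenylate = p_adenylate, tail_len_dist = tail_len_dist,
                 tail_purity = tail_purity, p_truncate = p_truncate,
                 truncation_sites = truncation_sites,
                 truncation_site_probs = truncation_site_probs,
                 read_len_dist = read_len_dist,
                 read_len_min = as.integer(read_len_min),
                 fragment_start_bias = fragment_start_bias,
                 p_crosslink_del = p_crosslink_del, p_subst = p_subst),
            class = "EndStateModel")
}

#' Genotype presets for the end-state model
#'
#' Illustrative parameterizations of the qualitative 3' end states reported
#' for scR1 in each genetic background; none is fitted (no rates are
#' available), they encode the direction and rough magnitude of each
#' phenotype:
#' \describe{
#'   \item{wild_type}{primary U5/U6 trimmed by 1-2 nt to a U4-U5 mature end;
#'     rare adenylation.}
#'   \item{rex1d}{no trimming: ends stay U5-U6.}
#'   \item{lhp1d}{over-trimming to U1-U3 plus frequent 1-4 nt
#'     oligoadenylation.}
#'   \item{lhp1d_trf4d}{lhp1d trimming but adenylation almost abolished.}
#'   \item{trf4d}{heterogeneous ends plus internal truncation at the
#'     nucleotide-453 analogue.}
#'   \item{air1d_air2d}{deep trimming, mode at a single terminal U.}
#'   \item{rrp6d}{shortened ends, some truncation, a fraction adenylated.}
#'   \item{trf4_bound}{not a genotype: the pool of surveillance substrates
#'     crosslinked to the TRAMP poly(A) polymerase in otherwise wild-type
#'     cells — deeply trimmed or truncated molecules, frequently
#'     oligoadenylated, with few retaining a mature U4-U5 end.}
#' }
#'
#' @param name Preset name.
#' @return An [end_state_model()].
#' @export
genotype_preset <- function(name = c("wild_type", "rex1d", "lhp1d",
                                     "lhp1d_trf4d", "trf4d", "air1d_air2d",
                                     "rrp6d", "trf4_bound")) {
  name <- match.arg(name)
  switch(name,
    wild_type = end_state_model(),
    rex1d = end_state_model(p_trim = 1, p_adenylate = 0.02),
    lhp1d = end_state_model(p_trim = c(0, 0, 0.15, 0.45, 0.40),
                            p_adenylate = 0.7,
                            tail_len_dist = rep(0.25, 4)),
    lhp1d_trf4d = end_state_model(p_trim = c(0, 0, 0.15, 0.45, 0.40),
                                  p_adenylate = 0.055,
                                  tail_len_dist = rep(0.25, 4)),
    trf4d = end_state_model(p_trim = c(0.10, 0.30, 0.25, 0.20, 0.15),
                            p_adenylate = 0.05, p_truncate = 0.25),
    air1d_air2d = end_state_model(p_trim = c(0, 0, 0, 0.15, 0.60, 0.25),
                                  p_adenylate = 0.3,
                                  tail_len_dist = rep(0.25, 4),
                                  p_truncate = 0.05),
    rrp6d = end_state_model(p_trim = c(0, 0, 0.2, 0.3, 0.3, 0.2),
                            p_adenylate = 0.3, tail_len_dist = rep(0.25, 4),
                            p_truncate = 0.3),
    trf4_bound = end_state_model(p_trim = c(0, 0, 0.1, 0.25, 0.35, 0.3),
                                 p_adenylate = 0.5,
                                 tail_len_dist = rep(0.25, 4),
                                 p_truncate = 0.3))
}

# evaluate expr with a temporarily seeded RNG, restoring ambient state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

sample_dist <- function(values, probs) {
  if (length(values) == 1L) return(values)
  values[sample.int(length(values), 1L, prob = probs)]
}

default_truncation_site <- function(ref) {
  # the scR1* endpoint analogue, scaled from nt 453 of the 522-nt RNA;
  # shifted upstream if the next reference base is A, so the boundary with a
  # non-templated A-tail stays identifiable under maximal genomic extension
  site <- min(max(1L, as.integer(round(453 / 522 * ref$length))),
              ref$terminator_start - 1L)
  while (site > 1L &&
         substring(ref$seq, site + 1L, site + 1L) == "A")
    site <- site - 1L
  site
}

random_tail <- function(len, purity) {
  if (len == 0L) return("")
  bases <- ifelse(stats::runif(len) < purity, "A",
                  sample(c("C", "G", "T"), len, replace = TRUE))
  paste(bases, collapse = "")
}

#' Simulate one molecule's 3' end state
#'
#' Draws the primary 3' end (U5 or U6), applies internal truncation or
#' terminator trimming, then optional oligoadenylation.  Uses the ambient
#' RNG stream; seed via the read/clone simulators or [set.seed()].
#'
#' Draw order (fixed, so seeded runs are reproducible across refactors):
#' primary end, truncation coin, truncation site or trim depth, adenylation
#' coin, tail length, tail bases.
#'
#' @param model An [end_state_model()].
#' @param ref A [ReferenceSeq][load_reference].
#' @return A list: `seq` (molecule sequence including any tail) and `truth`
#'   (one-row data.frame: `end_pos`, `u_count`, `tail`, `truncated`).
#' @export
simulate_molecule <- function(model, ref) {
  L <- ref$length
  primary_end <- if (stats::runif(1) < model$p_primary_u6) L else L - 1L
  truncated <- stats::runif(1) < model$p_truncate
  if (truncated) {
    sites <- model$truncation_sites
    if (is.null(sites)) {
      sites <- default_truncation_site(ref)
      probs <- 1
    } else probs <- model$truncation_site_probs
    end_pos <- as.integer(sample_dist(sites, probs))
  } else {
    trim <- sample_dist(seq_along(model$p_trim) - 1L, model$p_trim)
    end_pos <- max(1L, primary_end - as.integer(trim))
  }
  tail <- ""
  if (stats::runif(1) < model$p_adenylate) {
    len <- sample_dist(seq_along(model$tail_len_dist), model$tail_len_dist)
    tail <- random_tail(as.integer(len), model$tail_purity)
  }
  truth <- data.frame(end_pos = end_pos,
                      u_count = count_terminal_u(end_pos, ref),
                      tail = tail, truncated = truncated,
                      stringsAsFactors = FALSE)
  list(seq = paste0(substring(ref$seq, 1L, end_pos), tail), truth = truth)
}

substitute_bases <- function(seq, p) {
  n <- nchar(seq)
  if (n == 0L || p <= 0) return(list(seq = seq, n_subst = 0L))
  hit <- which(stats::runif(n) < p)
  if (!length(hit)) return(list(seq = seq, n_subst = 0L))
  bases <- strsplit(seq, "")[[1L]]
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), bases[i])
    bases[i] <- alt[sample.int(3L, 1L)]
  }
  list(seq = paste(bases, collapse = ""), n_subst = length(hit))
}

#' Simulate a crosslinking-style read library
#'
#' Each read is a fragment of a simulated molecule: the start position is
#' drawn with a 5' bias (weight `fragment_start_bias` on the molecule's
#' first third), the length from `read_len_dist`; fragments running past the
#' templated 3' end carry the molecule's non-templated tail.  Per read, one
#' interior templated base may be deleted (crosslink-induced deletion) and
#' substitution errors applied.
#'
#' @param model An [end_state_model()].
#' @param ref A [ReferenceSeq][load_reference].
#' @param n Number of reads (> 0).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame, one row per read: molecule state, fragment coordinates,
#'   the tail portion present in the read, `del_pos`, `n_subst`, and the
#'   ground-truth oligo(A) label of the in-read tail).
#' @export
simulate_crac_reads <- function(model, ref, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  with_seed(seed, {
    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      mol <- simulate_molecule(model, ref)
      end_pos <- mol$truth$end_pos
      len <- sample_dist(model$read_len_min +
                           seq_along(model$read_len_dist) - 1L,
                         model$read_len_dist)
      # keep >= 20 templated bases in every fragment so an error-free read
      # is always alignable and its truth labels recoverable
      max_start <- max(1L, end_pos - 19L)
      w <- rep(1, max_start)
      w[seq_len(max(1L, min(max_start, end_pos %/% 3L)))] <-
        model$fragment_start_bias
      start <- sample_dist(seq_len(max_start), w / sum(w))
      frag_end_in_mol <- min(start + len - 1L, nchar(mol$seq))
      templ_end <- min(frag_end_in_mol, end_pos)
      tail_in_read <- if (frag_end_in_mol > end_pos)
        substring(mol$seq, end_pos + 1L, frag_end_in_mol) else ""
      seq <- substring(mol$seq, start, frag_end_in_mol)
      del_pos <- NA_integer_
      n_templ <- templ_end - start + 1L
      if (stats::runif(1) < model$p_crosslink_del && n_templ >= 3L) {
        off <- 1L + sample.int(n_templ - 2L, 1L)  # interior templated base
        del_pos <- start + off - 1L
        seq <- paste0(substring(seq, 1L, off - 1L),
                      substring(seq, off + 1L, nchar(seq)))
      }
      sub <- substitute_bases(seq, model$p_subst)
      seqs[i] <- sub$seq
      rows[[i]] <- data.frame(
        read_id = sprintf("simread_%06d", i),
        mol_end_pos = end_pos, mol_u_count = mol$truth$u_count,
        mol_tail = mol$truth$tail, truncated = mol$truth$truncated,
        frag_ref_start = start, frag_ref_end = templ_end,
        tail_in_read = tail_in_read, del_pos = del_pos,
        n_subst = sub$n_subst,
        is_oligoA_true = classify_tail(tail_in_read)$is_oligoA,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    reads <- data.frame(id = truth$read_id, seq = seqs,
                        qual = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate ligation-mediated RT-PCR clones
#'
#' Each clone is the 3' portion of a simulated molecule from a fixed
#' upstream anchor (the gene-specific primer position) through the molecule
#' 3' end plus its non-templated tail, with the ligation adapter appended
#' verbatim.  Molecules whose 3' end lies too close to (or upstream of) the
#' anchor yield no amplifiable product and are redrawn.
#'
#' @inheritParams simulate_crac_reads
#' @param adapters An [adapter_set()]; the first adapter is ligated.
#' @param anchor_start 1-based reference position of the insert 5' end;
#'   default the adapter set's anchor primer start, clamped to the
#'   reference.
#' @return A list: `clones` (data.frame `id`, `seq`, `qual = NA`) and
#'   `truth` (one row per clone: `end_pos`, `u_count`, `tail`, `a_count`,
#'   `truncated`, `end_class`, `adenylated`).
#' @export
simulate_clones <- function(model, ref, n, seed = 1L,
                            adapters = adapter_set(), anchor_start = NULL) {
  if (n <= 0) stop("n must be positive")
  if (is.null(anchor_start)) {
    # the primer anchor when it leaves room for a >= 20 nt insert,
    # otherwise the reference 5' end (toy references are short)
    anchor_start <- adapters$anchor_primer_region[1L]
    if (anchor_start + 19L >= ref$terminator_start) anchor_start <- 1L
  }
  anchor_start <- max(1L, as.integer(anchor_start))
  with_seed(seed, {
    rows <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      attempts <- 0L
      repeat {
        mol <- simulate_molecule(model, ref)
        if (mol$truth$end_pos >= anchor_start + 19L) break
        attempts <- attempts + 1L
        if (attempts > 1000L)
          stop("no amplifiable molecules: every simulated 3' end lies ",
               "within 20 nt of anchor_start = ", anchor_start)
      }
      insert <- paste0(substring(ref$seq, anchor_start, mol$truth$end_pos),
                       mol$truth$tail)
      seqs[i] <- paste0(insert, adapters$adapters[1L])
      a_count <- nchar(mol$truth$tail) -
        nchar(gsub("A", "", mol$truth$tail, fixed = TRUE))
      rows[[i]] <- data.frame(
        clone_id = sprintf("simclone_%04d", i),
        end_pos = mol$truth$end_pos, u_count = mol$truth$u_count,
        tail = mol$truth$tail, a_count = a_count,
        truncated = mol$truth$truncated,
        end_class = classify_end(mol$truth$end_pos, ref),
        adenylated = a_count >= 1L, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    clones <- data.frame(id = truth$clone_id, seq = seqs,
                         qual = NA_character_, stringsAsFactors = FALSE)
    list(clones = clones, truth = truth)
  })
}

#' Write a simulated data set to an output directory
#'
#' @param sim Result of [simulate_crac_reads()] or [simulate_clones()].
#' @param model The [end_state_model()] used (written as resolved YAML).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_simulation <- function(sim, model, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$reads)) {
    write_fastx(sim$reads, file.path(outdir, "reads.fastq"), "fastq")
  } else {
    write_fastx(sim$clones, file.path(outdir, "clones.fa"), "fasta")
  }
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(model), file.path(outdir, "model.yaml"))
  invisible(outdir)
}
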