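#' Pipeline run configuration
#'
#' A fully serializable description of a run; re-executing a run from its
#' emitted resolved config reproduces byte-identical outputs.
#'
#' @param reference Path to the reference FASTA.
#' @param mode `"crac"` or `"clones"`.
#' @param reads Path to a FASTQ/FASTA of reads (crac mode).
#' @param clones Path to a FASTA of clone sequences (clones mode).
#' @param outdir Output directory.
#' @param terminator_len Encoded terminal T-tract length.
#' @param params [align_params()] block.
#' @param min_a,max_non_a_frac Oligo(A) calling thresholds.
#' @param denominator Per-million denominator for profiles (`NULL` = reads
#'   aligned to this reference).
#' @param adapters [adapter_set()] block (clones mode).
#' @param set_label Label for the clone set summary.
#' @param seed Seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters for simulation-driven runs).
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(reference, mode = c("crac", "clones"), reads = NULL,
                       clones = NULL, outdir = ".", terminator_len = 6L,
                       params = align_params(), min_a = 2L,
                       max_non_a_frac = 0.20, denominator = NULL,
                       adapters = adapter_set(), set_label = "sample",
                       seed = 1L) {
  mode <- match.arg(mode)
  structure(list(reference = reference, mode = mode, reads = reads,
                 clones = clones, outdir = outdir,
                 terminator_len = as.integer(terminator_len),
                 params = params, min_a = as.integer(min_a),
                 max_non_a_frac = max_non_a_frac, denominator = denominator,
                 adapters = adapters, set_label = set_label,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

check_inputs <- function(config, paths) {
  for (p in paths)
    if (is.null(p) || !file.exists(p))
      stop("input missing before any stage ran: ",
           if (is.null(p)) "(unset path)" else p)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

write_manifest <- function(config, outdir, outputs) {
  inputs <- Filter(Negate(is.null),
                   list(reference = config$reference, reads = config$reads,
                        clones = config$clones))
  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    input_md5 = as.list(vapply(inputs, function(p)
      unname(tools::md5sum(p)), character(1))),
    output_md5 = as.list(stats::setNames(
      vapply(outputs, function(p) unname(tools::md5sum(p)), character(1)),
      basename(unlist(outputs)))),
    resolved_config = strip_classes(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Run the crosslinking-read pipeline end to end
#'
#' Stages, in order: align reads to the reference, call non-encoded tails
#' and the oligo(A) verdict, build the per-nucleotide density profile.
#' Products: `alignments.tsv`, `tails.tsv`, `summary.json`, `profile.tsv`,
#' `profile.bedGraph`, and `manifest.json` with input/output checksums and
#' the resolved config.  A stage failure removes partial outputs.
#'
#' @param config A [run_config()] with `mode = "crac"`.
#' @return Invisibly, a list with the in-memory `alignments`, `calls`,
#'   `summary`, and `profile`.
#' @export
run_crac_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"), config$mode == "crac")
  check_inputs(config, list(config$reference, config$reads))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outs <- file.path(config$outdir,
                    c("alignments.tsv", "tails.tsv", "summary.json",
                      "profile.tsv", "profile.bedGraph"))
  stage <- "align"
  tryCatch({
    ref <- load_reference(config$reference, config$terminator_len)
    reads <- read_fastx(config$reads)
    al <- align_reads(reads, ref, config$params)
    write_alignments(al, outs[1L])
    stage <- "tails"
    calls <- call_tails(al, ref, config$min_a, config$max_non_a_frac)
    write_tails(calls, outs[2L], outs[3L])
    stage <- "profile"
    prof <- build_profile(al, calls, ref, config$denominator)
    write_profile(prof, ref, outs[4L], outs[5L])
    write_manifest(config, config$outdir, outs)
    invisible(list(alignments = al, calls = calls,
                   summary = tail_summary(calls), profile = prof))
  }, error = function(e) {
    unlink(outs)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}

#' Run the clone-annotation pipeline end to end
#'
#' Stages: strip adapters, annotate clone 3' ends, summarize the set.
#' Products: `clones.tsv`, `clone_summary.json`, `manifest.json`.
#'
#' @param config A [run_config()] with `mode = "clones"`.
#' @return Invisibly, a list with `annotations` and `summary`.
#' @export
run_clone_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"), config$mode == "clones")
  check_inputs(config, list(config$reference, config$clones))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outs <- file.path(config$outdir, c("clones.tsv", "clone_summary.json"))
  stage <- "clones"
  tryCatch({
    ref <- load_reference(config$reference, config$terminator_len)
    clones <- read_fastx(config$clones)
    ann <- annotate_clones(clones, ref, config$adapters, config$params)
    utils::write.table(ann, outs[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage <- "summary"
    s <- summarize_clone_set(ann, config$set_label)
    jsonlite::write_json(s, outs[2L], auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    write_manifest(config, config$outdir, outs)
    invisible(list(annotations = ann, summary = s))
  }, error = function(e) {
    unlink(outs)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}
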