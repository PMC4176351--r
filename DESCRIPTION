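Package: tailscan
Title: Non-Templated 3' Tail Extraction and 3' End Annotation for Small RNA
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the 3' end integrity of small structured
    RNAs, built around the yeast SRP RNA (scR1), an RNA polymerase III
    transcript ending in a genomically encoded U-tract. Aligns
    crosslinking-derived (CRAC/CLIP) reads to a small reference with a
    glocal aligner that tolerates single-base crosslink-induced deletions,
    extracts the non-encoded 3' tail of each read, classifies tails as
    oligo(A) marks of the TRAMP surveillance machinery, and builds
    per-nucleotide hit-density profiles normalized per million aligned
    reads. Also annotates ligation-mediated RT-PCR clone sequences:
    adapter stripping, terminal templated-U counting, non-templated
    adenosine counting, and 3' end classification (mature, extended,
    trimmed, truncated). A seeded synthetic-data generator emulates the
    relevant 3' end states (terminator trimming, oligoadenylation,
    internal truncation, crosslink deletions) with ground-truth labels so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
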