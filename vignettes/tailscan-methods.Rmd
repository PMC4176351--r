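---
title: "Measuring 3' end integrity of a pol III transcript: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3' end integrity of a pol III transcript: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscan)
```

## The problem

RNA polymerase III transcripts end in a genomically encoded run of uridines.
For the yeast SRP RNA (scR1) the termination signal is T6 on the coding
strand; the mature RNA retains a U4–U5 tract, while the primary transcript
extends to U5–U6 before a 3' exonuclease removes one or two residues.  The
3' end is therefore a sensitive readout of RNA surveillance: exonucleolytic
over-trimming shortens the U-tract, the TRAMP complex marks substrates with
short non-templated oligo(A) tails, and degradation intermediates end at
internal positions (for scR1, near nucleotide 453).

`tailscan` quantifies these states from two kinds of data:

1. **Crosslinking-derived short reads** (CRAC/CLIP libraries): each read is a
   fragment of an RNA bound by a tagged protein.  The read suffix that does
   not match the genome — the *non-encoded tail* — is extracted and
   classified as oligo(A) or not, and per-nucleotide density profiles are
   built for all reads and for the oligoadenylated subset.
2. **Ligation-mediated RT-PCR clones**: a blocked oligonucleotide is ligated
   to the RNA 3' end, the region is amplified and sequenced, and each clone
   reports one molecule's exact 3' end: how many templated U's it retains,
   and how many non-templated A's follow them.

## Coordinates and alphabet

All coordinates are 1-based and inclusive, so "nucleotide 453" is the 453rd
base of the reference.  Conversion to 0-based half-open intervals happens
only inside bedGraph export.  RNA input (U) is converted to DNA (T) on
ingestion; N is legal in reads, never matches any reference base, and counts
as non-A in tail statistics.

## The aligner and the templated/non-templated boundary

Reads are aligned to a single small reference with a glocal aligner written
for this purpose: a read prefix (after an optional 5' soft-clip of at most 3
nt) is aligned to a reference substring, and the remaining 3' read suffix is
reported as the non-encoded tail.  Default scores are match +1, mismatch −2,
gap −3 (linear).  Two error modes of crosslinked cDNA are modelled:

* **Crosslink-induced deletions** — single reference bases absent from the
  read, introduced during reverse transcription through the crosslink site.
  Up to two deletions per read are searched; the scores are chosen so that
  one deletion (−3) is preferred to truncating four or more matched bases.
* **Substitutions** — ordinary mismatches, limited by `max_mismatch_frac`
  (default 0.1 of aligned columns).

Insertions in the read relative to the reference are deliberately not
modelled: reverse-transcription errors at crosslink sites are losses, not
gains, and omitting an insert state makes the read length decompose exactly
as clip + (reference span − deletions) + tail.  A useful consequence is that
for a fixed clip, aligned length and deletion count, the alignment score
determines the mismatch count, which allows the *constrained* optimum — the
best score among alignments already satisfying the minimum-match-length,
mismatch-fraction and tail-length requirements — to be found exactly by
per-diagonal prefix sums.  Constrained selection matters: a read carrying a
crosslink deletion may have a shorter, clipped exact match that scores
higher but fails the length filter; the right answer is the feasible
deletion-bearing alignment, not "unaligned".

**Maximal genomic extension.**  When the boundary between templated and
non-templated sequence is ambiguous (the first tail base equals the next
reference base), ties are broken by assigning the maximum number of 3' read
bases to the reference.  A read base equal to the next reference base is
therefore always counted as templated, never as tail.  This is the
conservative convention: without it, A-tails upstream of genomic A residues
would be overcalled; with it, tail lengths can only be undercounted, never
overcounted.  At a T-tract 3' end the next genomic base is T, so a
non-templated A following the U-tract is always cleanly separated.

Remaining ties are resolved deterministically (smaller reference end, fewer
deletions, smaller reference start, smaller clip), making the aligner a pure
function of its inputs.  Antisense alignments are retained for coverage but
carry an empty tail — tail analysis concerns the sense transcript's 3' end
only.

Defaults: `min_match_len = 15` nt, `max_tail_len = 20` nt (longer clipped
suffixes usually mean adapter read-through), `max_clip5 = 3` nt.  The test
suite uses `min_match_len = 8` — the smallest permitted value — for toy
references shorter than 15 nt.

## The oligo(A) rule

A non-encoded tail is called oligo(A) when it has **at least 2 adenosines
and not more than 20% non-A nucleotides**.  The 20% bound is evaluated in
exact integer arithmetic — reject iff `(tail_len − a_count) · 5 > tail_len`
— so boundary cases like a 5-nt tail with one G (exactly 20% non-A, called
oligo(A)) never depend on floating-point rounding.  The `min_a` and
`max_non_a_frac` parameters are exposed, so the simpler "two or more A's"
rule is reachable by setting `max_non_a_frac = 1`.

## Density profiles

Profiles count, at every reference position, the reads whose matched
segment covers it (span counting, not 5'-end counting); positions deleted
from a read are not covered by it.  Densities are counts per million aligned
reads with an **explicit denominator**: the conventional normalization
divides by reads aligned genome-wide, which a single-reference analysis
cannot know, so the caller may supply it; the default (reads aligned to
this reference) is documented as a different scale.  Coverage conservation —
the column sums equal the summed span lengths minus deletions — is asserted
exactly on every run.

## Clone 3' end classes

With a T6 terminator at positions `terminator_start..L`, a clone whose
templated end is `ref_end` is classed:

| class     | condition                  | meaning                          |
|-----------|----------------------------|----------------------------------|
| extended  | `ref_end = L`              | full terminator retained (U6)    |
| mature    | `ref_end ∈ {L−2, L−1}`     | trimmed 1–2 nt (U4–U5)           |
| trimmed   | `terminator_start ≤ ref_end ≤ L−3` | over-trimmed (U ≤ 3)     |
| truncated | `ref_end < terminator_start` | internal degradation intermediate |

U5 ends are classed mature: wild-type molecules end in U4 or U5, while U5
also appears among unprocessed primary transcripts.  The raw U-length
distribution is always reported alongside the classes so the stricter
convention (U5 primary-like) can be read off without re-annotation.  A
clone is *adenylated* when at least one non-templated A follows the
templated end; a tail containing non-A bases is flagged `tail_impure`
rather than rejected, since sequencing error must not crash annotation.
Adapter stripping accepts an adapter prefix match of at least 12 nt with at
most 2 substitutions, nearest the 3' end; ambiguity codes other than N are
rejected.  The anchor-primer check (the real gene-specific primer sits at
positions 233–250) is a warning by default because toy references are
shorter; strict mode errors instead.

## The synthetic-data generator

The generator emulates the 3' end states the pipeline measures, with
ground-truth labels, so every stage is testable without external data.  Each
molecule draws: a primary end (U5 or U6, equal mass by default); internal
truncation with probability `p_truncate` (site defaulting to the nucleotide
453 analogue, `round(453/522 · L)`) or otherwise a trim depth from `p_trim`;
then a non-templated tail with probability `p_adenylate` (length 1–4 for
clones, per-base purity `tail_purity`, default pure A).  Reads add
fragmentation with a configurable 5' start bias (a multiplicative weight on
starts in the molecule's first third — a phenomenological stand-in for the
unexplained 5' dominance of crosslinking libraries, not a mechanistic
model), one interior crosslink deletion per read with probability
`p_crosslink_del`, and per-base substitutions `p_subst`.

Two generator choices keep the ground truth identifiable: every fragment
retains at least 20 templated bases (so an error-free read is always
alignable), and the default truncation site is shifted upstream until the
next reference base is not A (so an appended A-tail is never absorbed into
the genome by maximal genomic extension).  A single seeded RNG stream with
a fixed draw order (primary end, truncation coin, site/trim, adenylation
coin, tail length, tail bases; then per-read length, start, deletion,
substitutions) makes identical seeds give byte-identical outputs.

**Genotype presets** (`wild_type`, `rex1d`, `lhp1d`, `lhp1d_trf4d`,
`trf4d`, `air1d_air2d`, `rrp6d`, and the protein-bound pool `trf4_bound`)
encode the qualitative end states of each background: wild type trims 1–2
nt to U4–U5; loss of the trimming exonuclease leaves U5–U6; loss of the La
homologue over-trims to U1–U3 with frequent 1–4 nt adenylation; loss of the
TRAMP poly(A) polymerase removes most adenylation and adds internal
truncation; loss of both TRAMP RNA-binding subunits trims deepest (mode at
a single U).  These are illustrative parameterizations — no rates are
measurable from end-point data — and they are not fitted to anything.

**What passing tests do and do not show.**  The generator produces reads
whose only error modes are substitutions and single-base deletions, from a
uniform fragment-length distribution and a one-parameter start bias.  Real
libraries add adapter remnants, PCR duplicates, multi-locus mapping
ambiguity and non-uniform coverage; recovering truth on synthetic data
therefore validates the algorithmic contracts (boundary calling, the
oligo(A) rule, conservation, classification), not end-to-end accuracy on
deposited datasets, whose reproduction additionally depends on the original
genome-wide mapping parameters.

## Numerical and scale choices

Tests and the acceptance script run at the scale the method targets: a
synthetic 522-nt reference (the length of scR1) with a T6 terminator, clone
sets of 20–24 molecules (the study's sample sizes), and libraries of 5000
reads.  Aligner verification uses 500 random instances with references up
to 20 nt, where exhaustive enumeration of every clip/segment/deletion/tail
split is feasible as an independent oracle.  Parameter recovery of the
oligo(A) fraction uses near-full-length fragments so that every read
carries the molecule's 3' end and the estimate has the closed-form
expectation `p_adenylate · P(tail length ≥ 2)`.

Ground-truth label recovery under substitution noise (0.005/nt) is measured
on the oligo(A) verdict rather than exact coordinates: a substitution in
the last one or two read bases is always better explained as a short
non-encoded tail than as a terminal mismatch, so *no* soft-clipping aligner
can recover exact coordinates for essentially all reads; the verdict, by
contrast, is robust (measured recovery above 99.9%).  Zero-error inputs are
required to round-trip field-exactly, and the tests assert this on the full
grid of trim depth (0–6) by tail length (0–4) by truncation state.

## Known limitations

* Single-reference analysis: reads are not competitively mapped against the
  whole genome, so multi-locus reads that the original genome-wide mapping
  would discard are here assigned to the reference if they pass the score
  filters.
* At most two crosslink deletions per read are searched.
* Chromatogram interpretation (mixed-population direct sequencing traces)
  is out of scope; clones are single Sanger-style sequences.
* The generator's presets are qualitative; absolute abundances of truncated
  versus full-length species are free parameters.
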