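---
title: "Structure-based discovery of Ac/Ds transposable elements: methods and design"
author: "AcDsTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based discovery of Ac/Ds transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AcDsTools)
```

## The problem

Activator (*Ac*) is the 4.6-kb autonomous maize transposon of the hAT
superfamily; *Dissociation* (*Ds*) elements are its non-autonomous
derivatives, mobilized in trans by the Ac transposase. Every member of
the family shares two structural hallmarks and essentially nothing
else:

* an 11-bp **terminal inverted repeat** (TIR) at each end — 5'
  `[C/T]AGGGATGAAA` and 3' `TTTCATCCCT[A/G]`, exact reverse
  complements of one another up to the single degenerate position; and
* an 8-bp **target site duplication** (TSD) — a direct repeat of host
  sequence created by the insertion itself, flanking the element. The
  TSD is not a specific sequence; only the agreement of its two copies
  carries signal.

Because the interior of a Ds element can be almost anything (decayed
transposase fragments, captured gene pieces, "filler" DNA of unknown
provenance, or whole trapped retrotransposons), homology search against
known elements badly undercounts the family. AcDsTools implements the
structural route instead: find candidate TIR pairs, corroborate them
with the TSD, and only then ask what the interior is.

## Discovery model

`scanTIR()` reports every 11-bp window within a Hamming-distance budget
of either TIR motif. The degenerate position matches its two-letter set
at zero cost, and `N` never matches anything (windows overlapping `N`
are dropped). Because the two motifs are mutual reverse complements,
any genomic match is simultaneously a 5' terminus of an element on one
strand and a 3' terminus of an element on the other; both readings are
emitted, and consequently the final calls carry strand `*` — TIR
grammar alone cannot orient an element.

`pairCandidates()` evaluates, for each left terminus, all right termini
within the admissible span (default 50 bp – 30 kb; the ceiling is above
the largest cargo-inflated elements observed, ~24 kb) and admits a call
when the two flanking 8-mers agree within the TSD budget. Three
mismatch controls exist:

* `tirMaxMismatch` (default 2) per TIR at scan time,
* `tsdMaxMismatch` (default 2) between the TSD copies,
* `maxScore` (default 2) on the **sum** tir5 + tir3 + tsd.

The combined cap is the package's operative filter. The back-of-envelope
statistics are unforgiving: with independent budgets of 2, an 11-bp
motif hits a random window at rate ~1.3e-4 and two random 8-mers agree
within 2 mismatches at rate ~4e-3, which on a multi-Gb genome yields
thousands of chance TIR-pair + TSD coincidences — more than the entire
real element census. A combined budget of 2 drives the expected number
of chance calls genome-wide to well below one while still admitting
every combination of "perfect TIRs, near TSD" and vice versa.

Competition for a TIR hit is resolved **innermost-first** (shortest
span), then lowest score, then leftmost. Each hit supports at most one
call. This makes nested elements — a complete element inside the
interior of another, with its own TSD — detectable, because the nested
pair consumes different hits than the host pair. The rule set is a
design choice: any deterministic resolution would do, but this one
favors the biologically coherent reading (an element's own TSD sits
immediately at its boundary) and makes output order-independent.

`rescueNoTSD()` reruns pairing without TSD corroboration and reports
only calls that do not overlap the primary catalog, annotated with the
identity of their flanks (x of 8). Since the TSD is the main
specificity filter, the rescue pass demands perfect TIRs by default;
with mismatched TIRs allowed it would drown in chance pairs.

## Classification model

Classification is pure homology profiling against an annotated
reference element (`AcReference`): the element is locally aligned
(match +1, mismatch −1, gap open −2, extend −1) against the whole
reference and against three annotated segments — the two ~200-bp
subterminal regions (STRs) and the transposase exon-2/3 block — and
ungapped terminal identity runs are measured in 10-bp windows at ≥ 80%
identity, stopping at the first failing window. A segment alignment
scoring below `minCovScore` (default 25) contributes zero coverage;
this floor is what keeps the short, spurious local alignments that any
two random sequences share from registering as homology.

The label cascade (first match wins):

| rule | label | criterion | default thresholds |
|---|---|---|---|
| 1 | Ac-like | near-complete reference homology | full coverage ≥ 0.9, identity ≥ 0.9 |
| 2 | Ds2 | both STRs retained | STR coverage ≥ 0.5 each |
| 3 | Ds-l3 | transposase exon-2/3 fragment | exon coverage ≥ 0.1, block ≥ 200 bp |
| 4 | Ds1 | short + family-consensus match | length < 500 bp, identity ≥ 0.7 over ≥ 100 bp |
| 5 | Ds-l4 | homology confined to termini | terminal runs ≤ 40 bp each |
| 6 | unclassified | — | — |

The published class definitions are qualitative ("~200 bp of the
subterminal region", "about 30 bp at either end", "a large amount of
similarity"); the numeric thresholds are this package's, chosen to
separate the class archetypes with wide margins, and all are
configurable through `classifyThresholds()`. Ds1 and Ds-l4 share the
"TIRs plus filler" architecture and are separated primarily by the Ds1
family consensus (Ds1 filler is shared across copies; Ds-l4 filler is
variable). Without a consensus the Ds1 rule degrades to its length
fallback (< 500 bp; known Ds1 elements are all shorter than that) with
a warning.

Subterminal hexamers (`AAACGG`, the transposase binding motif; three or
more copies are associated with mobility) are counted in the two 200-bp
windows reading inward from each end, with the 3' window counted on the
reverse complement. For elements under 400 bp the windows are the two
halves — the published protocol does not address short elements, so the
halves rule is ours. Whether "3 or more copies in the subterminal
regions" pools the two ends or requires them in the 5' end alone is
also not specified; we count ends separately and set the mobility flag
on the pooled count, keeping both per-end counts in the catalog.

## Annotation

* **Insertion context** uses precedence genic > repetitive >
  intergenic. "Genic" means a gene model in or within 200 bp (strand
  ignored — the published convention is unstated). "Repetitive" is
  defined by the median genome-wide frequency of the 20-mers of the
  two 200-bp flanks (threshold 2.0), counted on both strands. This
  k-mer definition replaces a repeat-masking protocol and is
  self-contained and library-free; it is a declared stand-in, not a
  reimplementation of the original (which used external databases).
* **Internal cargo**: local-alignment matches of the interior
  (identity ≥ 0.8 over ≥ 100 bp) against a repeat library and a donor
  exon database, nested elements by recursive TIR scanning, residual
  interior as filler. Two exon matches of one donor separated by an
  interior segment with `GT...AG` termini merge into one gene fragment
  with an intron flag.
* **Compound decomposition** keys on internal exact copies of the
  element's own TSD word: the core element's right TSD copy survives
  internally, and each trapped block is led by another copy. Segment
  boundaries are placed at those copies; the final segment is a
  truncated duplicate when it ends in a TIR and aligns to the core.
  Without external libraries there is no other intrinsic signal for
  cargo boundaries, so this is the package's operational definition of
  a compound element, and the synthetic builder constructs exactly
  this architecture (drawing a TSD word that occurs nowhere else in
  the element, so boundaries are unambiguous).
* **Excision sites**: the predicted empty-site amplicon retains a
  single intact TSD copy between the flanks. Real excision footprints
  vary; the PCR assay the prediction serves does not resolve footprint
  sequence, so a fixed convention suffices and is flagged as such.
* **Junction matching** locates the TIR inside a transposon-display
  read, maps the adjacent 30-bp host word to the target genome at 90%
  identity, and calls the read `shared` when the implied junction sits
  within 8 bp (absorbing TSD ambiguity) of a cataloged element
  terminus, `polymorphic` when the host maps but no element is
  adjacent, `unmapped` otherwise.

## Filler clustering

Ds-l4 interiors are grouped by k-mer cosine distance (k = 8) and
neighbor joining. The published analysis aligned the elements with a
multiple-sequence aligner and built the tree in a viewer; an MSA-based
distance would dominate runtime here and add nothing testable, so the
distance stage is alignment-free by design. Cosine distance is not a
metric (the triangle inequality can fail); it is used only as NJ input.
The NJ implementation is the standard Q-criterion agglomeration with
deterministic tie-breaking (lexicographically smallest label pair) and
negative branch lengths clamped to zero; on additive matrices it
reproduces the generating tree's path lengths exactly, which the test
suite verifies against an independent implementation. Cluster count is
a parameter (the published three clusters were read off a phylogram by
eye); `cutClusters()` removes the n−1 longest internal edges, an
explicit reproducible rule.

## The synthetic genome

`implantGenome()` is first-class, tested code, and the study condition
for every benchmark in the package. Backgrounds are i.i.d. bases at GC
0.47 with synthetic two-exon gene models and two repeat families
implanted as 20-copy arrays at 1% divergence — enough realism to
exercise the genic/repetitive/unique distinction without modeling a
real chromosome. Elements are built to their class architectures with
lengths drawn from truncated normals around the published class
centers (Ds1 ~400 bp < 500; Ds2 mean ~1.4 kb; Ds-l3 mean ~4 kb; Ds-l4
~1 kb), and insertion uses true TSD semantics: the 8-bp host word at
the site is duplicated by the insertion itself, so the flanking direct
repeat is created, not assumed. Ground truth records post-insertion
coordinates, class, TSD word, cargo, context and a shared flag;
layered implantation (implanting into a prior simulation) shifts all
prior coordinates and supports two-genome designs for junction
sampling.

What the simulator does **not** emulate: sequence decay of old
elements (benchmark implants have clean TIRs/TSDs unless degradation
is requested explicitly), methylation, genome-scale repeat complexity,
and sequencing error. Perfect recall/precision on these genomes
therefore demonstrates the correctness of the machinery under its own
model, not expected performance on a real, decayed genome — on real
data the mismatch budgets do the work, and their specificity trade-off
is the combined-score analysis above.

## Problem sizes and numerical choices

The test suite and acceptance script use a 2-Mb background with 60
implants for end-to-end recovery, 50 × 5-kb sequences for the
brute-force scanner cross-check, 20 random 8-leaf trees for NJ
additivity, and 20 two-genome simulations of 25 junction reads each
for the sharing-fraction estimate; these sizes give exact or
low-variance answers while keeping a full run in minutes. Local
alignment uses `Biostrings::pairwiseAlignment`; its gap parameters are
expressed so that a length-k gap costs 2 + (k − 1), matching the
declared scoring. All randomness flows from a single integer seed per
operation; scanning and classification are deterministic and
order-independent.

## Known limitations

* Element strand is reported as `*`: the TIR grammar is
  strand-symmetric and interior homology is not consulted for
  orientation.
* The flank copy-number statistic saturates for flanks inside long
  tandem arrays and is undefined (`NA`) when both flanks are
  unavailable or N-rich (> 10% N).
* The Ds1/Ds-l4 boundary without a family consensus is a pure length
  rule and will misclass a hypothetical sub-500-bp Ds-l4.
* Compound decomposition requires the internal TSD copies to be exact;
  decayed compounds decompose as a single core.
* Junction matching assumes display reads in 5'-terminus orientation
  (host flank then TIR), the orientation the read generator produces.
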