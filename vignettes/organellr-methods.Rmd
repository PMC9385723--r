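---
title: "Methods: organelle genome finishing, repeat landscapes and plastid-to-mitochondrion transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle genome finishing, repeat landscapes and plastid-to-mitochondrion transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`organellr` implements the bespoke computational stages of a plant
organelle-genome study as a tested, reusable pipeline: finishing a
mitogenome assembly from a unitig graph with long-read support, profiling
its repeat landscape, detecting plastid-derived fragments in the
mitogenome and classifying their origin, and ranking hypervariable
intergenic spacers to build diagnostic species markers. This vignette
explains the models and procedures, the parameters that matter, the
synthetic-data generator used for validation, and the numerical choices
and limitations a careful user should know about.

## Coordinate and topology conventions

All coordinates are 1-based inclusive, matching GenBank and the R
sequence packages (Biostrings, IRanges); report files therefore need no
conversion. Circular genomes are first-class: an interval with
`start > end` wraps the origin and means `[start, L] U [1, end]`. The
allowed alphabet is `A/C/G/T/N`; other ambiguity codes are rejected at
construction so dirty input fails at the boundary, not deep inside an
algorithm.

## Resolving double-bifurcation structures

Plant mitogenomes carry dispersed repeats long enough to collapse in a
short-read assembly. In the unitig graph each collapsed 2-copy repeat
appears as a segment with two entries and two exits (a
double-bifurcation structure, DBS, the `>  =  <` shape); the traversal
pairing of entries to exits is ambiguous without long-range evidence.

The resolver enumerates every perfect matching of entries to exits (n!
matchings; n is 2 for 2-copy repeats, and graphs with more than four
entries are rejected rather than silently approximated). Each matched
pair is turned into a junction candidate sequence: the last `flank` bp
of the entry segment, the repeat, and the first `flank` bp of the exit,
orientations applied and GFA overlaps trimmed once. Long reads vote on
candidates through an internal mapper: exact k-mer anchors (default
`k = 15`) chained on their modal diagonal, with a read supporting a
junction only when its anchors cover at least `min_span` bp (default
200, clamped to the available flank) on *both* sides of the repeat. The
span rule encodes "the read distinguishes this junction": reads that
only touch the repeat cannot vote. Scoring is strand-symmetric by
construction, since both read orientations are anchored.

The matching with the largest total support wins; the repeat segment is
duplicated so each entry runs through its own copy to its matched exit.
Ties are broken deterministically toward the lexicographically smallest
concatenated candidate sequence and flagged `LOW_CONFIDENCE`; all-zero
support leaves the DBS intact, flagged `UNRESOLVED`. DBSs are processed
in segment-id order and re-detected after every resolution, because
resolving one repeat can expose or simplify another. The finished
molecule is an Eulerian circuit over the resolved bidirected graph
(Hierholzer's algorithm with lexicographic arc order), emitted from the
smallest segment id in forward orientation so repeated runs produce
byte-identical FASTA.

Defaults (`flank` 1000 bp, `k` 15, `min_span` 200 bp) were chosen once
for the study conditions — 1–5 kb repeat arms and reads a few kb long —
and are exposed as arguments. Read length must exceed
`repeat + 2 * min_span` for junctions to be resolvable at all; shorter
reads lower support towards zero rather than corrupting the choice.

A biological caveat: where repeats truly recombine in vivo, several
isomers coexist and the dominant-path rule picks one master circle. For
an inverted-repeat DBS the two matchings correspond exactly to the two
SSC-orientation isomers of a plastome; which one the reads favour is a
property of the read sample, not of the algorithm.

## Repeat landscape

**Microsatellites.** Perfect SSRs of unit 1–6 bp at MISA-style
thresholds (`1-10 2-5 3-4 4-3 5-3 6-3`, minimum copies per unit length).
A run is reported once under its shortest explaining period (motif
primitivity check), with maximal coordinates — the reported interval
cannot be extended in either direction without breaking perfection, and
may therefore end in a partial copy while `copies` counts whole copies.
Circular scanning appends the leading 240 bp and deduplicates wrapped
hits; origin-spanning runs longer than that window are out of scope.
Adjacent SSRs within 100 bp share a `compound` group id but are counted
individually, so counts can be compared under either compound
convention.

**Dispersed repeats.** Maximal arm pairs in three orientations —
forward (direct copy), palindromic (reverse-complement copy), reverse
(reversed, non-complemented copy) — with Hamming distance at most 3
between arms and length at least 30 bp. Seeds are exact k-mers; the
seed length is the largest k that the pigeonhole principle still
guarantees to occur in every arm pair capable of passing the
expectation-value filter (a pair of length `l` with `m` mismatches
contains an exact block of at least `ceiling((l-m)/(m+1))` bases), so k
adapts upward on large genomes where short noisy pairs are filtered
anyway. Consecutive seeds on one diagonal collapse to a single
representative, and extension runs in lock-step over all seeds,
exploring every split of the mismatch budget between the two directions
and keeping the longest result. Significance uses a binomial expectation value,
`E = L^2 * P(Hamming <= m | length)` under uniform composition, filtered
at `1e-4`; the filter is intentionally simple and documented rather than
a reimplementation of any specific tool's statistic. Detected pairs may
extend a few chance-matching bases beyond a planted copy; tests
therefore assert containment of the planted arms and re-verify the
Hamming bound on every reported pair. Hits inside annotated IRs are not
excluded: the IR pair itself is legitimately the dominant palindromic
repeat of a plastome.

**Tandem arrays.** A simplified tandem finder, not a reimplementation of
the full TRF probabilistic model: candidate periods are seeded by
positions matching their period-shifted copy, short interruptions are
bridged only when both flanking match-runs are substantial, and each
candidate array is scored against its majority-consensus unit tiled
across the array (match +2, mismatch −7, identity ≥ 80%, score ≥ 50,
period ≤ 500, ≥ 2 copies). Overlapping explanations keep the smallest
period. Because the consensus alignment is gap-free, arrays whose copies
differ by indels are found only if the seeding still chains; this is a
declared approximation, and validation is property-based (planted arrays
recovered; no perfect arrays on random sequence) rather than
count-matching.

**Quadripartite structure.** The longest pair of disjoint
reverse-complement-identical intervals of at least 1 kb defines the IR
pair; boundaries are extended maximally with circular wrap. The longer
arc between the IRs is the LSC, the shorter the SSC, and labels are
assigned so the circle reads LSC–IRa–SSC–IRb. Assembly comparison tests
equality up to rotation and global reverse complement, then retries
after reverse-complementing the detected SSC in place — the two
coexisting plastome isomers compare as
`identical_after_ssc_inversion`.

## Plastome–mitogenome homology and transfer origin

Fragment detection is seed-and-extend: exact 13-mer seeds on both
strands, ungapped X-drop extension (match +2, mismatch −3, X-drop 20),
and merging of alignments that overlap or abut within 10 bp on both
genomes on compatible diagonals (band 20). Merged, cross-diagonal
fragments are re-scored by affine-gap pairwise alignment
(Biostrings); single-alignment fragments keep their exact ungapped
identity. This replaces a full gapped extension: for organelle
homologies, which are recent and largely colinear, diagonal-band merging
recovers small indels while keeping the engine simple and fast.
Significance is the Karlin–Altschul form `E = K m n exp(-lambda S)` with
`lambda` solved at runtime from the score scheme under uniform
composition and `K` fixed at 0.35; the default cutoff is `1e-5`. At that
cutoff an exact match must be ~27 bp to qualify, so spurious fragments
between unrelated 100 kb sequences are expected well below one per
pair — the specificity the tests assert.

Fragments are labelled F1..Fn by ascending mitogenome coordinate.
Origin classification searches each fragment's plastid-side sequence
against an outgroup genome pair with the same engine and cutoff,
requiring ≥ 70% query coverage for a presence call (the coverage guard
stops a 20 bp sliver from counting as "found"). The decision table:
present in both outgroup genomes → vertical (inherited from the common
ancestor); only in the outgroup plastome → horizontal plastid-to-
mitochondrion transfer; in neither → unresolved; only in the outgroup
mitogenome → unresolved and flagged anomalous. Both the sum of fragment
lengths and the union of mitogenome intervals are reported as genome
shares, since published totals do not always state which convention
they use.

## Hypervariable spacers and diagnostic sites

Intergenic spacers are taken between outermost gene boundaries in
circular gene order (the origin-spanning spacer included); intron-
containing genes count as one span. Per region, the species panel is
aligned by deterministic center-star: the sequence minimising summed
pairwise edit distance is the center, all others are aligned to it with
affine gaps (open 10, extend 2 — the classic DNA alignment settings for
spacer work), and the pairwise alignments are merged by gap projection.
Center-star is deliberate: it is deterministic, dependency-free, and
adequate for short, closely related spacers; it does not attempt the
iterative refinement of a full progressive aligner, so planted variants
inside homopolymer runs can surface in a shifted column. Tests
therefore check variant classes and counts, not exact columns.

Distances use the Kimura 2-parameter model with pairwise gap deletion
(sites where either row has a gap or `N` are dropped per pair):
`d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with transition fraction `P`
and transversion fraction `Q`. Saturated pairs where the logarithm
argument is non-positive are `NA` ("undefined"), never clamped. Regions
are ranked by the arithmetic mean over defined pairs, with median and
maximum also reported, since a published per-region "distance" statistic
can plausibly be any of the three; regions dominated by undefined pairs
rank last and are flagged.

Variant sites: a gap-free column with ≥ 2 bases is a SNP; a maximal run
of adjacent columns with an identical gap pattern collapses to one indel
event (so a 3 bp deletion is one site, matching how indel sites are
counted in barcoding work); columns mixing gaps with base variation
belong to the indel event. Diagnostic selection is greedy set cover over
unordered species pairs, restricted to the top-ranked regions:
repeatedly add the site discriminating the most uncovered pairs, ties
preferring the earlier-ranked region then the smaller column. Undefined
or missing states never discriminate. The result is independently
re-verified against the alignment, and on panels small enough for
exhaustive search the greedy size is compared to the true minimum under
the standard `ln(#pairs)` approximation bound. If some pair cannot be
separated at all, selection fails loudly and names the pair.

## The synthetic-data generator

Every stage is validated against generated inputs with planted ground
truth, because the study's real inputs are deposited accessions that
require a download. The generator emulates: circular genomes with
planted 2-copy repeat families (direct or inverted), perfect SSR runs, a
quadripartite plastome built as LSC + IRa + SSC + revcomp(IRa)
(including the real study's region sizes 82,838 / 24,959 / 18,316 bp,
totalling 151,072 bp), organelle pairs sharing planted fragments with an
outgroup pair wired for the vertical/horizontal decision table, species
panels mutated only within spacers (each species guaranteed one private
SNP or short deletion at a reserved position), and error-free or
substitution-mutated long reads sampled uniformly around the circle.

Two deliberate design points. First, all planted elements are *sealed*:
the bases flanking each copy are forced to break any chance extension,
so planted coordinates are exactly the maximal ones a correct detector
must report, and boundary tests can assert equality instead of
tolerances. Second, the unitig-graph builder collapses only exact
repeats, keeping the walk-spells-genome invariant unambiguous. Real
organelle repeats are near-exact rather than exact, real read error is
indel-rich rather than substitution-only, and real coverage is uneven —
none of which the generator imitates. Passing tests therefore
demonstrate algorithmic correctness under clean conditions, not
robustness to every artefact of real sequencing data.

Backgrounds are uniform over `A/C/G/T` with an optional GC skew;
detectors are composition-agnostic by design, and no test depends on
composition. All randomness flows from one integer seed; identical
configurations produce byte-identical FASTA/GFA/FASTQ outputs.

## Problem sizes and numerical choices

The test and acceptance workloads use genome sizes the methods are
routinely run at in interactive work: 20–30 kb circles for resolution
(20 random seeds, repeat arms 1–5 kb), 5 kb sequences for the SSR
brute-force cross-check (50 seeds), 100 kb genome pairs for homology
recall/specificity (20 seeds), the full 151 kb plastome for structure
detection, and an 18-species panel (153 pairs) for marker selection.
These sizes exercise every code path, including the full-scale
quadripartite detection, while keeping a complete run to a few minutes.

Numerical details worth stating: the K2p closed form is evaluated in
double precision with no series approximation, and is checked against
direct evaluation on enumerated (P, Q) grids to 1e-12; Karlin–Altschul
`lambda` is found by `uniroot` to its default tolerance at call time;
E-value filters compare on the raw double, with no rounding before the
cutoff; all detector outputs are sorted on deterministic keys so reports
are reproducible byte-for-byte; ties anywhere in the pipeline break
lexicographically, never by hash order.

## Known limitations

* DBSs with more than four entries (repeat copy number > 4) are rejected;
  the enumeration would need 120+ matchings and long-read support rarely
  separates them.
* Repeats or planted elements spanning the assembly origin are not
  generated, and origin-spanning SSR runs longer than the 240 bp wrap
  window are missed.
* The tandem finder's gap-free consensus scoring under-reports arrays
  whose copies differ by indels.
* The homology engine is nucleotide-only and ungapped at the extension
  level; diverged (< ~80% identity) or heavily indel-ridden homologies
  will fragment or be missed.
* Center-star alignment can shift indel placement inside homopolymer
  runs relative to a progressive aligner; column-level comparisons
  across tools should allow for that.
* Published genome-scale counts (SSR totals, dispersed-repeat totals,
  fragment counts for the deposited accessions) are parameter-sensitive
  reimplementations of named tools; this package reproduces the
  procedures and validates them on planted truth, and recomputing the
  published counts requires the deposited records as input.
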