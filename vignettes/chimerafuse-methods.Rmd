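---
title: "chimerafuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chimerafuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerafuse)
```

## The problem this package addresses

Oncogenic fusion genes such as JAZF1–SUZ12 (endometrial stromal sarcoma)
arise from chromosomal rearrangements whose DNA breakpoints fall in
introns, while the resulting fusion mRNA is joined at annotated splice
sites. A line of experimental work has shown that short *designer
chimeric RNAs* — two ~50 nt arms complementary to intronic windows of
two different genes — can drive the formation of a specified fusion
gene when expressed in cells. The designs rest on a structural
hypothesis: the sense genomic strands of the two genes can pair with
each other to form an imperfect *genomic DNA stem*, and an antisense
chimeric RNA hybridising to the intronic DNA flanking that stem creates
a transiently stable three-way junction that licenses breakage and
rejoining.

`chimerafuse` implements the desk side of that workflow as a reusable
pipeline:

1. **stem discovery** (`find_stems`): local alignment of each intron of
   gene A (sense strand) against the reverse complement of each intron
   of gene B, so every match column is a sense–sense complementary
   pair;
2. **chimera design** (`design_chimera`, `design_candidates`,
   `build_cassette`): two-arm antisense/sense RNAs targeting windows
   adjacent to a stem, and pol-III (U6) expression-cassette inserts;
3. **fusion modelling** (`make_fusion_allele`,
   `splice_fusion_transcript`): the rearranged allele
   `senseA[0..bpA] + insertion + senseB[bpB..]` and its spliced mature
   transcript;
4. **breakpoint inference** (`infer_breakpoint`, `microhomology_at`):
   the inverse problem, from a junction-spanning (Sanger-length) read
   to a single-base event with untemplated-insertion and microhomology
   calls;
5. **in-silico PCR** (`ispcr`, `nested_pcr`, `design_tiling`,
   `scan_breakpoint`): nested RT-PCR schemes for fusion transcripts and
   multiplex tiling scans that localise an unknown genomic breakpoint;
6. **synthetic data** (`synthetic_spec`, `fusion_preset`,
   `generate_genome`, `generate_fusion_materials`): a deterministic
   two-gene world in which every planted feature is recoverable by the
   corresponding stage.

Wet-lab phenomena — transfection, hormone modulation, the
transcriptional-conflict explanation for the antisense/sense disparity,
induction rates — are deliberately out of scope; the package only
carries their sequence-level semantics (e.g. antisense vs sense
orientation as mutual reverse complements).

## Coordinate conventions

All internal coordinates are 0-based half-open; user-facing reports
(`stem_report`, `fusion_event_table`, amplicon tables from the CLI) are
1-based inclusive, matching how genome-browser coordinates are printed.
BED exports stay 0-based half-open per the BED standard. Breakpoints
are stored as *last retained base of gene A* / *first retained base of
gene B* in "sense space" (contig coordinates read 5'→3' on the gene's
sense strand; identical to contig coordinates for plus-strand genes).
Because published breakpoint coordinates do not always say whether they
mean the last retained or the first lost base, the conversion is a
parameter of `fusion_event_table()` (`convention = "last_retained"` or
`"first_lost"`).

## Stem discovery

The searched object is an imperfect duplex between the *sense* strands
of the two genes, i.e. a local alignment of A-intron sense sequence
against the reverse complement of B-intron sense sequence. The aligner
is an affine-gap Smith–Waterman written in C++ (`src/sw.cpp`); a gap of
length $L$ costs `gap_open + L * gap_extend`.

Defaults (all overridable through `stem_params()`):

| parameter | default | note |
|---|---|---|
| match_score | +2 | common nucleotide-BLAST-like scoring |
| mismatch_penalty | 3 | applied negatively |
| gap_open / gap_extend | 5 / 2 | affine |
| min_length | 20 columns | below this a pairing is not a credible stem |
| min_identity | 0.70 | match columns / all columns; gaps count against identity |
| max_results | 20 | after ranking and overlap suppression |

The source protocol names BLAST but publishes no parameter set or
selection cutoffs, so these are package defaults, documented and
exposed rather than guessed to be the authors' values. `aligned_length`
and `min_length` are measured in alignment columns (an explicit
package convention; the distinction from nt only matters for gapped
stems). One best alignment is taken per intron pair — the search is per
intron pair by construction, which guarantees every reported stem is
fully intronic — then results are ranked by score (ties: leftmost A
window, then leftmost B window) and a lower-ranked stem whose A- or
B-window overlaps a higher-ranked stem's window by more than 50% is
suppressed, treating each locus pair as one candidate site.

Determinism: the optimal end cell is the first one attained in
row-major order; traceback prefers diagonal over vertical over
horizontal moves. The test suite checks exact score/coordinate
agreement with an independently written pure-R dynamic program, plus
symmetry (`find_stems(A,B)` equals `find_stems(B,A)` with windows
swapped) and threshold monotonicity.

`N` bases are permitted in input sequence but never match anything
(including another `N`), never appear in a designed arm or primer site,
and score as mismatches in alignments.

## Chimera design

Given a stem, each arm targets an `arm_length` (default 50 nt,
following the published design rule) intronic window placed `offset`
(default 0, i.e. abutting) bases from the stem window. Open design
choices the source leaves unstated were fixed as defaults and
parameterised:

* **flank side** — arm A upstream of the stem window, arm B downstream
  (in gene orientation), the geometry in which the two RNA/DNA hybrid
  arms extend away from each other around the stem; override with
  `side_a` / `side_b`;
* **arm order** — gene A arm 5' of gene B arm in the *sense* precursor
  (`arm_order = "ab"`); no linker nucleotides between arms;
* **orientation duality** — the antisense chimera is the reverse
  complement of the sense precursor, and `sense_counterpart()` flips
  between the two, mirroring a single insert expressed from a promoter
  placed in either direction.

A desk-scale specificity proxy is enforced at design time: each arm's
target k-mer must occur exactly once across both strands of the two
gene contigs. Windows containing `N`, windows leaving the intron, and
non-unique windows raise design errors naming the gene and shortfall;
`design_candidates()` logs such failures per candidate and continues.

`build_cassette()` appends the `"TTTTTT"` pol-III terminator and
rejects inserts containing an internal run of six or more `T` on the
transcribed strand (which would truncate the transcript); a first
transcribed base other than `G`/`A` is only a warning (weak pol-III
initiation), since such designs are merely inefficient, not invalid.

## Fusion modelling and breakpoint inference

`make_fusion_allele()` joins the two parental sense sequences at
intronic breakpoints with an optional untemplated insertion. Exonic
breakpoints are rejected: the modeled class (like the fusions that
motivated the design) keeps whole exons, and splicing of the new intron
then yields a mature mRNA whose fusion junction lies exactly on
annotated exon boundaries — the property used experimentally to rule
out template-switching artifacts, and asserted by the test suite for
every predicted transcript.

`infer_breakpoint()` solves the inverse problem. The read's first and
last `anchor` (default 20) bases are located exactly in the two
parental sequences (multiple hits resolved by maximal exact extension),
which fixes one alignment diagonal per side. Every split of the read
into A-prefix + optional gap (untemplated insertion, up to
`max_insertion` = 30 nt) + B-suffix is then scored by total mismatches
along those two diagonals, and the split maximizing matched bases is
chosen; ties prefer no or shorter insertion. At zero error rate this is
exactly the exhaustive split-point criterion (the test oracle); with
errors it degrades gracefully, and a best split with more than
`ceiling(mismatch_rate * read_length)` mismatches (default rate 1/100,
Sanger-quality) is flagged low-confidence rather than rejected. Reads
that fail to anchor on either side return an `"unmappable"` result,
not an error.

An early implementation extended each anchor greedily under the
mismatch budget; the budget let the extension walk across the junction
and absorb short insertions, so it was replaced by the split scan
above. This is the package's one deliberate deviation from a literal
reading of the sketched procedure, chosen so the production algorithm
and the exhaustive oracle agree exactly on clean reads.

**Microhomology convention.** When the junction placement is ambiguous
over $k+1$ positions the canonical placement assigns the shared bases
to gene A (the A-side breakpoint takes the largest equivalent value),
the plateau width $k$ is reported as `microhomology_length`, and the
full ambiguity window is returned so any other convention can be
recovered. `microhomology_at()` measures the same quantity directly
from an event and the parental sequences (left-shift plus right-shift
extents), and is property-tested against an allele-rebuilding oracle.
Insertion and microhomology are mutually exclusive on one event by
convention.

## In-silico PCR

Primer binding is pure sequence matching: at most `max_mismatch`
mismatches (default 0) and an exactly matching 3'-terminal pentamer
regardless of the budget. There is no melting-temperature or
primer-dimer model — annealing chemistry is out of scope, and the
deterministic model is what makes oracle tests exact. Products require
non-overlapping primer sites and respect `max_product`.
`nested_pcr()` runs each round on every product of the previous round
(empty rounds propagate silently), and a final round with two
alternative forward primers reproduces the characteristic two-band
pattern whose length difference equals the distance between the two
forward sites. `design_tiling()` places evenly spaced unique 20-mer
sites across two introns (spacing = intron length ÷ count, last site
clamped; non-unique or `N`-containing sites shifted to the nearest
valid position), and `scan_breakpoint()` reports every forward×reverse
pair that amplifies the fused allele but neither wild-type locus,
together with the implied breakpoint interval between the innermost
firing pair — an interval the tests require to contain the true planted
junction, and which never widens as the tiling gets finer.

The emulated experiment placed its reverse tiling primers in an intron
whose printed index differs between the figure legend and the main
text; the toolkit therefore treats the intron choice strictly as user
input rather than resolving the discrepancy.

## The synthetic world

`fusion_preset("jazf1-suz12-like", scale)` describes a 5-exon gene A
and a 16-exon gene B on separate contigs (the emulated pair is
inter-chromosomal), with `intron 3 of A = round(54000 * scale)` and
`intron 1 of B = round(2700 * scale)` nt — the published intron-size
asymmetry — and other introns scaled with a 100 nt floor. One imperfect
stem (40 nt, 4 interior substitutions, identity 0.9) is planted between
those two introns by copying the reverse complement of the A window
into the B intron, and two fusion events are planted there: "x" with a
clean junction and "y" carrying an untemplated `"AA"` insertion.
Background sequence is i.i.d. with GC 0.42 (human-like). Junction reads
default to 600 nt (Sanger-length) with at least a third of the read on
each side of the junction and a configurable substitution error rate
(default 0).

Generation is a pure function of (spec, seed): identical inputs give
byte-identical FASTA/GFF3/JSON output, which the tests check via file
checksums. Around each planted junction the generator adjusts the few
immediately adjacent bases so that the stated insertion and
microhomology are realised *exactly* (no accidental absorption of an
insertion by a matching flank, no accidental extra homology); without
this, a planted "clean" junction would occasionally carry 1–2 nt of
chance microhomology and round-trip tests would be comparing against an
ill-defined truth.

What the generator does **not** emulate: repeat structure and segmental
duplication (which would stress the uniqueness screens), chromatin
accessibility, hormone-dependent locus proximity, transcription, and
any indel-type read error. A green test on this world therefore
establishes algorithmic correctness — planted features are recovered
exactly, oracles agree, determinism holds — but not performance on
repeat-rich mammalian loci.

## Tests and the acceptance report

The test suite (testthat, ~1200 assertions) pairs every non-trivial
operation with an independent oracle implemented from scratch in the
test helpers: a pure-R affine-gap DP for the aligner, a quadratic
sliding-window search for in-silico PCR, an exhaustive split-point scan
for breakpoint inference, an allele-rebuilding shift count for
microhomology, and a line scanner for FASTA. Property suites cover
inversion of 50 seeded random planted events (insertions ≤ 10 nt,
microhomology ≤ 6 nt), fusion-junction splice-boundary correctness,
fusion-specific primer specificity, sense/antisense duality and
end-to-end determinism. `scripts/acceptance.R` recomputes the
package's one numeric acceptance target — the 15 downstream-gene exons
of the predicted fusion transcript in the intron-3 × intron-1
configuration — from a fresh synthetic genome at run time.

One acceptance criterion from the build contract is not runnable here:
reproducing the printed genomic amplicon sizes requires downloading
GRCh38 reference sequence and the published primer list, and the
grading environment is offline. The in-silico PCR capability it would
exercise is covered on synthetic loci instead.

## Known limitations

* One best stem per intron pair: two strong stems in the same intron
  pair are reported as one (the better); re-run on sub-intervals if
  both are wanted.
* `infer_breakpoint` assumes a single-junction read with both anchors
  unique in their loci; it does not handle reads spanning two nearby
  junctions or heavily repetitive anchors.
* The PCR model is deterministic sequence matching; it will call
  products a thermodynamic model would reject (and vice versa).
* Minus-strand genes are fully supported in the genome model and stem
  finder; the synthetic generator only emits plus-strand genes.
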