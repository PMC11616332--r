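---
title: "Classifying Cas9 repair outcomes at a CAG-repeat amplicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Cas9 repair outcomes at a CAG-repeat amplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagrepair)
```

## The problem

A Cas9-induced double-strand break at or near an expanded CAG tract (such
as the one in *HTT* exon 1, where 40 or more units cause Huntington's
disease) is repaired through several competing pathways, and the repair
products tell the story: classical end joining leaves small indels and a
characteristic single-base duplication at a staggered cut; microhomology-
mediated (polymerase-theta) end joining excises the entire tract between
short repeated words in the flanks; homology-driven repair contracts the
tract in frame. Deep sequencing of the edited amplicon measures the
mixture of these products, but only after a chain of processing decisions
— quality filtering, pair merging, alignment, repeat genotyping and
categorisation — each of which can distort the measured proportions.

`cagrepair` implements that measurement chain as a tested pipeline, with a
ground-truth read simulator so every stage can be validated end to end,
plus the companion calculators used around such experiments: DNA
end-resection quantification from restriction-protection qPCR, ChIP/DRIP
percent-input and fold enrichment, contraction fractions from capillary
electrophoresis, and label-free proteomics differential abundance.

## Outcome categories

Each classified read is assigned to one of six headline categories, driven
by two quantities: the net indel length change (frameshift if not a
multiple of 3) and the repeat count relative to the unedited allele.

* **UNEDITED** — no indels (substitution-only reads stay here);
* **Ins CAG / Del CAG** — in-frame gain/loss of repeat units;
* **Ins / Del** — frameshift caused by insertions only / deletions only;
* **Indel** — frameshift with both event kinds.

A seventh internal label, **OTHER_INFRAME**, holds the rare in-frame read
whose indels leave the tract unchanged (a pure-flank in-frame indel).
The six categories above do not name this corner; it is reported alongside
them rather than silently folded in, so headline proportions are never
distorted.

On top of the category, each read is annotated with repair signatures:
whole-tract excision (a deletion covering the annotated repeat interval),
microhomology length and word at deletion junctions (most often CC/GG at
this locus), templated insertions (a copy of nearby flank sequence, the
polymerase-theta signature), and the staggered-cut single-base insertion
(duplication of the 4th nucleotide upstream of the PAM, the "−4 rule":
here a single inserted A).

## Coordinates and cut geometry

All coordinates are 0-based and half-open; cut sites are between-base
indices, which removes off-by-one ambiguity from junction arithmetic. For
a guide with protospacer at `[p, p+20)` and PAM at `[p+20, p+23)` on the
plus strand, the blunt cut sits between `p+16` and `p+17` (3 nt 5' of the
PAM) and the staggered-cut donor base is `p+16`. Guides whose protospacer
lies inside the repeat tract match at several registers; all placements
are counted and the leftmost is used.

The bundled default locus is a synthetic 242 bp amplicon with (CAG)41 at
`[58, 181)`. The flanks are not genomic sequence: they are constructed to
have matched length, to contain no CAG triplet, and to carry the
structural features the analysis needs — a guide ending 6 nt upstream of
the tract and one cutting 3 nt downstream (both with an adenine donor
base), and CC/GG words within 10 nt of both tract boundaries so that
whole-tract microhomology deletions exist. Any real locus can be supplied
as FASTA plus a JSON annotation via `read_locus()`.

## The read simulator defines the study conditions

`simulate_reads()` draws each read's outcome class from a user mixture and
builds the edited template exactly, so the truth table (class, repeat
count, net indel, expected category, signature flags) is known per read.
Defaults mirror the emulated assay: 250 bp paired-end reads, one million
reads per sample, constant Phred 30, zero substitution error unless
requested. The classes and their construction:

* `UNEDITED`; `STUTTER` — whole-unit slippage with probability
  `slip_prob` (default 0.02), geometric magnitude, 9:1 contraction bias.
  The modelled experiments report exact whole-unit stutter in unedited
  samples but no rate, so these defaults are explicit placeholders and
  are exposed in the class parameters;
* `INFRAME_DEL_CAG` / `INS_CAG` — in-frame loss (1–40 units) or gain
  (1–5 units, keeping templates within merging range of 250 bp reads);
* `WHOLE_TRACT_MH_DEL` — deletion spanning the whole tract plus 0–10
  flank nt whose junction carries a ≥2 nt repeat from the CC/GG word set;
  candidates are enumerated on the locus and sampled uniformly;
* `STAGGERED_INS` — duplication of the donor base at the blunt cut;
* `TEMPLATED_INS` — 4–12 nt copied from within 25 nt upstream of the cut;
* `FLANK_DEL` — 1–20 nt deleted near the cut, inside the flank;
* `DUAL_CUT_EXCISION` — deletion between two guides' blunt cuts;
* `COMPLEX` — a deletion at the cut plus a separated insertion whose net
  change is never a multiple of 3. The separation (12 nt) is deliberate:
  a deletion and an equally long insertion at the same point is
  mathematically a substitution run and carries no indel signal, so a
  composite class only has a well-defined expected category when its two
  events cannot be blurred into score-equivalent decompositions.

Because classes whose frame depends on a sampled size (flank deletions,
whole-tract deletions outside the default word set) can map to different
categories read by read, the truth table carries a per-read
`expected_category` computed from the generator's own ground truth with
the same category rules; validation compares classifier output against
those labels, and the drawn class mixture against the requested one.

What the simulator does *not* emulate: realistic position-dependent
Illumina error profiles, indel sequencing errors, chimeric reads or index
hopping, and PCR amplification bias beyond repeat stutter. Passing the
closure tests therefore shows the analysis chain is internally correct
and robust to uniform substitution noise — not that every artefact of a
real sequencing run is handled.

## Read processing choices

**Quality filter.** Reads with mean Phred below 5 are discarded
(inclusive boundary), a deterministic reading of the original trimming
threshold; the cutoff is a parameter.

**Pair merging.** Best ungapped overlap of the reverse-complemented mate,
requiring ≥20 nt overlap and ≤10% overlap mismatches; disagreements
resolve to the higher-quality base, merged quality is the per-base
maximum. The upstream tool's exact parameters are not published; these
are the package's own defaults, surfaced in the API.

**Alignment.** An affine-gap pairwise aligner (match +1, mismatch −2, a
gap of length L costs 6 + 0.5 L) aligns each merged read to the amplicon.
Two numeric decisions matter and both are documented choices:

* *Global, not fitting.* Merged reads span the complete PCR product, so
  the reference is consumed end to end. The alternative — free reference
  end-skips — turns out to be fragile: for a whole-tract deletion read,
  sequencing errors in the shorter flank make "skip the reference prefix
  and dump the flank as a read-end insertion" score above the true 133 nt
  deletion, corrupting ~10% of such reads at 1% error. Fitting alignment
  remains available (`free_ref_ends = TRUE`) for partial reads.
* *Identity = matching read bases / read length.* A deleted reference
  segment involves no read base, so a clean whole-tract excision scores
  ~1.0; random DNA lands at 0.25–0.4 and is rejected by the 0.6 gate.
  Counting deletion columns would reject the dominant biological outcome
  (a 123 nt excision is more than half the amplicon); counting indel
  events as single columns lets gap-chasing alignments of random DNA
  creep up to the gate.

Tie-breaks prefer mismatch over insertion over deletion, and all indels
are then left-normalised (shifted to their leftmost equivalent placement,
as in variant normalisation), so junction coordinates are reproducible.
The aligner is cross-checked in the test suite against
`Biostrings::pairwiseAlignment` under identical scoring.

**Repeat genotype.** `count_repeats()` finds the longest exact tandem run
of the motif (any phase, leftmost tie-break) — the standalone primitive,
validated against an exhaustive search. For classification, however, the
repeat count is called from the alignment: tract length plus the net
indel change intersecting the annotated tract. The difference matters
only under sequencing noise: one substitution splits an exact (CAG)41 run
into two ~20-unit runs although the tract length is unchanged. The
original analysis used a score-based tandem-repeat finder that tolerates
mismatches; the alignment-derived count is the analogous tolerant caller,
and the two coincide on error-free reads (enforced by the closure tests).

**Flank-change calls.** A read is flank-changed if any indel cannot be
placed, under any equivalent placement, inside the repeat interval. Using
the full placement range (not just the left-aligned position) prevents
overcalling flank changes at the tract's left edge, where left-alignment
pushes tract-internal deletions into the flank.

**Clustering.** Greedy, abundance-sorted: a read joins the first cluster
whose representative has identical length and ≥95% ungapped identity
(inclusive). Classification is per merged read; clusters feed the
top-variants report only.

## Stutter handling

`estimate_stutter()` builds the empirical distribution of unit change
among in-frame, tract-only reads of an unedited control. When a control
is supplied, `summarize_outcomes()` subtracts the scaled stutter halo from
the observed in-frame length distribution (non-negativity clamp, then
renormalisation), scaling by the unedited fraction estimated from the
zero-change mass. Both raw and corrected tables are always reported,
since the original analysis states stutter was "included" without giving
a method; a control deconvolved against itself correctly leaves a point
mass at zero change.

## Assay calculators

**Resection.** `ssDNA% = 100 / (2^(ΔCq − 1) + 0.5)` with ΔCq the digested
minus mock Cq. The value is 100 at ΔCq = 0, strictly decreasing, and
negative ΔCq clamps to 100 with a warning. Technical replicates are
averaged on the Cq scale before exponentiation; biological replicates are
summarised (mean ± SD) after transformation. Cells are flagged against a
site-specific unedited baseline, defaulting to the 10% cutoff observed in
unedited samples; the baseline is a flag, not a subtraction, since the
original procedure used it as a visual cutoff. The Cq simulator is the
analytic inverse, so the round trip is exact at zero noise.

**ChIP/DRIP enrichment.** `recovery% = 100 · 2^((Cq_input − log2(dilution))
− Cq_IP)`; fold enrichment is the recovery ratio over the reference
region, significant at ≥2-fold (inclusive).

**Capillary electrophoresis.** Peaks below 5% of the tallest peak's
height are excluded (inclusive boundary), then percent shortened is the
area fraction outside the full-length product. Full-length matching uses
a ±2 bp sizing window (the instrument's sizing error; configurable),
and products larger than full length + tolerance are reported separately
as possible expansions rather than silently inflating "shortened".

**LFQ differential abundance.** Proteins with fewer than 3 valid values
in *both* groups are dropped — the literal reading, so a protein fully
present in one group and absent in the other (an on/off protein) is
kept; the stricter either-group reading is a flag. Intensities are
log10-transformed (matching the volcano-plot convention of the modelled
analysis); missing values are imputed per sample from
`Normal(mean − 1.8·sd, (0.3·sd)²)`; equal-variance two-sample t-tests
(Welch by flag) give p-values; q-values are Benjamini–Hochberg by
default, with seeded group-label permutation FDR as an option (the
upstream tool's default was likely permutation-based — a documented
divergence). Significance requires q < 0.05 and |fold change| ≥ 1.5 on
the linear scale. The `difference` column is the second group's mean
minus the first's with labels ordered alphabetically, so swapping labels
negates every difference.

## Problem sizes and numerical checks

The package's own validation runs use 50,000-read simulations for the
generator–classifier closure (error-free and at 1% substitution error),
1,000 random 300-mers against the exhaustive repeat-run search, 500
random deletions against placement-enumeration microhomology, a 32-cell
resection round trip, and 2,000-protein LFQ matrices (5 + 5 replicates)
for null calibration and power; these sizes give binomial noise well
inside the tolerances being checked while keeping a full run in minutes.
Reported empirical behaviour (closure error, flag precision/recall, LFQ
recall and FDR) is computed by `scripts/acceptance.R` at run time, not
stated here.

## Known limitations

* Expansions beyond the read length are invisible — a ~250 bp read
  cannot span a product much longer than the unedited amplicon, so the
  pipeline measures contractions far better than expansions.
* The classifier is per-read: unique molecular identifiers, consensus
  building and PCR duplicate structure are out of scope.
* The stutter model's rates are placeholders (the modelled data
  constrain its existence, not its magnitude).
* The LFQ stage starts from a protein intensity matrix; peptide roll-up
  and raw-spectra processing belong to upstream tools.
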