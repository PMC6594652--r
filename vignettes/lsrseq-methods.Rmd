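---
title: "lsrseq: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lsrseq: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the junction
model and breakpoint conventions, the alignment engine, the statistical
machinery, every tunable default with its rationale, and what the
synthetic-data generator does and does not emulate.  It states no
empirical result that the test suite does not itself compute.

## Biological setting

AID (activation-induced deaminase) initiates double-strand breaks in the
repetitive, G-rich switch (S) regions of the IgH locus.  Classical class
switch recombination (CSR) joins the donor Sμ to a downstream acceptor S
region.  The same machinery can instead join Sμ to "like-switch" repeats
flanking the 3′ regulatory region (3′RR) super-enhancers — duplicated in
humans as 3′RR1 and 3′RR2 — deleting the whole constant-gene cluster and
silencing the B-cell receptor.  Both event classes are read out by nested
PCR across the junction and amplicon sequencing; the computational task
is to turn junction-spanning reads into breakpoint-resolved, deduplicated
junction calls and to relate the breakpoints to sequence features (AID
hotspots, APOBEC3 sites, G-quadruplexes).

## Coordinates and the canonical junction

All public coordinates are 0-based half-open; a *break* is an inter-base
position in `[0, region length]`.  This makes microhomology arithmetic
unambiguous: a junction is fully described by
`(donor_break, acceptor_break, mh_len, insertion_seq)` with the
reconstruction identity

```
donor[.. donor_break) + insertion_seq + acceptor[acceptor_break + mh_len ..)
```

reproducing the read across the junction window.  Given the two flank
alignments, both flanks are first **maximally extended by perfect
matches** toward the junction.  A read overlap claimed perfectly by both
references is microhomology, assigned to *both* flanks with breaks
reported at the outer edges (donor break at the rightmost donor-matching
position, acceptor break at the leftmost acceptor-matching position);
an empty overlap is blunt; read bases claimed by neither flank are an
insertion.  Exactly one of `mh_len > 0` and a non-empty insertion can
hold; an overlap containing a mismatch to either reference is shrunk to
the maximal perfectly shared core, residual bases becoming insertion.

### Anchor robustness

A local aligner will happily extend a flank *across* the junction when
the score gain of further matches exceeds the mismatch/gap penalties —
in a repetitive locus this is common, and it corrupts the diagonal on
which the perfect-extension convention operates.  `classify_structure()`
therefore evaluates a small set of candidate anchorings per flank:

* the end of the longest gapless block of the alignment (immune to
  gapped over-extension);
* that anchor retracted to the nearest run of ≥ 10 consecutive matches
  (immune to gapless over-extension through a mismatch);
* the anchor extended along its diagonal, hopping isolated mismatches
  confirmed by ≥ 4 downstream matches (absorbs sequencing errors sitting
  between a conservatively trimmed segment end and the true junction).

Each candidate split is scored by how cheaply it reconstructs the
junction window — 2 per mismatching base, 1 per inserted base — and the
cheapest split wins.  On error-free reads all candidates coincide; the
cost model only arbitrates genuinely ambiguous representations, always
deterministically.

## Alignment engine

Reads are aligned by exact 12-mer seeding (a read/region/orientation
triple is attempted only if it shares a seed) followed by affine-gap
Smith–Waterman (Gotoh) in compiled code: match +2, mismatch −3, gap of
length L costs 5 + 2L.  The floor for reported segments — 20 bp at ≥ 90 %
identity — mirrors the classical dot-plot criterion that delineates
switch-like repeats.

Because the single best local alignment of a chimeric read can bridge
the junction through a low-identity stretch, each alignment is
decomposed into gapless blocks and, within every block, maximal
subsegments are extracted under a scoring that *encodes the identity
floor* (match +1, mismatch −t/(1−t), i.e. −9 at t = 0.9): any stretch
below threshold identity has negative drift and cannot be bridged.  The
read intervals left and right of the alignment are then searched
recursively, so a donor flank masked by a bridging alignment is still
recovered.  When a placement ties in score across reference offsets —
unavoidable in tandem repeats — the smallest reference start is kept and
the segment is flagged `multi_mapped`.

Assembly accepts only deletional junctions (donor forward toward the
read 5′ end, acceptor forward toward the 3′ end); reads whose flanks
disagree in orientation are tallied as `orientation_conflict` and
excluded, and wholly reverse-complemented reads are re-oriented before
assembly.  Among competing acceptor windows the highest-scoring segment
wins (ties: longer segment, then lexicographic region id; surviving ties
are flagged).  An intermediate-role segment (Sγ/Sα remnant) between the
flanks — or substituting the acceptor flank — makes the junction
`complex`; its structure fields describe the donor-side junction and the
remnant's own interval is recorded.

## Feature scans

* **AID hotspots**: every 4-mer is tested against WRCY and RGYW
  (W = A/T, R = A/G, Y = C/T); overlaps are all reported and a 4-mer such
  as AGCT yields one occurrence per matched class.  N never matches.
* **APOBEC3**: TC on the stored strand, GA as the opposite-strand TC.
* **G4Hunter**: run-based scores (+min(run, 4) per G, −min(run, 4) per C,
  0 for A/T/N), windowed arithmetic means, tracts where |mean| ≥
  threshold with overlapping windows merged and sign giving the strand.
  Window 25 and threshold 1.2 follow the published G4Hunter method; the
  source assay does not state the values it used, so figure tracks are
  not bit-reproducible and both knobs are exposed.
* **Repeats**: a gapless diagonal scanner (direct and inverted
  orientation, self-comparisons exclude the main diagonal) reporting
  merged qualifying windows of ≥ 20 bp at ≥ 90 % identity.  Gapless by
  design: the dot plot is used descriptively, and gapless diagonals
  reproduce the tandem-repeat block pattern without importing a full
  gapped aligner's scoring.  Repeat hits are paired intervals and are
  therefore exported as TSV rather than BED.

## Break statistics

Distance from a break to a feature is edge distance: 0 within or on the
boundary of an occurrence, else the gap to the nearest interval edge —
the most conservative choice given the 4 bp vs 2 bp motif lengths.  The
random-break null is **exact**: `expected_random_distance()` enumerates
every inter-base position of the region's amplifiable interval and
averages the distances; no Monte Carlo is involved (a sampling oracle is
used in the tests only to cross-check the enumeration).  The null is
restricted to the amplifiable interval because PCR cannot observe breaks
beyond the primers.  Observed-vs-null comparison uses a two-sided
Mann–Whitney U test plus the difference of means; the test was not named
by the assay's description, so the machinery reports both the statistic
and the means and users may substitute their own test.  Structure
distributions are compared by Pearson chi-square without continuity
correction (Fisher's exact test is substituted and flagged when an
expected count falls below 1).

## Quantification

Unique junctions are keyed on
`(donor_region, donor_break, acceptor_region, acceptor_break,
insertion_seq, junction_type, intermediate_region)` — coordinates and
junctional sequence, *not* the raw read string — so clonally redundant
reads carrying sequencing errors away from the junction still collapse.
The per-million denominator is all reads entering the caller
(pre-filter); `sample_quant()` exposes the counts so a
junction-spanning-only denominator can be derived if preferred.
Multi-primer libraries (hs3 / hs1,2 / hs4 amplicons) merge by key union
with read counts summed and per-amplicon provenance retained.

## The simulator: a stated world

`simulate_reads()` emulates junction-spanning amplicon reads from a
nested-PCR library sequenced single-end at 200 bp:

| parameter | default | rationale |
|---|---|---|
| read length | 200 bp | single-end amplicon sequencing of the assay |
| structure mix | 8 % blunt / 70 % microhomology / 22 % insertion | suicide-recombination junction sets are microhomology-dominated with few blunt joins (reported blunt fraction 7.8 %) |
| mh / insertion lengths | truncated geometric, means 4.1 / 4.9 bp | reported mean lengths for such junctions; realism defaults only, never asserted as outputs |
| complex fraction | 0.14 | ~14 % of junctions carry a downstream S remnant |
| clone size | geometric, mean 5 | clonal redundancy the deduplication step must undo |
| background | 10 % junction-free reads | off-target amplification and carrier DNA |
| error model | substitutions only, default 0 | keeps acceptance thresholds interpretable |
| donor flank in read | 40–120 bp | junction must sit inside the read with alignable flanks |
| repeat-unit divergence | 10 % | see below |

Synthetic references are tandem arrays of motif-bearing units with
seeded point divergence between copies, flanked by random sequence and
annotated as like-switch intervals.  The 10 % divergence default is the
realistic choice: real switch repeats hover near the 90 %-identity /
20 bp detection threshold of the classical dot-plot criterion, i.e.
copies are similar but far from identical.  (At a few percent divergence
a synthetic array becomes *more* self-identical than real switch DNA and
short flanks place ambiguously across copies — a property of degenerate
references, not of the caller, and visible through the `multi_mapped`
flag.)

Requested microhomologies are realised by searching the acceptor for an
existing occurrence of the donor flank's terminal k-mer (with maximality
guards so the canonical microhomology equals the requested one), rather
than by editing the acceptor sequence: edits to a shared reference would
interfere across the many junctions drawn from one region.  A
consequence of this conditioning is that the *realised* microhomology
distribution is shorter than the configured geometric (long shared
k-mers between distinct synthetic regions are rare — mean ≈ 2.9 bp under
defaults against a configured 4.1 bp).  All recovery tests therefore
compare against the truth table, which records the realised, canonical
values; blunt and insertion joins carry analogous guards so every truth
record is exactly the canonical description of its read.

For break-placement experiments (`placement = "motif_targeted"`),
breaks are drawn around AID hotspot centres with Gaussian jitter.  The
acceptance check of directional motif proximity uses insertion-only
joins, because blunt/microhomology feasibility guards condition the
break position on local sequence context — a thinning that would itself
bias distances; with insertions the drawn break is emitted verbatim.

**What a green test does not establish.**  The generator emulates read
structure, clonality, dilution and substitution noise.  It does not
model homopolymer indel errors (real single-end amplicon data from
semiconductor sequencing contains them; the caller tolerates them only
as alignment artifacts), PCR chimeras, quality-score structure, primer
mispriming, or the true long-range homology structure of the IgH locus.
Green acceptance tests establish the correctness of the algorithms on
the stated world, not assay-level accuracy on patient material — the
assay's own headline fractions derive from undeposited data and are
deliberately never asserted.

## Numerical and degenerate-input choices

* N bases never match motifs, score 0 in G4Hunter, break repeat
  diagonals and count as mismatches in alignment and extension.
* Empty feature lists make distance reports an error (distance to
  nothing is undefined) and empty call sets propagate as header-only
  tables and zero quantities.
* All tie-breaks are deterministic (smallest reference start; highest
  score, then longest, then lexicographic region id), so identical
  inputs and seeds give byte-identical outputs — reruns of the pipeline
  are compared by checksum in the acceptance suite.
* Derived seeds stay below 2^31; region builders save and restore the
  RNG state so they can be called inside a seeded simulation without
  perturbing its stream.

## Known limitations

* Substitution-only error tolerance: reads with true indels near the
  junction may shift canonical breakpoints by the indel length.
* Breakpoint placement inside long perfect repeats is fundamentally
  ambiguous; the convention makes it deterministic, not "correct".
* The microhomology length distribution of simulated junctions is
  conditioned on k-mer availability between synthetic regions (above).
* Inversional junctions are tallied (`orientation_conflict`) but not
  characterised; the assay models deletional joins only.
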