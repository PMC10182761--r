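---
title: "Detecting and drawing plastome junction sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and drawing plastome junction sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpjunctions)
```

## The problem

Chloroplast genomes are (usually) circular molecules of roughly 120–170 kb
with a quadripartite structure: large single-copy region (LSC), inverted
repeat b (IRb), small single-copy region (SSC), inverted repeat a (IRa),
where IRa is the reverse complement of IRb. The four region boundaries
(JLB, JSB, JSA, JLA) move as the IR expands or contracts, which is read by
comparing the genes adjacent to the junctions across species.

The obstacle is the deposited linearization. GenBank records cut the
circle at an arbitrary point: most start at the first base of the LSC, but
a substantial minority start inside the LSC, inside an IR arm, or at/inside
the SSC, and then one region — and any gene crossing the cut — is split
across the sequence origin and written with start > end
(`join(x..n,1..y)` for features). A junction analysis that assumes
LSC-first input mislabels regions or fails outright on such records.
`cpjunctions` treats the starting point as a nuisance parameter and removes
it before any junction is computed.

## The detection procedure

**Canonical k-mer scan.** The sequence is decomposed into overlapping
k-mers (default k = 55 bp, step 1 bp; for circular records the windows wrap
the origin so every base starts one window). Each window is counted under
its *canonical* form — the lexicographically smaller of the k-mer and its
reverse complement — so a k-mer inside IRb and its mirror inside IRa share
one key with count 2, while k-mers in single-copy territory have count 1.
Windows containing non-ACGT letters are excluded (never single-copy, and
they break exact-match extension): a conservative choice that avoids
treating ambiguity runs as unique sequence.

**Rotation point.** Among all positions whose canonical k-mer is
single-copy, the longest maximal run (wrap-aware) is located and the
sequence is rotated to start at its midpoint. A rule of the form "after N
consecutive single-copy k-mers, start there" needs a value of N and can sit
arbitrarily close to an IR boundary; the midpoint of the longest run is
parameter-free, dominates any fixed N, and maximizes the distance of the
new origin from both IR boundaries, so the IR is guaranteed not to straddle
the start of the rotated sequence. Ties between equally long runs go to the
run with the smaller deposited start. A genome with no single-copy k-mer at
all (e.g. a perfect whole-molecule duplication) has no usable rotation
point and is reported as such.

**Inverted-repeat search.** On the rotated (wrap-free) sequence the
package looks for the maximum-length pair of non-overlapping substrings in
which one is the exact reverse complement of the other. Exact matches are
found by seeding: windows of `seed_len` (default 20 bp, about the minimum
exact-match length a practitioner would use for repeats of this size; arms
shorter than the seed are undetectable) are hashed, and a window matching
the reverse complement of another yields a seed pair (i, j). All seeds of
one exact inverted match share the anti-diagonal i + j, with consecutive i,
so maximal exact matches are recovered as runs of consecutive seeds within
an anti-diagonal group — which also makes each recovered match *maximal*
(extension is free in both directions). Matches on the same anti-diagonal
separated by at most `chain_gap` bp (default 10) are chained into one arm
pair; this tolerates the handful of point differences between the two
deposited IR copies seen in some records while never bridging distinct
repeats (a chained gap is recorded on the result as its divergence).
Palindromic matches that would overlap themselves are truncated to the
longest non-overlapping sub-pair (on anti-diagonal c a match starting at p
is capped at ⌊(c − 2p + 1)/2⌋). Ties among equal-length candidates go to
the leftmost first arm, then the leftmost second arm. Low-complexity
blowup is bounded by skipping seed k-mers occurring more than 64 times.

**Classification and mapping back.** Arm coordinates are mapped to the
deposited orientation by the rotation inverse (an interval crossing the
origin is wrap-encoded, start > end). The two single-copy gaps between the
arms are measured on the circle: the longer is LSC, the shorter SSC, and
the arm immediately following the LSC in forward order is IRb. When the two
gaps are exactly equal the gap containing deposited base 1 (else the gap
with the lower start) is labeled LSC — an arbitrary but deterministic and
documented rule. A gap of length zero (arms abutting; an SSC fully absorbed
by the IR) is rejected as a degenerate tetrad: such a molecule has only
three regions and the four-junction display is not defined for it.

**Filter.** Genomes whose longest IR arm is shorter than `min_ir_len`
(default 100 bp — short enough to keep true IRs, long enough to discard
tRNA-scale incidental repeats) are excluded, as are genomes with no
`/gene`-bearing features; the verdict carries the failed rule ("IR < 100
bp" / "unannotated"). The threshold is a strict less-than: an arm of
exactly 100 bp passes.

**Standardization.** The accepted genome is rotated so the LSC starts at
base 1, giving the display order LSC–IRb–SSC–IRa with IRa ending at the
last base. Gene segments are remapped; segments that had been split by the
deposited origin and become contiguous are merged back into one interval.

## Junctions and gene context

A junction's *position* is the coordinate of the last base of its upstream
region; the junction line sits between position and position + 1. This
makes "distance 0" well-defined: a gene whose boundary abuts the junction
has distance 0, and distances count the bases strictly between the gene
boundary and the line. The left flank of a junction is the gene whose
junction-proximal boundary is nearest upstream; the right flank nearest
downstream; a gene covering both sides populates the spanning slot (with
its per-side base counts, which for single-segment genes sum to the gene
length) and serves as both flanks. All distances are circular, so a gene
near base 1 is the right flank of JLA and a gene wrapping the origin spans
JLA. For multi-segment (join) genes the flank logic uses the union of
segments; the per-side split of a spanning multi-segment gene is counted
base-by-base against the circle cut at the junction, and the sum identity
is only guaranteed for single-segment genes. No distance cutoff is
applied: the nearest gene flanks a junction however far away it is, which
keeps sparse annotations drawable.

Per region, the drawing plan follows a 0/1/2+ rule: no genes — nothing
drawn; one gene — drawn mid-region with the region's endpoint coordinates
indicated; two or more — the first and last gene (ascending start in
region walking order) drawn at their true locations. A gene belongs to the
region containing its first base; this assigns junction-spanning genes to
their upstream region, matching how such genes are conventionally listed.

## Rendering

The figure is laid out deterministically: fixed row height, rows in input
order, and per-row bp→pixel scaling so every genome spans the same canvas
width (lengths are compared via the printed sizes, not the block widths;
with a global scale a 120 kb and a 210 kb genome could not share a
readable row). Regions shorter than the minimum visible width (40 px) are
widened to it, with their true size printed. Gene glyphs are arrows whose
direction encodes the strand (right = plus, left = minus). Labels are
placed under fixed approximate font metrics (7 px/character, 12 px line
height) by greedy lane assignment within per-row bands; a label that
cannot be placed without overlap within the lane budget is dropped (and
logged) rather than drawn on top of another — the diagram guarantees no
two text labels collide. SVG is the authoritative output and is
byte-identical across runs (no timestamps, fixed number formatting);
PDF/PNG renditions are drawn natively from the same layout through R's
graphics devices on a best-effort basis. Colors, fonts and pixel geometry
are fixed package defaults; tests assert structure (element counts, text,
marker direction), never pixels.

## The synthetic-plastome generator

Fixtures are built as LSC + IRb + SSC + revcomp(IRb) from uniform random
nucleotides under a fixed seed, annotated with a junction-exercising gene
catalog (a JLB-spanning *rps19*, a JSA-spanning *ycf1*, *trnH* near JLA,
*ndhF* near JSB, two rRNA genes inside the IR that are automatically
mirrored into the other arm), then rotated so deposited base 1 falls at
each of the nine starting-point groups. Groups a–h are rotations of one
molecule; group i is a variant whose SSC is shrunk to hold a single gene.
Three generator details matter for exact planted-truth recovery:

* **Uniqueness is checked, not assumed.** After generation, every
  canonical 55-mer window not fully inside an IR arm must be single-copy;
  a collision triggers regeneration under a perturbed seed (bounded
  retries). This enforces that the planted pair is the only inverted
  repeat of consequence.
* **Boundary guards.** One base at each planted arm flank is adjusted so
  the maximal exact match cannot extend past the planted boundary by
  chance (a 1-in-4 event per flank otherwise). Without the guard, "recover
  the planted arms exactly" would be unattainable by construction rather
  than by any defect.
* **Planted divergence.** `mutations_in_ira` point differences (kept ≥ 25
  bp from the arm ends, ≥ 3 bp apart) exercise the chaining tolerance.

What the generator does *not* emulate: real gene catalogs and densities,
pseudogenes, sequencing error, trans-spliced genes, base composition bias,
dispersed repeat families, or IRs diverging by indels (chaining assumes
collinear point differences). Passing the fixture sweep therefore
demonstrates correct coordinate arithmetic, rotation invariance, and
detection of clean IRs — not robustness to every artifact of real
deposited records. The companion script
`scripts/verify-refseq-junctions.R` closes part of that gap by comparing
detection against the published tetrad coordinates of 18 representative
RefSeq plastomes once those records are fetched.

## Validation scale and numerical choices

The test suite recovers planted truth over all nine groups × three size
profiles (LSC/IR/SSC = 900/300/200, 2000/500/400, 5000/1000/600 bp) ×
five seeds, chosen as the smallest sizes that still leave every region
much longer than k = 55 and the arms much longer than the seed; the
finder-vs-oracle sweep uses 200 random sequences of 400–1200 bp with
planted arms of 30–60 bp, where the pure-R brute-force oracle (a per
anti-diagonal scan of the complement-match matrix) is exact and fast. The
oracle comparisons run with `chain_gap = 0` because the oracle is by
definition exact-match; chaining is validated separately on fixtures with
planted divergence. Published coordinate tables are accepted as custom
junction input even when their two IR arms differ by a base or two (this
occurs in real annotation); the equal-arm invariant is enforced as a
warning for user-supplied tetrads, while partition and region order remain
hard errors.

Other deliberate choices: linear records are never rotated (rotating a
linear molecule is meaningless) and an IR arm touching a sequence end is
flagged as possibly truncated; the minimal-gene-content condition (IRa,
IRb, or SSC holding ≤ 1 gene) is reported as an auxiliary flag alongside
the positional group code a–h rather than replacing it, since the two
classifications are orthogonal; only the longest IR pair is reported
(aberrant multi-repeat architectures are out of scope); and coordinates
are 1-based inclusive throughout, matching GenBank convention, with
start > end encoding origin wrap everywhere a region or gene crosses the
cut.

## Known limitations

* IR arms shorter than `seed_len` (20 bp) are undetectable; arms between
  20 and 100 bp are detected and then filtered by default.
* IR copies diverging by insertions/deletions shift the anti-diagonal and
  are not chained; such genomes report the longest exact segment pair.
* A genome whose SSC has been entirely lost (arms abutting) is rejected
  rather than drawn as a tripartite structure.
* The per-side split of junction-spanning *multi-segment* genes is a
  base-count convention, not a biological statement about exon placement.
* Rendering drops labels (with a log message) when a row is too crowded
  for the lane budget; on toy-scale fixtures with dense annotation this
  can hide an endpoint label, whereas realistic 120–170 kb genomes are
  sparse at junction scale.
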