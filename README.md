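# cpjunctions

Junction-site analysis and visualization for chloroplast genomes.

Most plastomes are circular molecules with a quadripartite ("tetrad")
organization: a large single-copy region (LSC), a small single-copy region
(SSC), and two inverted-repeat arms (IRb, IRa) that are reverse complements
of each other. The four boundaries between these regions — JLB (LSC/IRb),
JSB (IRb/SSC), JSA (SSC/IRa), and JLA (IRa/LSC) — shift as the IR expands
or contracts during evolution, moving genes such as *rps19*, *ndhF*,
*ycf1*, and *trnH* between single-copy and repeat territory. Comparing the
genes flanking these junctions across species is a standard way to read IR
expansion/contraction, but deposited GenBank records are linearized at
arbitrary points of the circle: base 1 may sit anywhere — mid-LSC, inside
an IR arm, even splitting a region across the sequence origin — and naive
junction tools mislabel or fail on such records.

`cpjunctions` makes the analysis independent of the deposited starting
point:

1. **Rotation normalization.** The genome is scanned with canonical k-mers
   (k = 55, step 1; a k-mer and its reverse complement share one count).
   Positions whose canonical k-mer occurs exactly once are single-copy;
   the sequence is rotated to start at the midpoint of the longest
   single-copy run, guaranteeing the IR lies wholly inside the rotated
   sequence.
2. **IR detection.** A native seed-and-extend finder locates the
   maximum-length pair of non-overlapping substrings where one is the
   reverse complement of the other (exact matches on shared
   anti-diagonals, optionally chained across gaps of at most 10 bp to
   tolerate the point divergence present in some deposited IR copies).
3. **Tetrad classification.** The two single-copy gaps between the arms
   are measured on the circle; the longer is LSC, the shorter SSC, and the
   arm following the LSC is IRb. Coordinates are mapped back to the
   deposited orientation (a region spanning the origin is written with
   start > end). Genomes whose longest IR arm is under 100 bp, and
   genomes without gene annotation, are filtered out.
4. **Standardization and junctions.** The record is rotated so the LSC
   begins at base 1 (display order LSC–IRb–SSC–IRa), the four junction
   positions are read off the region ends, and each junction's flanking
   genes, distances, strands, and junction-spanning genes are computed.
5. **Rendering.** Any number (≥ 1) of genomes are stacked into one
   deterministic SVG diagram (PDF/PNG renditions drawn natively), one row
   per genome, with per-row scaling, strand-arrow gene glyphs (right arrow
   = plus strand, left = minus), distance annotations, and
   collision-free labels.

A synthetic-plastome generator produces ground-truth annotated GenBank
fixtures covering all nine deposited-starting-point groups (a: first base
of LSC, b: inside LSC, c/d: IRb, e/f: SSC, g/h: IRa, i: minimal gene
content), so the whole pipeline is testable without downloads.

## Worked example

Generate a group-h fixture (deposited base 1 inside IRa, so the IRa wraps
the origin) and run it through the pipeline:

```r
library(cpjunctions)

fx  <- generate_fixture(fixture_spec(start_group = "h", seed = 1))
res <- process_genome(fx$genome)
res$tetrad
#> <cpj_tetrad> genome length 1,700 bp
#>   LSC       201..1100      (900 bp)
#>   IRb      1101..1400      (300 bp)
#>   SSC      1401..1600      (200 bp)
#>   IRa      1601..200       (300 bp)  [wraps origin]
res$group$code
#> [1] "h"
res$standardized$tetrad
#> <cpj_tetrad> genome length 1,700 bp
#>   LSC         1..900       (900 bp)
#>   IRb       901..1200      (300 bp)
#>   SSC      1201..1400      (200 bp)
#>   IRa      1401..1700      (300 bp)
```

The detected tetrad is reported in deposited coordinates (note the
wrapping IRa, written start > end), matches the planted truth exactly, and
standardizes to LSC-first. The junction gene contexts:

```
JLB @ 900:  spanning rps19 (60|60 bp)
JSB @ 1200: left rrn23 (21 bp), right ndhF (4 bp)
JSA @ 1400: spanning ycf1 (50|50 bp)
JLA @ 1700: left rrn16 (70 bp), right trnH (2 bp)
```

i.e. *rps19* crosses the LSC/IRb junction with 60 bp on each side, *ndhF*
starts 4 bp into the SSC, *ycf1* spans SSC/IRa, and *trnH* sits 2 bp from
the IRa/LSC junction — the classic picture of the plastome junction
neighborhood. `run_junction_pipeline()` wires this end-to-end for many
records and writes the figure plus per-genome region and junction tables:

```r
run_junction_pipeline(inputs = c("a.gb", "b.gb"), outdir = "out",
                      formats = c("svg", "pdf", "png"))
```

A command-line front end (with a `make-fixtures` subcommand) is installed
at `inst/scripts/cpjunctions.R`:

```sh
Rscript inst/scripts/cpjunctions.R make-fixtures --outdir fixtures
Rscript inst/scripts/cpjunctions.R -o out fixtures/*.gb
```

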