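#!/usr/bin/env Rscript

# Network-dependent companion check: run tetrad detection on the 18
# representative RefSeq chloroplast genomes and compare the detected
# deposited-coordinate regions with the published values shipped at
# inst/extdata/refseq_tetrads.tsv.
#
# The records are not bundled and are not downloaded here; fetch them
# yourself (e.g. with NCBI efetch, format "gbwithparts") into a directory
# of <accession>.gb files, then run:
#
#   Rscript scripts/verify-refseq-junctions.R --gbdir <dir>
#
# Exit status 0 when every available record matches.

suppressPackageStartupMessages({
  library(optparse)
  library(cpjunctions)
})

parser <- OptionParser(option_list = list(
  make_option("--gbdir", type = "character", default = NULL,
              help = "directory containing <accession>.gb files"),
  make_option("--tolerance", type = "integer", default = 0L,
              help = "allowed per-coordinate deviation in bp [default %default]")
))
opt <- parse_args(parser)
if (is.null(opt$gbdir)) stop("--gbdir is required")

ref <- read.delim(system.file("extdata", "refseq_tetrads.tsv",
                              package = "cpjunctions"), comment.char = "#")
status <- 0L
n_checked <- 0L
for (r in seq_len(nrow(ref))) {
  acc <- ref$accession[r]
  gb <- file.path(opt$gbdir, paste0(acc, ".gb"))
  if (!file.exists(gb)) {
    message(acc, ": record not present, skipped")
    next
  }
  n_checked <- n_checked + 1L
  res <- process_genome(parse_genbank(gb))
  if (inherits(res, "cpj_skip")) {
    message(acc, ": FILTERED (", res$reason, ")")
    status <- 1L
    next
  }
  want <- parse_tetrad_string(ref$regions[r])
  ok <- TRUE
  for (nm in c("lsc", "irb", "ssc", "ira")) {
    dev <- max(abs(res$tetrad[[nm]]$start - want[[nm]]$start),
               abs(res$tetrad[[nm]]$end - want[[nm]]$end))
    if (dev > opt$tolerance) ok <- FALSE
  }
  grp_ok <- res$group$code == ref$start_code[r]
  if (ok && grp_ok) {
    message(acc, ": OK (group ", res$group$code, ")")
  } else {
    message(acc, ": MISMATCH\n  detected ", format_tetrad(res$tetrad),
            "\n  published ", ref$regions[r],
            if (!grp_ok) paste0("\n  group ", res$group$code, " != ",
                                ref$start_code[r]) else "")
    status <- 1L
  }
}
message(n_checked, " of ", nrow(ref), " records checked")
quit(status = if (n_checked == 0L) 1L else status)
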