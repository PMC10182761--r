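# Shared fixture helpers for the test suite.

# Write a generated fixture's GenBank text to a temp file; returns the path.
write_fixture_gb <- function(fx, dir = tempdir()) {
  path <- file.path(dir, paste0(fx$genome$accession, ".gb"))
  writeLines(fx$gb_text, path)
  path
}

# Canonical comparison form of a tetrad: label:start-end for all regions.
tetrad_signature <- function(t) format_tetrad(t)

# Rotation-invariant signature of the junction gene contexts of a
# processed genome: per junction, flank gene names, distances, and the
# spanning split. Identical across deposited rotations of one molecule.
distance_signature <- function(result) {
  vapply(result$view$contexts, function(cx) {
    paste(
      cx$junction$name,
      if (is.null(cx$left_gene)) "." else cx$left_gene$name, cx$left_distance,
      if (is.null(cx$right_gene)) "." else cx$right_gene$name, cx$right_distance,
      if (is.null(cx$spanning)) "." else {
        paste0(cx$spanning$gene$name, ":", cx$spanning$bases_on_left, "|",
               cx$spanning$bases_on_right)
      },
      sep = "/"
    )
  }, character(1L))
}

# A minimal hand-written GenBank record (independent of write_genbank).
minimal_gb_text <- function(sequence, topology = "circular",
                            accession = "TEST0001.1",
                            organism = "Testia minima",
                            feature_lines = character(0L)) {
  n <- nchar(sequence)
  seq_lines <- character(0L)
  low <- tolower(sequence)
  for (i in seq.int(1L, n, by = 60L)) {
    seq_lines <- c(seq_lines, sprintf("%9d %s", i, substr(low, i, min(i + 59L, n))))
  }
  c(
    sprintf("LOCUS       TESTREC %d bp DNA %s PLN 01-JAN-2024", n, topology),
    sprintf("ACCESSION   %s", sub("\\.\\d+$", "", accession)),
    sprintf("VERSION     %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf('                     /organism="%s"', organism),
    feature_lines,
    "ORIGIN",
    seq_lines,
    "//"
  )
}
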