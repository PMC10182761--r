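# GenBank flat-file writing (used by the synthetic fixture generator and the
# round-trip tests) and the tabular outputs.

# Location string for a gene; wrap-encoded segments are split into the
# standard join(x..n,1..y) form.
format_location <- function(gene, genome_length) {
  segs <- gene_segments_split(gene, genome_length)
  parts <- apply(segs, 1L, function(s) {
    if (s[1L] == s[2L]) sprintf("%d", s[1L]) else sprintf("%d..%d", s[1L], s[2L])
  })
  loc <- if (length(parts) > 1L) {
    sprintf("join(%s)", paste(parts, collapse = ","))
  } else {
    parts
  }
  if (gene$strand == "-") sprintf("complement(%s)", loc) else loc
}

# Render one genome as GenBank flat-file text.
format_genbank <- function(genome) {
  n <- genome$length
  out <- character(0L)
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %-8s PLN 01-JAN-2024",
                        genome$accession, n, genome$topology))
  out <- c(out, sprintf("DEFINITION  %s chloroplast, complete genome.", genome$organism))
  out <- c(out, sprintf("ACCESSION   %s", sub("\\.\\d+$", "", genome$accession)))
  out <- c(out, sprintf("VERSION     %s", genome$accession))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", n))
  out <- c(out, sprintf('                     /organism="%s"', genome$organism))
  out <- c(out, '                     /mol_type="genomic DNA"')
  for (g in genome$genes) {
    key <- if (g$kind %in% c("tRNA", "rRNA")) g$kind else "gene"
    out <- c(out, sprintf("     %-15s %s", key, format_location(g, n)))
    out <- c(out, sprintf('                     /gene="%s"', g$name))
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(genome$sequence)
  for (i in seq.int(1L, n, by = 60L)) {
    chunk <- substr(seq, i, min(i + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", i, paste(tens, collapse = " ")))
  }
  c(out, "//")
}

#' Write a genome as a GenBank flat file
#'
#' Emits the subset of the format read back by [parse_genbank()]: LOCUS line
#' with topology, VERSION, a source feature carrying `/organism`, one
#' feature per gene with `/gene` qualifier (origin-wrapping genes written as
#' `join(x..n,1..y)`), and the ORIGIN sequence block.
#'
#' @param genome an [annotated_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  writeLines(format_genbank(genome), path)
  invisible(path)
}

#' Write the per-genome region table
#'
#' One row per region per genome (accession, organism, region, start, end,
#' length), with coordinates in the deposited orientation; a start greater
#' than the end marks a region that wraps the sequence origin.
#'
#' @param results list of entries, each with elements `genome` (an
#'   [annotated_genome()]) and `tetrad` (a [tetrad()]).
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_region_table <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(tetrad_regions(r$tetrad), function(reg) {
      data.frame(accession = r$genome$accession, organism = r$genome$organism,
                 region = reg$label, start = reg$start, end = reg$end,
                 length = reg$length, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Write the per-genome junction table
#'
#' One row per junction per genome: junction name, position (standardized
#' coordinates), flanking genes with their distances to the junction line,
#' and the spanning gene with its per-side base counts when one gene crosses
#' the junction.
#'
#' @param results list of entries, each with `genome` and `contexts` (the
#'   output of [gene_context()] for the four junctions).
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_junction_table <- function(results, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(r$contexts, function(cx) {
      data.frame(
        accession = r$genome$accession,
        junction = cx$junction$name,
        position = cx$junction$position,
        left_gene = if (is.null(cx$left_gene)) NA_character_ else cx$left_gene$name,
        left_distance = if (is.null(cx$left_gene)) NA_integer_ else cx$left_distance,
        right_gene = if (is.null(cx$right_gene)) NA_character_ else cx$right_gene$name,
        right_distance = if (is.null(cx$right_gene)) NA_integer_ else cx$right_distance,
        spanning_gene = if (is.null(cx$spanning)) NA_character_ else cx$spanning$gene$name,
        spanning_left_bp = if (is.null(cx$spanning)) NA_integer_ else cx$spanning$bases_on_left,
        spanning_right_bp = if (is.null(cx$spanning)) NA_integer_ else cx$spanning$bases_on_right,
        stringsAsFactors = FALSE
      )
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
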