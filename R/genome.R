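# In-memory model: annotated genome, gene features, tetrad regions, IR pair.

IUPAC_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V")

#' Construct a gene feature
#'
#' @param name gene name (the `/gene` qualifier value).
#' @param strand `"+"` or `"-"`.
#' @param segments integer matrix with two columns (start, end), one row per
#'   location segment, 1-based inclusive; `start > end` marks a segment that
#'   wraps the sequence origin.
#' @param kind feature kind, one of `"gene"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @return object of class `cpj_gene`.
#' @export
gene_feature <- function(name, strand, segments, kind = "gene") {
  if (is.vector(segments)) segments <- matrix(segments, ncol = 2L, byrow = TRUE)
  storage.mode(segments) <- "integer"
  stopifnot(
    is.character(name), length(name) == 1L, nzchar(name),
    strand %in% c("+", "-"),
    is.matrix(segments), ncol(segments) == 2L, nrow(segments) >= 1L,
    all(segments >= 1L),
    kind %in% c("gene", "tRNA", "rRNA", "other")
  )
  structure(
    list(name = name, strand = strand, segments = unname(segments), kind = kind),
    class = "cpj_gene"
  )
}

# Total gene length under wrap semantics.
gene_length <- function(gene, genome_length) {
  sum(vapply(seq_len(nrow(gene$segments)), function(i) {
    ivl_length(gene$segments[i, 1L], gene$segments[i, 2L], genome_length)
  }, integer(1L)))
}

# Split any wrap-encoded segments into plain (non-wrapping) intervals.
gene_segments_split <- function(gene, genome_length) {
  out <- lapply(seq_len(nrow(gene$segments)), function(i) {
    s <- gene$segments[i, 1L]; e <- gene$segments[i, 2L]
    if (s <= e) matrix(c(s, e), ncol = 2L)
    else rbind(c(s, genome_length), c(1L, e))
  })
  do.call(rbind, out)
}

# First covered base in reading order (start of the first segment).
gene_first_base <- function(gene) gene$segments[1L, 1L]

#' Construct an annotated genome record
#'
#' @param accession record identifier.
#' @param organism organism name (the `/organism` qualifier).
#' @param sequence nucleotide string; lowercase accepted and uppercased.
#' @param topology `"circular"` or `"linear"`.
#' @param genes list of [gene_feature()] objects in record order.
#' @return object of class `cpj_genome`.
#' @export
annotated_genome <- function(accession, organism, sequence,
                             topology = c("circular", "linear"),
                             genes = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), IUPAC_LETTERS)
  if (length(bad) > 0L) {
    stop("sequence contains non-IUPAC characters: ", paste(bad, collapse = " "))
  }
  n <- nchar(sequence)
  for (g in genes) {
    if (any(g$segments > n)) {
      stop("gene '", g$name, "' has a coordinate beyond the sequence length ", n)
    }
  }
  structure(
    list(accession = accession, organism = organism, length = n,
         sequence = sequence, topology = topology, genes = genes),
    class = "cpj_genome"
  )
}

#' @export
print.cpj_genome <- function(x, ...) {
  cat(sprintf("<cpj_genome> %s (%s): %s bp, %s, %d gene feature(s)\n",
              x$accession, x$organism, format_bp(x$length), x$topology,
              length(x$genes)))
  invisible(x)
}

# --- tetrad ------------------------------------------------------------------

REGION_ORDER <- c("LSC", "IRb", "SSC", "IRa")

#' Construct a tetrad (the four-region partition of a plastome)
#'
#' Regions are given in deposited or standardized coordinates; any region may
#' wrap the origin (start > end). The constructor checks that the four
#' regions partition the circle in LSC, IRb, SSC, IRa walking order, that the
#' two IR arms have equal length, and that LSC is at least as long as SSC.
#'
#' @param lsc,irb,ssc,ira length-2 integer vectors `c(start, end)`.
#' @param genome_length total sequence length in bp. `NA` is accepted for a
#'   tetrad parsed from a coordinate string before its record is read (a
#'   wrapping region makes the length underdetermined); such a tetrad is not
#'   validated and carries `NA` lengths for wrapping regions.
#' @param validate set to `FALSE` to skip structural checks (used when
#'   carrying user-supplied junction coordinates verbatim).
#' @return object of class `cpj_tetrad`: named list of regions, each with
#'   `label`, `start`, `end`, `length`, plus `genome_length`.
#' @export
tetrad <- function(lsc, irb, ssc, ira, genome_length = NA, validate = TRUE) {
  genome_length <- as.integer(genome_length)
  mk <- function(label, iv) {
    iv <- as.integer(iv)
    stopifnot(length(iv) == 2L, all(iv >= 1L))
    if (!is.na(genome_length)) stopifnot(all(iv <= genome_length))
    len <- if (is.na(genome_length) && iv[1L] > iv[2L]) {
      NA_integer_
    } else {
      ivl_length(iv[1L], iv[2L], genome_length)
    }
    list(label = label, start = iv[1L], end = iv[2L], length = len)
  }
  t <- structure(
    list(lsc = mk("LSC", lsc), irb = mk("IRb", irb), ssc = mk("SSC", ssc),
         ira = mk("IRa", ira), genome_length = genome_length),
    class = "cpj_tetrad"
  )
  if (validate && !is.na(genome_length)) validate_tetrad(t)
  t
}

#' Validate tetrad invariants
#'
#' @param t a `cpj_tetrad`.
#' @return `t` invisibly; stops on violation.
#' @export
validate_tetrad <- function(t) {
  n <- t$genome_length
  regions <- list(t$lsc, t$irb, t$ssc, t$ira)
  total <- sum(vapply(regions, `[[`, integer(1L), "length"))
  if (total != n) {
    stop("tetrad regions do not partition the genome: lengths sum to ",
         total, ", genome length is ", n)
  }
  # Detected tetrads always have equal arms; user-supplied coordinates from
  # published tables occasionally differ by a base or two, so this is a
  # warning rather than an error.
  if (t$irb$length != t$ira$length) {
    warning("IRb length (", t$irb$length, ") != IRa length (", t$ira$length,
            ")")
  }
  if (t$lsc$length < t$ssc$length) {
    stop("LSC (", t$lsc$length, " bp) shorter than SSC (", t$ssc$length, " bp)")
  }
  # Walking order: each region must start right after the previous one ends.
  for (i in seq_along(regions)) {
    cur <- regions[[i]]
    nxt <- regions[[if (i == 4L) 1L else i + 1L]]
    expected <- (cur$end %% n) + 1L
    if (nxt$start != expected) {
      stop("region order violated: ", nxt$label, " starts at ", nxt$start,
           " but ", cur$label, " ends at ", cur$end)
    }
  }
  invisible(t)
}

#' @export
print.cpj_tetrad <- function(x, ...) {
  cat("<cpj_tetrad> genome length", format_bp(x$genome_length), "bp\n")
  for (r in list(x$lsc, x$irb, x$ssc, x$ira)) {
    cat(sprintf("  %-3s %9d..%-9d (%s bp)%s\n", r$label, r$start, r$end,
                format_bp(r$length), if (r$start > r$end) "  [wraps origin]" else ""))
  }
  invisible(x)
}

# Region list in walking order.
tetrad_regions <- function(t) list(t$lsc, t$irb, t$ssc, t$ira)

#' Format a tetrad as a region string
#'
#' Inverse of [parse_tetrad_string()]: produces
#' `"LSC:s-e;IRb:s-e;SSC:s-e;IRa:s-e"`.
#'
#' @param t a `cpj_tetrad`.
#' @return single string.
#' @export
format_tetrad <- function(t) {
  paste(vapply(tetrad_regions(t), function(r) {
    sprintf("%s:%d-%d", r$label, r$start, r$end)
  }, character(1L)), collapse = ";")
}

# --- IR pair -----------------------------------------------------------------

# Two repeat arms in one coordinate system. arm_1 is the arm with the lower
# start; labels (IRb/IRa) are assigned later by classify_tetrad().
ir_pair <- function(arm_1, arm_2, length, mismatch = 0L) {
  structure(
    list(arm_1 = as.integer(arm_1), arm_2 = as.integer(arm_2),
         length = as.integer(length), mismatch = as.integer(mismatch)),
    class = "cpj_irpair"
  )
}

#' @export
print.cpj_irpair <- function(x, ...) {
  cat(sprintf("<cpj_irpair> arms %d..%d / %d..%d, %s bp, %d mismatch bp\n",
              x$arm_1[1L], x$arm_1[2L], x$arm_2[1L], x$arm_2[2L],
              format_bp(x$length), x$mismatch))
  invisible(x)
}
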