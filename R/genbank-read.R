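# GenBank flat-file reading.
#
# No GenBank feature-table reader ships with the installed stack, so the
# subset of the format this tool needs (LOCUS topology, ACCESSION/VERSION,
# /organism, gene-bearing features with join/complement locations, ORIGIN
# block) is parsed here directly.

#' Read all records from a GenBank flat file
#'
#' @param path path to a `.gb`/`.gbk` flat file; multi-record files are
#'   split on `//` terminators and parsed record-by-record.
#' @return list of [annotated_genome()] objects.
#' @export
read_genbank_records <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  records <- Map(function(s, e) lines[s:e], starts, ends)
  records <- Filter(function(r) any(grepl("^LOCUS", r)), records)
  if (length(records) == 0L) stop("no GenBank record found in ", path)
  lapply(records, parse_genbank_record, path = path)
}

#' Parse a GenBank flat file into an annotated genome
#'
#' Reads the first record of `path`. Features lacking a `/gene` qualifier
#' are skipped; multi-interval (`join`) locations are preserved as multiple
#' segments; topology is taken from the LOCUS line and defaults to linear
#' when absent. A record with gene features sharing identical
#' (name, segments) — typically a gene and its CDS — contributes a single
#' feature, so each gene plots once.
#'
#' @param path path to a GenBank flat file with an ORIGIN sequence block.
#' @return an [annotated_genome()].
#' @export
parse_genbank <- function(path) {
  read_genbank_records(path)[[1L]]
}

parse_genbank_record <- function(lines, path = "<text>") {
  locus_i <- grep("^LOCUS", lines)[1L]
  locus <- if (!is.na(locus_i)) lines[locus_i] else ""
  topology <- if (grepl("\\bcircular\\b", locus, ignore.case = TRUE)) {
    "circular"
  } else {
    "linear"
  }

  accession <- NA_character_
  ver_i <- grep("^VERSION", lines)[1L]
  acc_i <- grep("^ACCESSION", lines)[1L]
  if (!is.na(ver_i)) {
    accession <- strsplit(trimws(sub("^VERSION", "", lines[ver_i])), "\\s+")[[1L]][1L]
  }
  if (is.na(accession) || !nzchar(accession)) {
    if (!is.na(acc_i)) {
      accession <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i])), "\\s+")[[1L]][1L]
    }
  }
  if (is.na(accession) || !nzchar(accession)) {
    accession <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1L]][1L]
  }

  # --- sequence ---------------------------------------------------------
  origin_i <- grep("^ORIGIN", lines)[1L]
  if (is.na(origin_i)) {
    stop("GenBank record ", accession, " in ", path, " has no ORIGIN sequence block")
  }
  seq_lines <- lines[seq.int(origin_i + 1L, length(lines))]
  seq_lines <- seq_lines[trimws(seq_lines) != "//"]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) {
    stop("GenBank record ", accession, " in ", path, " has an empty ORIGIN block")
  }

  # --- features ---------------------------------------------------------
  feat_i <- grep("^FEATURES", lines)[1L]
  feats <- list()
  organism <- NA_character_
  if (!is.na(feat_i)) {
    block <- lines[seq.int(feat_i + 1L, origin_i - 1L)]
    feats <- parse_feature_block(block)
    src <- Filter(function(f) f$key == "source", feats)
    if (length(src) > 0L && !is.null(src[[1L]]$qualifiers[["organism"]])) {
      organism <- src[[1L]]$qualifiers[["organism"]]
    }
  }
  if (is.na(organism)) {
    org_i <- grep("^\\s{2}ORGANISM", lines)[1L]
    organism <- if (!is.na(org_i)) trimws(sub("^\\s*ORGANISM", "", lines[org_i])) else "unknown"
  }

  genes <- list()
  seen <- character(0L)
  for (f in feats) {
    gene_name <- f$qualifiers[["gene"]]
    if (is.null(gene_name) || f$key == "source") next
    loc <- parse_location(f$location)
    key <- paste(gene_name, paste(t(loc$segments), collapse = ","), sep = "@")
    if (key %in% seen) next
    seen <- c(seen, key)
    kind <- switch(f$key, gene = "gene", tRNA = "tRNA", rRNA = "rRNA", "other")
    genes[[length(genes) + 1L]] <-
      gene_feature(gene_name, loc$strand, loc$segments, kind)
  }
  if (length(genes) == 0L) {
    cpj_log("warn", "record has no /gene-bearing features (unannotated)",
            accession = accession, stage = "parse")
  }

  annotated_genome(accession, organism, sequence, topology, genes)
}

# Split the FEATURES table into (key, location, qualifiers) entries.
parse_feature_block <- function(block) {
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) {
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
    feats
  }
  for (line in block) {
    if (grepl("^ {5}\\S", line)) {
      feats <- flush(cur, feats)
      parts <- regmatches(line, regexec("^ {5}(\\S+)\\s+(\\S.*)$", line))[[1L]]
      if (length(parts) == 3L) {
        cur <- list(key = parts[2L], location = parts[3L],
                    qualifiers = list(), in_location = TRUE)
      } else {
        cur <- NULL
      }
    } else if (!is.null(cur) && grepl("^\\s{6,}\\S", line)) {
      body <- trimws(line)
      if (startsWith(body, "/")) {
        cur$in_location <- FALSE
        m <- regmatches(body, regexec('^/([A-Za-z_0-9]+)=?"?([^"]*)"?$', body))[[1L]]
        if (length(m) == 3L) cur$qualifiers[[m[2L]]] <- m[3L]
      } else if (isTRUE(cur$in_location)) {
        cur$location <- paste0(cur$location, body)
      }
    }
  }
  flush(cur, feats)
}

# Parse a GenBank location string into strand + segment matrix.
# Handles n..m, single-base n, complement(...), join(...), order(...),
# nested complement(join(...)) and join(complement(..), ...); partial-end
# markers (< >) are stripped.
parse_location <- function(text) {
  text <- gsub("[<>[:space:]]", "", text)
  strand <- if (grepl("complement", text)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", text)
  parts <- strsplit(inner, ",")[[1L]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("unparseable feature location: ", text)
  segs <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (any(is.na(nums))) stop("unparseable feature location: ", text)
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2L)))
  list(strand = strand, segments = unname(segs))
}
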