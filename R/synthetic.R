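# Ground-truth synthetic plastomes: four-region circular molecules
# (IRa = reverse complement of IRb, optionally with point divergence),
# annotated with junction-exercising genes, rotated into any of the nine
# starting-point groups, and written as GenBank flat-file text.

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Run code with a private RNG state.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Default gene catalog: names follow the genes commonly found at plastome
# junctions. rps19 spans JLB (60 bp each side), ycf1 spans JSA (50|50),
# trnH sits 2 bp from JLA, ndhF 4 bp into the SSC.
default_fixture_genes <- function(lsc_len, ir_len, ssc_len,
                                  ssc_single_gene = FALSE) {
  g <- data.frame(
    region = c("LSC", "LSC", "LSC", "IRb", "IRb", "SSC", "SSC"),
    rel_start = c(3L, 121L, lsc_len - 59L,
                  max(1L, ir_len %/% 3L - 29L),
                  max(1L, min(2L * ir_len %/% 3L, ir_len - 79L)),
                  5L, ssc_len - 49L),
    length = c(70L, 80L, 120L, 60L, 80L, 90L, 100L),
    strand = c("-", "+", "+", "+", "-", "-", "-"),
    name = c("trnH", "matK", "rps19", "rrn16", "rrn23", "ndhF", "ycf1"),
    stringsAsFactors = FALSE
  )
  if (ssc_single_gene) g <- g[g$region != "SSC" | g$name == "ndhF", ]
  g
}

#' Specify a synthetic plastome fixture
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp
#'   (`lsc_len >= ssc_len >= 2`, `ir_len >= 1`).
#' @param start_group one of `"a"`-`"h"` (deposited starting point: first
#'   base of / inside LSC, IRb, SSC, IRa) or `"i"` (minimal-gene-content
#'   scenario; rotated like group a).
#' @param genes data frame with columns `region`, `rel_start` (1-based
#'   within the region), `length`, `strand`, `name`; a gene may run past
#'   its region end to span a junction. Genes placed wholly inside IRb are
#'   automatically mirrored into IRa (reverse strand), as in real
#'   plastomes. Default: a six-gene junction-exercising catalog.
#' @param seed integer seed for the nucleotide generator; generation is
#'   deterministic given the spec.
#' @param mutations_in_ira number of point differences planted in the IRa
#'   copy (exercises match chaining); placed at least 25 bp from the arm
#'   ends.
#' @return object of class `cpj_fixture_spec`.
#' @export
fixture_spec <- function(lsc_len = 900L, ir_len = 300L, ssc_len = 200L,
                         start_group = "a", genes = NULL, seed = 1L,
                         mutations_in_ira = 0L) {
  lsc_len <- as.integer(lsc_len); ir_len <- as.integer(ir_len)
  ssc_len <- as.integer(ssc_len)
  stopifnot(lsc_len >= ssc_len, ssc_len >= 2L, ir_len >= 1L,
            start_group %in% c(letters[1:9]),
            mutations_in_ira >= 0L)
  if (is.null(genes)) {
    genes <- default_fixture_genes(lsc_len, ir_len, ssc_len,
                                   ssc_single_gene = start_group == "i")
  }
  structure(
    list(lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len,
         start_group = start_group, genes = genes, seed = as.integer(seed),
         mutations_in_ira = as.integer(mutations_in_ira)),
    class = "cpj_fixture_spec"
  )
}

# Build the LSC-first molecule with boundary guards and a uniqueness check:
# every canonical 55-mer window not fully inside an IR arm must be
# single-copy, so the planted arms are the only inverted repeat and are
# exactly maximal. Retries with a perturbed seed when the check fails.
generate_molecule <- function(spec, k = 55L, max_attempts = 10L) {
  L <- spec$lsc_len; I <- spec$ir_len; S <- spec$ssc_len
  n <- L + 2L * I + S
  for (attempt in seq_len(max_attempts) - 1L) {
    chars <- with_seed(spec$seed + 7919L * attempt, function() {
      lsc <- rand_seq(L); irb <- rand_seq(I); ssc <- rand_seq(S)
      ira <- strsplit(revcomp(irb), "")[[1L]]
      if (spec$mutations_in_ira > 0L) {
        lo <- 26L; hi <- I - 25L
        if (hi < lo) stop("IR too short for the requested mutations")
        grid <- seq.int(lo, hi, by = 3L)
        pos <- sort(sample(grid, min(spec$mutations_in_ira, length(grid))))
        for (p in pos) {
          ira[p] <- setdiff(c("A", "C", "G", "T"), ira[p])[1L]
        }
      }
      c(strsplit(lsc, "")[[1L]], strsplit(irb, "")[[1L]],
        strsplit(ssc, "")[[1L]], ira)
    })
    # Boundary guards: stop chance extension of the planted arms.
    # Outer flank: LSC end vs. LSC start (after IRa, the circle closes).
    if (chars[L] == .COMP[[chars[1L]]]) {
      chars[L] <- setdiff(c("A", "C", "G", "T"), .COMP[[chars[1L]]])[1L]
    }
    # Inner flank: SSC first base vs. SSC last base.
    p1 <- L + I + 1L; p2 <- L + I + S
    if (p1 != p2 && chars[p1] == .COMP[[chars[p2]]]) {
      chars[p1] <- setdiff(c("A", "C", "G", "T"), .COMP[[chars[p2]]])[1L]
    }
    M <- paste(chars, collapse = "")
    if (n < k || molecule_is_clean(M, L, I, S, k)) return(M)
  }
  stop("could not generate a fixture without spurious repeats after ",
       max_attempts, " attempts")
}

# Uniqueness oracle: canonical k-mer counts over the circular molecule;
# windows not fully inside an IR arm must be single-copy.
molecule_is_clean <- function(M, L, I, S, k) {
  n <- nchar(M)
  prof <- kmer_profile(M, k, 1L, "circular")
  counts <- table(prof$canon)
  cnt <- as.integer(counts[prof$canon])
  i <- prof$starts
  in_irb <- i >= L + 1L & i + k - 1L <= L + I
  in_ira <- i >= L + I + S + 1L & i + k - 1L <= n
  all(cnt[!(in_irb | in_ira)] == 1L)
}

# Rotation offset (0-based) putting deposited base 1 at the group's
# starting point.
group_offset <- function(group, L, I, S) {
  switch(group,
         a = 0L, i = 0L,
         b = L %/% 3L,
         c = L,
         d = L + I %/% 3L,
         e = L + I,
         f = L + I + S %/% 3L,
         g = L + I + S,
         h = L + I + S + I %/% 3L)
}

#' Generate a synthetic plastome fixture
#'
#' Builds the LSC+IRb+SSC+IRa molecule from the spec's seed, plants the
#' gene catalog (mirroring IRb-internal genes into IRa), rotates the
#' molecule so deposited base 1 sits at the spec's starting-point group,
#' and renders GenBank flat-file text. The returned truth is the planted
#' tetrad and gene list in deposited coordinates (wrap-encoded where a
#' region or gene crosses the origin).
#'
#' @param spec a [fixture_spec()].
#' @param molecule optional pre-built LSC-first molecule for this spec
#'   (reused across rotations of one molecule; must come from
#'   an identical spec up to `start_group`).
#' @return list with `genome` (an [annotated_genome()]), `gb_text`
#'   (character vector of GenBank lines), `truth` (deposited-coordinate
#'   [tetrad()]), `genes` (deposited-coordinate gene list), `offset` (the
#'   rotation applied), and `spec`.
#' @export
generate_fixture <- function(spec, molecule = NULL) {
  stopifnot(inherits(spec, "cpj_fixture_spec"))
  L <- spec$lsc_len; I <- spec$ir_len; S <- spec$ssc_len
  n <- L + 2L * I + S
  M <- if (is.null(molecule)) generate_molecule(spec) else molecule
  stopifnot(nchar(M) == n)
  off <- group_offset(spec$start_group, L, I, S)
  deposited <- rotate_sequence(M, off)
  dep <- function(p) pos_from_deposited(p, off, n)

  region_off <- c(LSC = 0L, IRb = L, SSC = L + I, IRa = L + I + S)
  cat_rows <- spec$genes
  # mirror IRb-internal genes into IRa
  irb_internal <- cat_rows$region == "IRb" &
    cat_rows$rel_start + cat_rows$length - 1L <= I
  if (any(irb_internal)) {
    mir <- cat_rows[irb_internal, , drop = FALSE]
    r2 <- mir$rel_start + mir$length - 1L
    mir$region <- "IRa"
    mir$rel_start <- I - r2 + 1L
    mir$strand <- ifelse(mir$strand == "+", "-", "+")
    cat_rows <- rbind(cat_rows, mir)
  }

  genes <- lapply(seq_len(nrow(cat_rows)), function(i) {
    row <- cat_rows[i, ]
    a <- region_off[[row$region]] + row$rel_start
    b <- a + row$length - 1L
    if (b > n) stop("gene '", row$name, "' runs past the molecule end")
    da <- dep(a); db <- dep(b)
    segs <- if (da <= db) c(da, db) else rbind(c(da, n), c(1L, db))
    kind <- if (startsWith(row$name, "trn")) "tRNA"
            else if (startsWith(row$name, "rrn")) "rRNA" else "gene"
    gene_feature(row$name, row$strand, segs, kind)
  })

  truth <- tetrad(
    lsc = c(dep(1L), dep(L)),
    irb = c(dep(L + 1L), dep(L + I)),
    ssc = c(dep(L + I + 1L), dep(L + I + S)),
    ira = c(dep(L + I + S + 1L), dep(n)),
    genome_length = n
  )

  accession <- sprintf("SYN%s%04d.1", toupper(spec$start_group),
                       spec$seed %% 10000L)
  organism <- sprintf("Plastoma synthetica group-%s", spec$start_group)
  genome <- annotated_genome(accession, organism, deposited, "circular", genes)
  list(genome = genome, gb_text = format_genbank(genome), truth = truth,
       genes = genes, offset = off, spec = spec)
}

#' Generate the nine-group fixture suite
#'
#' Groups a-h are rotations of the same molecule (same seed), so their
#' standardized tetrads and gene-to-junction distances must agree exactly.
#' Group i is a separate molecule whose SSC is shrunk to hold a single
#' gene, raising the minimal-gene-content flag.
#'
#' @param base_spec a [fixture_spec()]; its `start_group` is ignored.
#' @param seed optional seed override.
#' @return named list of nine [generate_fixture()] results (`a`..`i`).
#' @export
generate_group_suite <- function(base_spec = fixture_spec(), seed = NULL) {
  if (!is.null(seed)) base_spec$seed <- as.integer(seed)
  out <- list()
  shared <- NULL
  for (g in letters[1:8]) {
    sp <- base_spec
    sp$start_group <- g
    if (is.null(shared)) shared <- generate_molecule(sp)
    out[[g]] <- generate_fixture(sp, molecule = shared)
  }
  ssc_genes <- base_spec$genes[base_spec$genes$region == "SSC", , drop = FALSE]
  keep <- if (nrow(ssc_genes) > 0L) {
    ssc_genes[order(ssc_genes$rel_start), ][1L, , drop = FALSE]
  } else {
    NULL
  }
  ssc_i <- if (!is.null(keep)) {
    max(keep$rel_start + keep$length - 1L + 10L, 50L)
  } else {
    max(50L, base_spec$ssc_len %/% 2L)
  }
  genes_i <- rbind(base_spec$genes[base_spec$genes$region != "SSC", , drop = FALSE],
                   keep)
  sp_i <- fixture_spec(base_spec$lsc_len, base_spec$ir_len,
                       ssc_len = min(ssc_i, base_spec$lsc_len),
                       start_group = "i", genes = genes_i,
                       seed = base_spec$seed,
                       mutations_in_ira = base_spec$mutations_in_ira)
  out[["i"]] <- generate_fixture(sp_i)
  out
}

#' Materialize a fixture suite as GenBank files
#'
#' Writes `<group>.gb` for each of the nine groups plus a synthetic-truth
#' region table (`truth_regions.synthetic.tsv`).
#'
#' @param outdir output directory (created if missing).
#' @param base_spec a [fixture_spec()] passed to [generate_group_suite()].
#' @return the fixture list, invisibly.
#' @export
write_fixture_suite <- function(outdir, base_spec = fixture_spec()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  suite <- generate_group_suite(base_spec)
  for (g in names(suite)) {
    writeLines(suite[[g]]$gb_text, file.path(outdir, paste0(g, ".gb")))
  }
  write_region_table(
    lapply(suite, function(f) list(genome = f$genome, tetrad = f$truth)),
    file.path(outdir, "truth_regions.synthetic.tsv")
  )
  invisible(suite)
}
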