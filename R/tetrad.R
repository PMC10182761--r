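# From an IR arm pair to the labeled four-region tetrad, the record filter,
# the LSC-first standardization, and the starting-point group.

#' Classify the tetrad from an inverted-repeat pair
#'
#' Measures the two single-copy gaps between the arms on the circle, labels
#' the longer gap LSC and the shorter SSC (a tie is broken in favour of the
#' gap containing deposited base 1, else the gap with the lower start), and
#' labels the arm immediately following LSC in forward wrap-aware order IRb,
#' the other IRa.
#'
#' @param ir a `cpj_irpair` in deposited coordinates (arms may wrap).
#' @param genome_length total sequence length in bp.
#' @return a validated [tetrad()] in deposited coordinates.
#' @export
classify_tetrad <- function(ir, genome_length) {
  n <- genome_length
  a1 <- ir$arm_1; a2 <- ir$arm_2
  after <- function(iv) (iv[2L] %% n) + 1L   # first base after the arm
  gap1_start <- after(a1)                    # gap following arm 1
  gap1_len <- circ_dist_fwd(gap1_start, a2[1L], n)
  gap2_start <- after(a2)                    # gap following arm 2
  gap2_len <- circ_dist_fwd(gap2_start, a1[1L], n)
  if (gap1_len == 0L || gap2_len == 0L) {
    stop("degenerate tetrad: IR arms abut, single-copy region of length 0")
  }
  gap_end <- function(gs, glen) ((gs - 1L + glen - 1L) %% n) + 1L
  g1 <- c(gap1_start, gap_end(gap1_start, gap1_len))
  g2 <- c(gap2_start, gap_end(gap2_start, gap2_len))

  lsc_is_g1 <- if (gap1_len != gap2_len) {
    gap1_len > gap2_len
  } else if (pos_in_ivl(1L, g1[1L], g1[2L])) {
    TRUE
  } else if (pos_in_ivl(1L, g2[1L], g2[2L])) {
    FALSE
  } else {
    g1[1L] < g2[1L]
  }
  if (lsc_is_g1) {
    tetrad(lsc = g1, irb = a2, ssc = g2, ira = a1, genome_length = n)
  } else {
    tetrad(lsc = g2, irb = a1, ssc = g1, ira = a2, genome_length = n)
  }
}

#' Filter verdict for a genome
#'
#' A genome is rejected when its longest inverted-repeat arm is shorter than
#' `min_ir_len` (strictly; an arm of exactly `min_ir_len` bp passes) or when
#' it carries no gene features.
#'
#' @param genome an [annotated_genome()].
#' @param detection the detection result for the genome: a `cpj_irpair`, a
#'   [tetrad()], or `NULL` when no inverted repeat was found.
#' @param params [detection_params()].
#' @return `list(pass = logical, reason = character)`; `reason` names the
#'   failed rule (`"IR < <min> bp"` or `"unannotated"`), empty on pass.
#' @export
passes_filter <- function(genome, detection, params = detection_params()) {
  arm_len <- if (is.null(detection)) {
    0L
  } else if (inherits(detection, "cpj_irpair")) {
    detection$length
  } else if (inherits(detection, "cpj_tetrad")) {
    detection$irb$length
  } else {
    stop("detection must be a cpj_irpair, cpj_tetrad, or NULL")
  }
  if (is.na(arm_len) || arm_len < params$min_ir_len) {
    return(list(pass = FALSE, reason = sprintf("IR < %d bp", params$min_ir_len)))
  }
  if (length(genome$genes) == 0L) {
    return(list(pass = FALSE, reason = "unannotated"))
  }
  list(pass = TRUE, reason = "")
}

#' Standardize the genome start to the first base of the LSC
#'
#' Rotates the genome so the LSC starts at base 1 and remaps all gene
#' segments and regions, yielding the LSC-IRb-SSC-IRa walking order with
#' IRa ending at the last base. Gene segments that were split by the
#' deposited origin and become contiguous after rotation are merged back
#' into one segment.
#'
#' @param genome an [annotated_genome()].
#' @param tet the genome's [tetrad()] in deposited coordinates.
#' @return `list(genome =, tetrad =, offset =)`: the rotated genome (gene
#'   list included), the standardized tetrad, and the 0-based rotation
#'   applied.
#' @export
standardize_start <- function(genome, tet) {
  n <- genome$length
  offset <- tet$lsc$start - 1L
  new_seq <- rotate_sequence(genome$sequence, offset)
  remap <- function(p) pos_from_deposited(p, offset, n)

  genes <- lapply(genome$genes, function(g) {
    segs <- g$segments
    segs[] <- c(remap(segs[, 1L]), remap(segs[, 2L]))
    # merge segments that became contiguous (deposited-origin splits)
    if (nrow(segs) > 1L) {
      merged <- segs[1L, , drop = FALSE]
      for (i in 2L:nrow(segs)) {
        last <- nrow(merged)
        if (segs[i, 1L] == merged[last, 2L] + 1L) {
          merged[last, 2L] <- segs[i, 2L]
        } else {
          merged <- rbind(merged, segs[i, , drop = FALSE])
        }
      }
      segs <- merged
    }
    gene_feature(g$name, g$strand, segs, g$kind)
  })

  lens <- vapply(tetrad_regions(tet), `[[`, integer(1L), "length")
  bounds <- cumsum(lens)
  std_tet <- tetrad(
    lsc = c(1L, bounds[1L]),
    irb = c(bounds[1L] + 1L, bounds[2L]),
    ssc = c(bounds[2L] + 1L, bounds[3L]),
    ira = c(bounds[3L] + 1L, bounds[4L]),
    genome_length = n
  )
  std_genome <- annotated_genome(genome$accession, genome$organism, new_seq,
                                 genome$topology, genes)
  list(genome = std_genome, tetrad = std_tet, offset = offset)
}

# Number of genes whose first base falls inside the region.
genes_in_region <- function(genes, region) {
  sum(vapply(genes, function(g) {
    pos_in_ivl(gene_first_base(g), region$start, region$end)
  }, logical(1L)))
}

#' Classify the starting-point group of a deposited record
#'
#' Codes: `a`/`c`/`e`/`g` when deposited base 1 is the first base of
#' LSC/IRb/SSC/IRa respectively; `b`/`d`/`f`/`h` when base 1 falls strictly
#' inside that region. The auxiliary `i_flag` marks minimal-gene-content
#' genomes: IRa, IRb, or SSC holding at most one gene.
#'
#' @param genome an [annotated_genome()].
#' @param tet the genome's [tetrad()] in deposited coordinates.
#' @return `list(code = one of letters a-h, i_flag = logical)`.
#' @export
classify_start_group <- function(genome, tet) {
  codes <- list(lsc = c("a", "b"), irb = c("c", "d"),
                ssc = c("e", "f"), ira = c("g", "h"))
  code <- NA_character_
  for (nm in names(codes)) {
    r <- tet[[nm]]
    if (r$start == 1L) {
      code <- codes[[nm]][1L]
      break
    }
    if (pos_in_ivl(1L, r$start, r$end)) {
      code <- codes[[nm]][2L]
      break
    }
  }
  i_flag <- any(vapply(list(tet$ira, tet$irb, tet$ssc), function(r) {
    genes_in_region(genome$genes, r) <= 1L
  }, logical(1L)))
  list(code = code, i_flag = i_flag)
}
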