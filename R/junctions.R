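# The four junction sites of a standardized genome and the gene context
# (flanking genes, distances, strands, spanning genes) needed for drawing.
#
# Convention: a junction's position is the coordinate of the last base of
# its upstream region; the junction line sits between position and
# position + 1, so an abutting gene has distance 0.

#' Compute the four junction sites of a standardized tetrad
#'
#' @param tet a standardized [tetrad()] (LSC starting at base 1).
#' @return named list of four junctions `JLB`, `JSB`, `JSA`, `JLA`, each
#'   `list(name, left_region, right_region, position)`; `JLA`'s downstream
#'   side wraps to base 1.
#' @export
compute_junctions <- function(tet) {
  stopifnot(inherits(tet, "cpj_tetrad"), tet$lsc$start == 1L)
  mk <- function(name, left, right, pos) {
    structure(list(name = name, left_region = left, right_region = right,
                   position = pos), class = "cpj_junction")
  }
  list(
    JLB = mk("JLB", "LSC", "IRb", tet$lsc$end),
    JSB = mk("JSB", "IRb", "SSC", tet$irb$end),
    JSA = mk("JSA", "SSC", "IRa", tet$ssc$end),
    JLA = mk("JLA", "IRa", "LSC", tet$genome_length)
  )
}

# Does the gene cover position p (wrap-aware over split segments)?
gene_covers <- function(gene, p, n) {
  segs <- gene_segments_split(gene, n)
  any(p >= segs[, 1L] & p <= segs[, 2L])
}

#' Gene context of one junction
#'
#' The left flank is the gene whose junction-proximal boundary is nearest
#' upstream of the junction line, the right flank the gene nearest
#' downstream (distance 0 = abutting). A gene covering both sides of the
#' line populates `spanning` and serves as both flanks with distance 0.
#' All distances are measured circularly, so genes near base 1 are the
#' right-side flank of JLA.
#'
#' @param genes list of [gene_feature()]s in standardized coordinates.
#' @param junction one junction from [compute_junctions()].
#' @param genome_length total sequence length in bp.
#' @return `list(junction, left_gene, left_distance, right_gene,
#'   right_distance, spanning)`; flanks are `NULL` (distances `NA`) for an
#'   empty gene list, `spanning` is `NULL` or `list(gene, bases_on_left,
#'   bases_on_right)`.
#' @export
gene_context <- function(genes, junction, genome_length) {
  n <- genome_length
  P <- junction$position
  Pn <- (P %% n) + 1L
  ctx <- structure(
    list(junction = junction, left_gene = NULL, left_distance = NA_integer_,
         right_gene = NULL, right_distance = NA_integer_, spanning = NULL),
    class = "cpj_junction_context"
  )
  if (length(genes) == 0L) return(ctx)

  dist_left <- vapply(genes, function(g) {
    if (gene_covers(g, P, n)) return(0L)
    segs <- gene_segments_split(g, n)
    min(circ_dist_fwd(segs[, 2L], P, n))
  }, integer(1L))
  dist_right <- vapply(genes, function(g) {
    if (gene_covers(g, Pn, n)) return(0L)
    segs <- gene_segments_split(g, n)
    min(circ_dist_fwd(Pn, segs[, 1L], n))
  }, integer(1L))

  spans <- vapply(genes, function(g) {
    gene_covers(g, P, n) && gene_covers(g, Pn, n)
  }, logical(1L))

  if (any(spans)) {
    g <- genes[[which(spans)[1L]]]
    ctx$spanning <- list(
      gene = g,
      bases_on_left = spanning_side_bases(g, P, n, side = "left"),
      bases_on_right = spanning_side_bases(g, P, n, side = "right")
    )
    ctx$left_gene <- g
    ctx$right_gene <- g
    ctx$left_distance <- 0L
    ctx$right_distance <- 0L
  } else {
    li <- which.min(dist_left)
    ri <- which.min(dist_right)
    ctx$left_gene <- genes[[li]]
    ctx$left_distance <- dist_left[li]
    ctx$right_gene <- genes[[ri]]
    ctx$right_distance <- dist_right[ri]
  }
  ctx
}

# Bases of a junction-spanning gene on each side of the junction line. For
# a single-segment gene (possibly wrap-encoded) the two counts sum to the
# gene length. Multi-segment genes are counted base-by-base against the
# circle cut at the junction line.
spanning_side_bases <- function(gene, P, n, side = c("left", "right")) {
  side <- match.arg(side)
  if (nrow(gene$segments) == 1L) {
    s <- gene$segments[1L, 1L]; e <- gene$segments[1L, 2L]
    if (side == "left") circ_dist_fwd(s, P, n) + 1L
    else circ_dist_fwd((P %% n) + 1L, e, n) + 1L
  } else {
    segs <- gene_segments_split(gene, n)
    ranks <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      circ_dist_fwd((P %% n) + 1L, segs[i, 1L]:segs[i, 2L], n)
    }))
    if (side == "right") sum(ranks < n / 2) else sum(ranks >= n / 2)
  }
}

#' Plan which genes of a region are drawn
#'
#' Applies the 0/1/2+ rule: no genes, nothing is drawn; exactly one gene,
#' it is drawn in the middle of the region with the region's endpoints
#' indicated; two or more genes, the first and last gene (by ascending
#' start in region walking order) are drawn at their true locations.
#' A gene belongs to the region containing its first base.
#'
#' @param genes list of [gene_feature()]s in standardized coordinates.
#' @param region one region of a [tetrad()] (element `lsc`, `irb`, `ssc`
#'   or `ira`).
#' @param genome_length total sequence length in bp.
#' @return `list(region, plotted_genes, endpoints_shown)`;
#'   `plotted_genes` is a list of `list(gene, placement)` with placement
#'   `"mid-region"` or `"at-location"`.
#' @export
plan_region_genes <- function(genes, region, genome_length) {
  n <- genome_length
  members <- Filter(function(g) {
    pos_in_ivl(gene_first_base(g), region$start, region$end)
  }, genes)
  plan <- structure(
    list(region = region, plotted_genes = list(), endpoints_shown = FALSE),
    class = "cpj_region_plan"
  )
  if (length(members) == 0L) return(plan)
  ord <- order(vapply(members, function(g) {
    circ_dist_fwd(region$start, gene_first_base(g), n)
  }, integer(1L)))
  members <- members[ord]
  if (length(members) == 1L) {
    plan$plotted_genes <- list(list(gene = members[[1L]], placement = "mid-region"))
    plan$endpoints_shown <- TRUE
  } else {
    plan$plotted_genes <- list(
      list(gene = members[[1L]], placement = "at-location"),
      list(gene = members[[length(members)]], placement = "at-location")
    )
  }
  plan
}
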