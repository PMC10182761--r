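# Deterministic layout of the stacked junction diagram. All geometry is
# computed here; the SVG writer and the PDF/PNG device renderer only draw
# what the FigureSpec says.
#
# Row anatomy (dy from the row top):
#   14   organism/accession/length baseline
#   86,75,64,...  "above" label band lanes (gene + junction names), going up
#   92..116       region blocks
#   127,138,149   "below" label band lanes (distances, region sizes,
#                 endpoints), going down
# Label collisions are resolved by greedy lane assignment under fixed
# approximate font metrics (7 px/char, 12 px line height); a label that
# cannot be placed within the lane budget is dropped with a warning rather
# than drawn overlapping.

.LAYOUT <- list(
  canvas_width = 1200, row_height = 170, margin_top = 16, margin_bottom = 24,
  x0 = 40, min_block_w = 40,
  dy_organism = 14, dy_above0 = 86, lane_h = 13, max_above_lanes = 5,
  dy_block = 92, block_h = 24, dy_below0 = 127, max_below_lanes = 4,
  dy_jline0 = 80, dy_jline1 = 128, dy_glyph_plus = 99, dy_glyph_minus = 109,
  char_w = 7, text_h = 12
)

.REGION_FILL <- c(LSC = "#79b473", IRb = "#e5864e", SSC = "#6f8fc9",
                  IRa = "#e5864e")

# Estimated horizontal extent of a label under the layout font metrics.
label_extent <- function(text, x, anchor) {
  w <- nchar(text) * .LAYOUT$char_w
  switch(anchor,
         start = c(x, x + w),
         middle = c(x - w / 2, x + w / 2),
         end = c(x - w, x))
}

# Greedy lane assignment: items get the first lane whose last occupant ends
# before they start. Returns items with a `lane` field; items beyond
# `max_lanes` are dropped with a warning.
assign_lanes <- function(items, max_lanes) {
  if (length(items) == 0L) return(items)
  ext <- t(vapply(items, function(it) label_extent(it$text, it$x, it$anchor),
                  numeric(2L)))
  ord <- order(ext[, 1L], ext[, 2L])
  lane_end <- rep(-Inf, max_lanes)
  out <- list()
  for (i in ord) {
    lane <- which(ext[i, 1L] >= lane_end + 3)[1L]
    if (is.na(lane)) {
      cpj_log("info", paste0("label '", items[[i]]$text,
                             "' dropped: no free label lane"), stage = "layout")
      next
    }
    lane_end[lane] <- ext[i, 2L]
    it <- items[[i]]
    it$lane <- lane - 1L
    out[[length(out) + 1L]] <- it
  }
  out
}

# Assemble junctions, contexts, and region plans for one standardized
# genome: the drawable view of a record.
#' Build the drawable view of a standardized genome
#'
#' Computes the four junctions, their gene contexts, and the per-region
#' gene plans for a genome already standardized to LSC-first orientation.
#'
#' @param genome standardized [annotated_genome()].
#' @param tet standardized [tetrad()].
#' @return list with elements `genome`, `tetrad`, `junctions`, `contexts`,
#'   `plans`.
#' @export
genome_view <- function(genome, tet) {
  juncs <- compute_junctions(tet)
  contexts <- lapply(juncs, function(j) gene_context(genome$genes, j, genome$length))
  plans <- lapply(tetrad_regions(tet), function(r) {
    plan_region_genes(genome$genes, r, genome$length)
  })
  names(plans) <- REGION_ORDER
  list(genome = genome, tetrad = tet, junctions = juncs,
       contexts = contexts, plans = plans)
}

# Proportional block widths with a minimum visible width for tiny regions.
block_widths <- function(bp, total_w, min_w) {
  w <- bp / sum(bp) * total_w
  repeat {
    fixed <- w <= min_w
    if (!any(fixed) || all(fixed)) break
    w2 <- w
    w2[fixed] <- min_w
    w2[!fixed] <- bp[!fixed] / sum(bp[!fixed]) * (total_w - min_w * sum(fixed))
    if (all(w2[!fixed] > min_w)) {
      w <- w2
      break
    }
    w <- w2
  }
  pmax(w, min_w)
}

# Circular midpoint of a gene's first segment.
gene_mid <- function(gene, n) {
  s <- gene$segments[1L, 1L]
  len <- ivl_length(gene$segments[1L, 1L], gene$segments[1L, 2L], n)
  ((s - 1L + (len - 1L) %/% 2L) %% n) + 1L
}

#' Lay out the stacked junction figure
#'
#' Produces a deterministic, layout-ready description of the figure: fixed
#' row height, rows in input order, per-row bp-to-pixel scaling so genomes
#' of different lengths span the same canvas width, region blocks with a
#' minimum visible width, junction lines, strand-arrow gene glyphs, and
#' collision-free text labels.
#'
#' @param views list of [genome_view()] results (length >= 1).
#' @return object of class `cpj_figure` with `canvas` and `rows`.
#' @export
layout_figure <- function(views) {
  stopifnot(length(views) >= 1L)
  L <- .LAYOUT
  W <- L$canvas_width - 2 * L$x0
  rows <- vector("list", length(views))

  for (vi in seq_along(views)) {
    v <- views[[vi]]
    tet <- v$tetrad
    n <- tet$genome_length
    row_y <- L$margin_top + (vi - 1L) * L$row_height
    regions <- tetrad_regions(tet)
    bp <- vapply(regions, `[[`, integer(1L), "length")
    w <- block_widths(bp, W, L$min_block_w)
    x <- L$x0 + cumsum(c(0, w[-4L]))
    blocks <- Map(function(r, xx, ww) {
      list(label = r$label, x = xx, w = ww, start = r$start, end = r$end,
           bp = r$length)
    }, regions, x, w)
    names(blocks) <- REGION_ORDER

    # bp -> x within the row (standardized coordinates)
    pos_x <- function(p) {
      for (b in blocks) {
        if (p >= b$start && p <= b$end) {
          return(b$x + (p - b$start + 0.5) / b$bp * b$w)
        }
      }
      NA_real_
    }

    jx <- c(JLB = blocks$LSC$x + blocks$LSC$w,
            JSB = blocks$IRb$x + blocks$IRb$w,
            JSA = blocks$SSC$x + blocks$SSC$w,
            JLA = blocks$IRa$x + blocks$IRa$w)
    junction_lines <- lapply(names(jx), function(nm) {
      list(name = nm, x = unname(jx[[nm]]),
           y0 = row_y + L$dy_jline0, y1 = row_y + L$dy_jline1)
    })

    # ---- glyphs: junction-context genes at true location, region-plan
    # genes at true location or mid-region; drawn once per gene ----------
    glyphs <- list()
    above <- list()
    below <- list()
    seen <- character(0L)
    add_glyph <- function(gene, gx) {
      key <- paste(gene$name, gene_first_base(gene))
      if (key %in% seen || is.na(gx)) return(invisible(NULL))
      seen <<- c(seen, key)
      gy <- row_y + if (gene$strand == "+") L$dy_glyph_plus else L$dy_glyph_minus
      glyphs[[length(glyphs) + 1L]] <<-
        list(name = gene$name, strand = gene$strand, x = gx, y = gy)
      above[[length(above) + 1L]] <<-
        list(text = gene$name, x = gx, anchor = "middle", class = "gene-label")
      invisible(NULL)
    }

    for (jn in names(v$junctions)) {
      cx <- v$contexts[[jn]]
      jxx <- unname(jx[[jn]])
      if (!is.null(cx$spanning)) {
        add_glyph(cx$spanning$gene, jxx)
        below[[length(below) + 1L]] <- list(
          text = sprintf("%s %s|%s bp", cx$spanning$gene$name,
                         format_bp(cx$spanning$bases_on_left),
                         format_bp(cx$spanning$bases_on_right)),
          x = jxx, anchor = "middle", class = "distance-label")
      } else {
        if (!is.null(cx$left_gene)) {
          add_glyph(cx$left_gene, pos_x(gene_mid(cx$left_gene, n)))
          below[[length(below) + 1L]] <- list(
            text = sprintf("%s %s bp", cx$left_gene$name,
                           format_bp(cx$left_distance)),
            x = jxx - 4, anchor = "end", class = "distance-label")
        }
        if (!is.null(cx$right_gene)) {
          add_glyph(cx$right_gene, pos_x(gene_mid(cx$right_gene, n)))
          below[[length(below) + 1L]] <- list(
            text = sprintf("%s %s bp", cx$right_gene$name,
                           format_bp(cx$right_distance)),
            x = jxx + 4, anchor = "start", class = "distance-label")
        }
      }
    }
    for (rn in names(v$plans)) {
      plan <- v$plans[[rn]]
      b <- blocks[[rn]]
      for (pg in plan$plotted_genes) {
        gx <- if (pg$placement == "mid-region") {
          b$x + b$w / 2
        } else {
          pos_x(gene_mid(pg$gene, n))
        }
        add_glyph(pg$gene, gx)
      }
      if (plan$endpoints_shown) {
        below[[length(below) + 1L]] <- list(text = format_bp(b$start), x = b$x,
                                            anchor = "start",
                                            class = "region-endpoint-label")
        below[[length(below) + 1L]] <- list(text = format_bp(b$end),
                                            x = b$x + b$w, anchor = "end",
                                            class = "region-endpoint-label")
      }
    }

    # junction names into the above band, region sizes into the below band
    for (nm in names(jx)) {
      above[[length(above) + 1L]] <- list(text = nm, x = unname(jx[[nm]]),
                                          anchor = "middle",
                                          class = "junction-name-label")
    }
    for (b in blocks) {
      below[[length(below) + 1L]] <- list(
        text = sprintf("%s %s bp", b$label, format_bp(b$bp)),
        x = b$x + b$w / 2, anchor = "middle", class = "region-size-label")
    }

    above <- assign_lanes(above, .LAYOUT$max_above_lanes)
    below <- assign_lanes(below, .LAYOUT$max_below_lanes)
    labels <- c(
      list(list(text = sprintf("%s  (%s)  %s bp", v$genome$organism,
                               v$genome$accession, format_bp(n)),
                x = L$x0, y = row_y + L$dy_organism, anchor = "start",
                class = "organism-label", italic = TRUE)),
      lapply(above, function(it) {
        it$y <- row_y + L$dy_above0 - it$lane * L$lane_h
        it$italic <- FALSE
        it[c("text", "x", "y", "anchor", "class", "italic")]
      }),
      lapply(below, function(it) {
        it$y <- row_y + L$dy_below0 + it$lane * L$lane_h
        it$italic <- FALSE
        it[c("text", "x", "y", "anchor", "class", "italic")]
      })
    )

    rows[[vi]] <- list(
      accession = v$genome$accession, organism = v$genome$organism,
      total_length_bp = n, y = row_y, blocks = blocks,
      junction_lines = junction_lines, glyphs = glyphs, labels = labels,
      bp_per_px = n / W
    )
  }

  structure(
    list(
      canvas = c(width = L$canvas_width,
                 height = L$margin_top + length(views) * L$row_height +
                   L$margin_bottom),
      rows = rows
    ),
    class = "cpj_figure"
  )
}
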