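# SVG emission and native PDF/PNG rendering of a FigureSpec. The SVG is
# plain deterministic text (no timestamps, fixed number formatting) so
# identical input yields byte-identical output.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num <- function(x) sprintf("%.2f", x)

#' Serialize a figure as an SVG document
#'
#' Emits one group per genome row with region-block rectangles, junction
#' lines, gene glyphs whose arrow markers encode the strand (right arrow =
#' plus strand, left arrow = minus strand), and all text labels. Output is
#' byte-identical across runs for identical input.
#'
#' @param figure a `cpj_figure` from [layout_figure()].
#' @return single string: the SVG document.
#' @export
figure_to_svg <- function(figure) {
  stopifnot(inherits(figure, "cpj_figure"), length(figure$rows) >= 1L)
  w <- figure$canvas[["width"]]
  h <- figure$canvas[["height"]]
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s" font-family="Helvetica, Arial, sans-serif" font-size="11">',
            num(w), num(h), num(w), num(h)),
    "<defs>",
    '<marker id="arrow-plus" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="0" markerUnits="userSpaceOnUse"><path d="M0,0 L7,3 L0,6 Z" fill="#222222"/></marker>',
    '<marker id="arrow-minus" markerWidth="8" markerHeight="8" refX="0" refY="3" orient="0" markerUnits="userSpaceOnUse"><path d="M7,0 L0,3 L7,6 Z" fill="#222222"/></marker>',
    "</defs>",
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#ffffff"/>', num(w), num(h))
  )
  bh <- .LAYOUT$block_h
  dy_block <- .LAYOUT$dy_block
  for (row in figure$rows) {
    out <- c(out, sprintf('<g class="genome-row" data-accession="%s">',
                          xml_escape(row$accession)))
    for (b in row$blocks) {
      out <- c(out, sprintf(
        '<rect class="region-block" data-region="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#333333" stroke-width="0.8"/>',
        b$label, num(b$x), num(row$y + dy_block), num(b$w), num(bh),
        .REGION_FILL[[b$label]]))
    }
    for (j in row$junction_lines) {
      out <- c(out, sprintf(
        '<line class="junction-line" data-junction="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#111111" stroke-width="1" stroke-dasharray="3,2"/>',
        j$name, num(j$x), num(j$y0), num(j$x), num(j$y1)))
    }
    for (g in row$glyphs) {
      if (g$strand == "+") {
        x1 <- g$x - 7; x2 <- g$x + 7; marker <- "arrow-plus"
      } else {
        x1 <- g$x + 7; x2 <- g$x - 7; marker <- "arrow-minus"
      }
      out <- c(out, sprintf(
        '<line class="gene-glyph" data-gene="%s" data-strand="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#222222" stroke-width="2" marker-end="url(#%s)"/>',
        xml_escape(g$name), g$strand, num(x1), num(g$y), num(x2), num(g$y),
        marker))
    }
    out <- c(out, vapply(row$labels, function(lab) {
      sprintf('<text class="%s" x="%s" y="%s" text-anchor="%s"%s>%s</text>',
              lab$class, num(lab$x), num(lab$y), lab$anchor,
              if (isTRUE(lab$italic)) ' font-style="italic"' else "",
              xml_escape(lab$text))
    }, character(1L)))
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Render a figure to PDF or PNG
#'
#' Draws the same FigureSpec geometry through R's grid graphics onto a
#' `pdf()` or `png()` device. Rendering is best-effort: if the device is
#' unavailable a warning is issued and nothing is written (the SVG remains
#' the authoritative output).
#'
#' @param figure a `cpj_figure` from [layout_figure()].
#' @param format `"pdf"` or `"png"`.
#' @param path output file path.
#' @return `path` invisibly, or `NULL` if the device failed.
#' @export
convert_figure <- function(figure, format = c("pdf", "png"), path) {
  format <- match.arg(format)
  w <- figure$canvas[["width"]]
  h <- figure$canvas[["height"]]
  opened <- tryCatch({
    if (format == "pdf") {
      grDevices::pdf(path, width = w / 96, height = h / 96, useDingbats = FALSE)
    } else {
      grDevices::png(path, width = w, height = h, res = 96, type = "cairo")
    }
    TRUE
  }, error = function(e) {
    warning("could not open ", format, " device (", conditionMessage(e),
            "); only the SVG output is available")
    FALSE
  })
  if (!opened) return(invisible(NULL))
  on.exit(grDevices::dev.off(), add = TRUE)
  draw_figure_grid(figure)
  invisible(path)
}

# Shared grid rendering of a FigureSpec (y axis flipped to match SVG).
draw_figure_grid <- function(figure) {
  w <- figure$canvas[["width"]]
  h <- figure$canvas[["height"]]
  grid::grid.newpage()
  vp <- grid::viewport(xscale = c(0, w), yscale = c(h, 0))
  grid::pushViewport(vp)
  on.exit(grid::popViewport(), add = TRUE)
  nat <- function(v) grid::unit(v, "native")
  bh <- .LAYOUT$block_h
  dy_block <- .LAYOUT$dy_block
  for (row in figure$rows) {
    for (b in row$blocks) {
      grid::grid.rect(x = nat(b$x), y = nat(row$y + dy_block),
                      width = nat(b$w), height = nat(bh),
                      just = c("left", "top"),
                      gp = grid::gpar(fill = .REGION_FILL[[b$label]],
                                      col = "#333333", lwd = 0.8))
    }
    for (j in row$junction_lines) {
      grid::grid.lines(x = nat(c(j$x, j$x)), y = nat(c(j$y0, j$y1)),
                       gp = grid::gpar(col = "#111111", lty = "22"))
    }
    for (g in row$glyphs) {
      xs <- if (g$strand == "+") c(g$x - 7, g$x + 7) else c(g$x + 7, g$x - 7)
      grid::grid.lines(
        x = nat(xs), y = nat(c(g$y, g$y)),
        arrow = grid::arrow(length = grid::unit(5, "points"), type = "closed"),
        gp = grid::gpar(col = "#222222", fill = "#222222", lwd = 2))
    }
    for (lab in row$labels) {
      just <- switch(lab$anchor, start = "left", middle = "centre", end = "right")
      grid::grid.text(
        lab$text, x = nat(lab$x), y = nat(lab$y), just = c(just, "bottom"),
        gp = grid::gpar(fontsize = 9,
                        fontface = if (isTRUE(lab$italic)) "italic" else "plain"))
    }
  }
}

#' Write a figure in the requested formats
#'
#' Writes `<prefix>.junctions.svg` (always, when `"svg"` is requested) and
#' best-effort `<prefix>.junctions.pdf` / `.png` renditions.
#'
#' @param figure a `cpj_figure`.
#' @param outdir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param formats subset of `c("svg", "pdf", "png")`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_figure <- function(figure, outdir, prefix = "cpjunctions",
                         formats = c("svg", "pdf", "png")) {
  stopifnot(length(formats) >= 1L, all(formats %in% c("svg", "pdf", "png")))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0L)
  if ("svg" %in% formats) {
    p <- file.path(outdir, paste0(prefix, ".junctions.svg"))
    writeLines(figure_to_svg(figure), p)
    paths["svg"] <- p
  }
  for (fmt in intersect(formats, c("pdf", "png"))) {
    p <- file.path(outdir, paste0(prefix, ".junctions.", fmt))
    if (!is.null(convert_figure(figure, fmt, p))) paths[fmt] <- p
  }
  invisible(paths)
}
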