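# Structural assertions on the figure layout and emitted SVG. Tests check
# element counts, text content and marker direction, never pixels.

suite_figure <- function(seed = 2) {
  suite <- generate_group_suite(fixture_spec(seed = seed))
  views <- lapply(suite, function(fx) process_genome(fx$genome)$view)
  layout_figure(unname(views))
}

svg_doc <- function(fig) xml2::read_xml(figure_to_svg(fig))

ns_free <- function(doc) {
  xml2::xml_ns_strip(doc)
  doc
}

test_that("one genome yields one row with four blocks and four junction lines", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  fig <- layout_figure(list(process_genome(fx$genome)$view))
  expect_s3_class(fig, "cpj_figure")
  expect_length(fig$rows, 1L)
  expect_length(fig$rows[[1L]]$blocks, 4L)
  expect_length(fig$rows[[1L]]$junction_lines, 4L)
  doc <- ns_free(svg_doc(fig))
  expect_length(xml2::xml_find_all(doc, "//g[@class='genome-row']"), 1L)
  expect_length(xml2::xml_find_all(doc, "//rect[@class='region-block']"), 4L)
  expect_length(xml2::xml_find_all(doc, "//line[@class='junction-line']"), 4L)
})

test_that("rows of different genome lengths share the canvas width", {
  f1 <- generate_fixture(fixture_spec(seed = 4))
  f2 <- generate_fixture(fixture_spec(lsc_len = 2000, ir_len = 500,
                                      ssc_len = 400, seed = 4))
  fig <- layout_figure(list(process_genome(f1$genome)$view,
                            process_genome(f2$genome)$view))
  spans <- vapply(fig$rows, function(r) {
    b <- r$blocks
    (b$IRa$x + b$IRa$w) - b$LSC$x
  }, numeric(1L))
  expect_equal(spans[1L], spans[2L])
  expect_false(fig$rows[[1L]]$bp_per_px == fig$rows[[2L]]$bp_per_px)
})

test_that("a tiny SSC still gets a visible block with its true size printed", {
  suite <- generate_group_suite(fixture_spec(lsc_len = 5000, ir_len = 1000,
                                             ssc_len = 600, seed = 5))
  view <- process_genome(suite$i$genome)$view
  fig <- layout_figure(list(view))
  ssc <- fig$rows[[1L]]$blocks$SSC
  expect_gte(ssc$w, 40)
  # true bp size appears among the labels
  labels <- vapply(fig$rows[[1L]]$labels, `[[`, "", "text")
  expect_true(any(grepl(paste0("SSC ", format(ssc$bp, big.mark = ","), " bp"),
                        labels, fixed = TRUE)))
})

test_that("organism names and strand-correct arrow markers appear in the SVG", {
  fig <- suite_figure(seed = 6)
  doc <- ns_free(svg_doc(fig))
  rows <- xml2::xml_find_all(doc, "//g[@class='genome-row']")
  expect_length(rows, 9L)
  org <- xml2::xml_text(xml2::xml_find_all(doc, "//text[@class='organism-label']"))
  expect_length(org, 9L)
  expect_true(all(grepl("Plastoma synthetica", org)))
  glyphs <- xml2::xml_find_all(doc, "//line[@class='gene-glyph']")
  expect_gt(length(glyphs), 0L)
  strands <- xml2::xml_attr(glyphs, "data-strand")
  markers <- xml2::xml_attr(glyphs, "marker-end")
  expect_true(all(markers[strands == "+"] == "url(#arrow-plus)"))
  expect_true(all(markers[strands == "-"] == "url(#arrow-minus)"))
  expect_true(any(strands == "-"))
  # both marker definitions exist; the minus marker points left
  expect_length(xml2::xml_find_all(doc, "//marker[@id='arrow-minus']"), 1L)
})

test_that("a junction-spanning gene is drawn once, across the junction line", {
  fx <- generate_fixture(fixture_spec(seed = 7))
  res <- process_genome(fx$genome)
  fig <- layout_figure(list(res$view))
  row <- fig$rows[[1L]]
  jlb_x <- Filter(function(j) j$name == "JLB", row$junction_lines)[[1L]]$x
  rps <- Filter(function(g) g$name == "rps19", row$glyphs)
  expect_length(rps, 1L)
  expect_equal(rps[[1L]]$x, jlb_x)
  # its two side lengths are annotated at the junction
  labels <- vapply(row$labels, `[[`, "", "text")
  expect_true(any(grepl("^rps19 60\\|60 bp$", labels)))
})

test_that("SVG output is byte-identical across repeated runs", {
  s1 <- figure_to_svg(suite_figure(seed = 8))
  s2 <- figure_to_svg(suite_figure(seed = 8))
  expect_identical(s1, s2)
})

test_that("no two text labels overlap under the layout font metrics", {
  fig <- suite_figure(seed = 9)
  doc <- ns_free(svg_doc(fig))
  texts <- xml2::xml_find_all(doc, "//text")
  x <- as.numeric(xml2::xml_attr(texts, "x"))
  y <- as.numeric(xml2::xml_attr(texts, "y"))
  anchor <- xml2::xml_attr(texts, "text-anchor")
  anchor[is.na(anchor)] <- "start"
  txt <- xml2::xml_text(texts)
  w <- nchar(txt) * 7
  x0 <- ifelse(anchor == "start", x, ifelse(anchor == "middle", x - w / 2, x - w))
  x1 <- x0 + w
  y0 <- y - 10
  y1 <- y + 2
  nlab <- length(txt)
  for (i in seq_len(nlab - 1L)) {
    js <- (i + 1L):nlab
    clash <- x0[js] < x1[i] & x1[js] > x0[i] & y0[js] < y1[i] & y1[js] > y0[i]
    expect_false(any(clash),
                 info = paste("overlap:", txt[i], "vs",
                              paste(txt[js][clash], collapse = ", ")))
  }
})

test_that("figures render to PDF and PNG files (best-effort)", {
  fx <- generate_fixture(fixture_spec(seed = 10))
  fig <- layout_figure(list(process_genome(fx$genome)$view))
  pdf_path <- withr::local_tempfile(fileext = ".pdf")
  res <- convert_figure(fig, "pdf", pdf_path)
  if (!is.null(res)) {
    expect_true(file.exists(pdf_path))
    expect_gt(file.size(pdf_path), 0)
  }
  png_path <- withr::local_tempfile(fileext = ".png")
  res2 <- tryCatch(convert_figure(fig, "png", png_path), warning = function(w) NULL)
  if (!is.null(res2)) {
    expect_true(file.exists(png_path))
    expect_gt(file.size(png_path), 0)
  }
})

test_that("an empty figure is rejected before serialization", {
  expect_error(layout_figure(list()))
})
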