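# GenBank flat-file and configuration-file reading/writing.

test_that("a minimal circular record transcribes directly into the model", {
  set.seed(11)
  seq <- rand_dna(200)
  gb <- minimal_gb_text(seq, topology = "circular", feature_lines = c(
    "     gene            10..99",
    '                     /gene="psbA"'
  ))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- parse_genbank(path)
  expect_equal(g$length, 200L)
  expect_equal(g$topology, "circular")
  expect_equal(g$sequence, seq)
  expect_equal(g$accession, "TEST0001.1")
  expect_equal(g$organism, "Testia minima")
  expect_length(g$genes, 1L)
  expect_equal(g$genes[[1L]]$name, "psbA")
  expect_equal(g$genes[[1L]]$strand, "+")
  expect_equal(g$genes[[1L]]$segments, matrix(c(10L, 99L), ncol = 2L))
})

test_that("complement(join()) locations keep split segments and minus strand", {
  set.seed(12)
  gb <- minimal_gb_text(rand_dna(200), feature_lines = c(
    "     gene            complement(join(150..200,1..30))",
    '                     /gene="trnH"'
  ))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- parse_genbank(path)
  expect_length(g$genes, 1L)
  expect_equal(g$genes[[1L]]$strand, "-")
  expect_equal(g$genes[[1L]]$segments,
               matrix(c(150L, 200L, 1L, 30L), ncol = 2L, byrow = TRUE))
})

test_that("organism comes from the /organism qualifier", {
  set.seed(13)
  gb <- minimal_gb_text(rand_dna(120), accession = "NC_036102.1",
                        organism = "Sophora alopecuroides",
                        feature_lines = c(
                          "     gene            5..40",
                          '                     /gene="matK"'
                        ))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- parse_genbank(path)
  expect_equal(g$organism, "Sophora alopecuroides")
  expect_equal(g$accession, "NC_036102.1")
})

test_that("features without /gene are skipped and gene+CDS pairs dedupe", {
  set.seed(14)
  gb <- minimal_gb_text(rand_dna(150), feature_lines = c(
    "     gene            10..80",
    '                     /gene="rbcL"',
    "     CDS             10..80",
    '                     /gene="rbcL"',
    "     misc_feature    90..100",
    '                     /note="no gene tag"'
  ))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- parse_genbank(path)
  expect_length(g$genes, 1L)
  expect_equal(g$genes[[1L]]$name, "rbcL")
})

test_that("missing ORIGIN block is fatal; unannotated records parse with a warning", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA circular", "FEATURES", "//"), path)
  expect_error(parse_genbank(path), "ORIGIN")

  set.seed(15)
  gb <- minimal_gb_text(rand_dna(100))
  path2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path2)
  g <- withr::with_options(list(cpjunctions.log_level = "quiet"),
                           parse_genbank(path2))
  expect_length(g$genes, 0L)
})

test_that("fixture GenBank text round-trips through the parser", {
  for (grp in c("a", "e", "h")) {
    fx <- generate_fixture(fixture_spec(start_group = grp, seed = 3))
    path <- write_fixture_gb(fx, withr::local_tempdir())
    g <- parse_genbank(path)
    expect_equal(g$accession, fx$genome$accession)
    expect_equal(g$length, fx$genome$length)
    expect_equal(g$topology, "circular")
    expect_equal(g$organism, fx$genome$organism)
    expect_equal(g$sequence, fx$genome$sequence)
    expect_length(g$genes, length(fx$genes))
    for (i in seq_along(g$genes)) {
      expect_equal(g$genes[[i]]$name, fx$genes[[i]]$name)
      expect_equal(g$genes[[i]]$strand, fx$genes[[i]]$strand)
      expect_equal(g$genes[[i]]$segments, fx$genes[[i]]$segments)
    }
  }
})

test_that("tetrad strings parse, tolerate dash/separator variants, and round-trip", {
  t1 <- parse_tetrad_string("LSC:2-85726;IRb:85727-109824;SSC:109825-130908;IRa:130909-1")
  expect_equal(t1$ira$start, 130909L)
  expect_equal(t1$ira$end, 1L)       # wraps the origin
  expect_equal(t1$lsc$start, 2L)

  # published-table style: commas and en-dashes
  t2 <- parse_tetrad_string("LSC:1–84221, IRb:84222–110095, SSC:110096–128234, IRa:128235–154108",
                            genome_length = 154108)
  expect_equal(t2$lsc$end, 84221L)
  expect_equal(t2$irb$length, 25874L)

  # round trip, including the wrapping case
  expect_equal(format_tetrad(parse_tetrad_string(format_tetrad(t1))),
               format_tetrad(t1))

  expect_error(parse_tetrad_string("LSC:1-4;IRb:5-6"), "missing")
  expect_error(parse_tetrad_string("LSC:1-4;IRb:5-6;SSC:x-8;IRa:9-10"),
               "malformed")
})

test_that("configuration files parse entries, optional overrides, and comments", {
  cfg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment line",
    "",
    "a.gb\tLSC:1-84221;IRb:84222-110095;SSC:110096-128234;IRa:128235-154108",
    "b.gb"
  ), cfg)
  entries <- parse_config(cfg)
  expect_length(entries, 2L)
  expect_equal(entries[[1L]]$gb_path, "a.gb")
  expect_equal(entries[[1L]]$custom_tetrad$lsc$end, 84221L)
  expect_null(entries[[2L]]$custom_tetrad)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0L), empty)
  expect_length(parse_config(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a.gb", "b.gb\tLSC:1-4;IRb:5-6"), bad)
  expect_error(parse_config(bad), "line 2")
})

test_that("non-IUPAC sequence letters are fatal on read", {
  gb <- minimal_gb_text("ACGTACGTZZ")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_error(parse_genbank(path), "non-IUPAC")
})

test_that("region table mirrors the deposited tetrad, wrap notation included", {
  fx <- generate_fixture(fixture_spec(start_group = "h", seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_region_table(list(list(genome = fx$genome, tetrad = fx$truth)),
                            path)
  back <- read.delim(path)
  expect_equal(nrow(back), 4L)
  expect_equal(back$region, c("LSC", "IRb", "SSC", "IRa"))
  ira <- back[back$region == "IRa", ]
  expect_true(ira$start > ira$end)   # group h: IRa spans the origin
  expect_equal(sum(back$length), fx$genome$length)
})
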