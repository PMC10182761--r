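# Tetrad classification, the record filter, LSC-first standardization, and
# starting-point groups.

test_that("arm pair with an origin-wrapping arm classifies to the published shape", {
  # IRb 85727..109824 (24,098 bp) and IRa 130909..1 wrapping the origin of
  # a 155,005 bp genome: LSC must be 2..85726 and SSC 109825..130908
  ir <- cpjunctions:::ir_pair(c(85727L, 109824L), c(130909L, 1L), 24098L)
  tet <- classify_tetrad(ir, 155005L)
  expect_equal(c(tet$lsc$start, tet$lsc$end), c(2L, 85726L))
  expect_equal(c(tet$irb$start, tet$irb$end), c(85727L, 109824L))
  expect_equal(c(tet$ssc$start, tet$ssc$end), c(109825L, 130908L))
  expect_equal(c(tet$ira$start, tet$ira$end), c(130909L, 1L))
  expect_equal(tet$irb$length, tet$ira$length)
})

test_that("equal single-copy gaps break the tie toward deposited base 1", {
  ir <- cpjunctions:::ir_pair(c(101L, 150L), c(251L, 300L), 50L)
  tet <- classify_tetrad(ir, 300L)
  expect_equal(tet$lsc$length, tet$ssc$length)
  expect_true(tet$lsc$start <= 1L || tet$lsc$start > tet$lsc$end ||
                (1L >= tet$lsc$start && 1L <= tet$lsc$end))
  expect_equal(c(tet$lsc$start, tet$lsc$end), c(1L, 100L))
  expect_equal(c(tet$irb$start, tet$irb$end), c(101L, 150L))
})

test_that("abutting arms (single-copy region of length 0) are rejected", {
  ir <- cpjunctions:::ir_pair(c(101L, 150L), c(151L, 200L), 50L)
  expect_error(classify_tetrad(ir, 400L), "degenerate")
})

test_that("the filter is a strict step at the minimum IR length", {
  g_ann <- annotated_genome("FIL0001.1", "Filtra exempla", "ACGTACGTAC",
                            "circular",
                            list(gene_feature("aaa", "+", c(1L, 4L))))
  params <- detection_params()
  for (case in list(list(len = 50L, pass = FALSE), list(len = 99L, pass = FALSE),
                    list(len = 100L, pass = TRUE), list(len = 150L, pass = TRUE))) {
    ir <- cpjunctions:::ir_pair(c(1L, case$len), c(1000L, 1000L + case$len - 1L),
                                case$len)
    v <- passes_filter(g_ann, ir, params)
    expect_equal(v$pass, case$pass)
    if (!case$pass) expect_equal(v$reason, "IR < 100 bp")
  }
  # no IR found at all
  v <- passes_filter(g_ann, NULL, params)
  expect_false(v$pass)
  expect_equal(v$reason, "IR < 100 bp")
  # structurally fine but unannotated
  g_un <- annotated_genome("FIL0002.1", "Filtra nuda", "ACGTACGTAC", "circular")
  ir_ok <- cpjunctions:::ir_pair(c(1L, 120L), c(1000L, 1119L), 120L)
  v2 <- passes_filter(g_un, ir_ok, params)
  expect_false(v2$pass)
  expect_equal(v2$reason, "unannotated")
})

test_that("standardization puts LSC first and unwraps origin-split genes", {
  for (grp in c("a", "e", "h")) {
    fx <- generate_fixture(fixture_spec(start_group = grp, seed = 4))
    res <- process_genome(fx$genome)
    std <- res$standardized
    expect_equal(std$tetrad$lsc$start, 1L)
    expect_equal(std$tetrad$ira$end, std$tetrad$genome_length)
    # group a is already standardized: identity transform
    if (grp == "a") expect_equal(std$offset, 0L)
    # all genes contiguous again after standardization
    for (g in std$genome$genes) {
      expect_equal(nrow(g$segments), 1L)
      expect_lte(g$segments[1L, 1L], g$segments[1L, 2L])
    }
  }
  # the standardized gene maps agree between rotations of one molecule
  fa <- process_genome(generate_fixture(fixture_spec(start_group = "a", seed = 4))$genome)
  fh <- process_genome(generate_fixture(fixture_spec(start_group = "h", seed = 4))$genome)
  sig <- function(r) {
    vapply(r$standardized$genome$genes, function(g) {
      paste(g$name, g$strand, g$segments[1L, 1L], g$segments[1L, 2L])
    }, character(1L))
  }
  expect_setequal(sig(fa), sig(fh))
})

test_that("start groups follow where deposited base 1 falls", {
  g <- annotated_genome("GRP0001.1", "Groupa exempla",
                        strrep("ACGT", 25L), "circular",
                        list(gene_feature("aaa", "+", c(1L, 4L))))
  # published row shapes (coordinates as printed, lengths consistent)
  t_a <- tetrad(c(1, 84221), c(84222, 110095), c(110096, 128234),
                c(128235, 154108), 154108)
  expect_equal(classify_start_group(g, t_a)$code, "a")

  t_b <- tetrad(c(163399, 88112), c(88113, 117864), c(117865, 133646),
                c(133647, 163398), 163399)
  expect_equal(classify_start_group(g, t_b)$code, "b")

  t_e <- tetrad(c(44327, 130575), c(130576, 156658), c(1, 18243),
                c(18244, 44326), 156658)
  expect_equal(classify_start_group(g, t_e)$code, "e")

  # all eight positional codes over the synthetic suite
  suite <- generate_group_suite(fixture_spec(seed = 6))
  for (grp in letters[1:8]) {
    res <- process_genome(suite[[grp]]$genome)
    expect_equal(res$group$code, grp)
    expect_false(res$group$i_flag)
  }
  res_i <- process_genome(suite$i$genome)
  expect_true(res_i$group$i_flag)
})

test_that("tetrad invariants reject inconsistent region sets", {
  expect_error(tetrad(c(1, 100), c(101, 150), c(151, 200), c(201, 240), 260),
               "partition")
  expect_warning(tetrad(c(1, 100), c(101, 150), c(151, 200), c(201, 260), 260),
                 "IRb length")
  expect_error(tetrad(c(1, 50), c(51, 100), c(101, 200), c(201, 250), 250),
               "shorter than SSC")
})
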