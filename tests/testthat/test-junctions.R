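# Junction sites and their gene contexts.

published_tetrad <- function() {
  tetrad(c(1, 84221), c(84222, 110095), c(110096, 128234), c(128235, 154108),
         154108)
}

test_that("junction positions read off the standardized region ends", {
  j <- compute_junctions(published_tetrad())
  expect_equal(j$JLB$position, 84221L)
  expect_equal(j$JSB$position, 110095L)
  expect_equal(j$JSA$position, 128234L)
  expect_equal(j$JLA$position, 154108L)
  expect_equal(j$JLB$left_region, "LSC")
  expect_equal(j$JLA$right_region, "LSC")

  toy <- tetrad(c(1, 4), c(5, 6), c(7, 8), c(9, 10), 10)
  jt <- compute_junctions(toy)
  expect_equal(vapply(jt, `[[`, integer(1L), "position"),
               c(JLB = 4L, JSB = 6L, JSA = 8L, JLA = 10L))
  expect_true(all(diff(vapply(jt, `[[`, integer(1L), "position")) > 0))
})

test_that("a gene crossing JLB splits into the printed side lengths", {
  tet <- published_tetrad()
  j <- compute_junctions(tet)
  genes <- list(gene_feature("rps19", "+", c(84100L, 84300L)))
  cx <- gene_context(genes, j$JLB, tet$genome_length)
  expect_false(is.null(cx$spanning))
  expect_equal(cx$spanning$bases_on_left, 122L)   # 84221 - 84100 + 1
  expect_equal(cx$spanning$bases_on_right, 79L)   # 84300 - 84222 + 1
  expect_equal(cx$spanning$bases_on_left + cx$spanning$bases_on_right, 201L)
  expect_equal(cx$left_gene$name, "rps19")
  expect_equal(cx$right_gene$name, "rps19")
  expect_equal(cx$left_distance, 0L)
})

test_that("an abutting gene has distance zero without spanning", {
  tet <- published_tetrad()
  j <- compute_junctions(tet)
  genes <- list(gene_feature("rpl22", "-", c(84000L, 84221L)))
  cx <- gene_context(genes, j$JLB, tet$genome_length)
  expect_null(cx$spanning)
  expect_equal(cx$left_gene$name, "rpl22")
  expect_equal(cx$left_distance, 0L)
})

test_that("an empty gene list leaves both flanks absent", {
  tet <- published_tetrad()
  j <- compute_junctions(tet)
  cx <- gene_context(list(), j$JSB, tet$genome_length)
  expect_null(cx$left_gene)
  expect_null(cx$right_gene)
  expect_true(is.na(cx$left_distance))
})

test_that("moving a gene across a junction mirrors its flank and distance", {
  tet <- published_tetrad()
  j <- compute_junctions(tet)
  n <- tet$genome_length
  before <- list(gene_feature("ndhX", "+", c(84150L, 84211L)))  # ends 10 bp left
  after <- list(gene_feature("ndhX", "+", c(84232L, 84293L)))   # starts 10 bp right
  cx_b <- gene_context(before, j$JLB, n)
  cx_a <- gene_context(after, j$JLB, n)
  expect_equal(cx_b$left_gene$name, "ndhX")
  expect_equal(cx_b$left_distance, 10L)
  expect_equal(cx_a$right_gene$name, "ndhX")
  expect_equal(cx_a$right_distance, 10L)
})

test_that("JLA wraps: genes near base 1 flank it on the right, wrapping genes span it", {
  tet <- published_tetrad()
  j <- compute_junctions(tet)
  n <- tet$genome_length
  genes <- list(gene_feature("trnH", "-", c(3L, 72L)))
  cx <- gene_context(genes, j$JLA, n)
  expect_equal(cx$right_gene$name, "trnH")
  expect_equal(cx$right_distance, 2L)

  wrap <- list(gene_feature("ycf2", "+", c(154060L, 51L)))  # wraps the origin
  cxw <- gene_context(wrap, j$JLA, n)
  expect_false(is.null(cxw$spanning))
  expect_equal(cxw$spanning$bases_on_left, 49L)   # 154060..154108
  expect_equal(cxw$spanning$bases_on_right, 51L)  # 1..51
  expect_equal(cxw$spanning$bases_on_left + cxw$spanning$bases_on_right,
               cpjunctions:::gene_length(wrap[[1L]], n))
})

test_that("region gene plans apply the 0/1/2+ rule", {
  tet <- tetrad(c(1, 100), c(101, 130), c(131, 160), c(161, 190), 190)
  n <- 190L
  mk <- function(s, e) gene_feature(paste0("g", s), "+", c(s, e))
  # three genes: only first and last plotted, at their locations
  plan3 <- plan_region_genes(list(mk(5L, 20L), mk(40L, 50L), mk(90L, 99L)),
                             tet$lsc, n)
  expect_length(plan3$plotted_genes, 2L)
  expect_equal(vapply(plan3$plotted_genes, function(p) p$gene$name, ""),
               c("g5", "g90"))
  expect_true(all(vapply(plan3$plotted_genes, function(p) p$placement, "") ==
                    "at-location"))
  expect_false(plan3$endpoints_shown)
  # one gene: mid-region with endpoints indicated
  plan1 <- plan_region_genes(list(mk(110L, 120L)), tet$irb, n)
  expect_length(plan1$plotted_genes, 1L)
  expect_equal(plan1$plotted_genes[[1L]]$placement, "mid-region")
  expect_true(plan1$endpoints_shown)
  # no genes: empty plan
  plan0 <- plan_region_genes(list(mk(110L, 120L)), tet$ssc, n)
  expect_length(plan0$plotted_genes, 0L)
})

test_that("junction distances are invariant under the deposited rotation", {
  sigs <- list()
  for (grp in c("a", "c", "f", "h")) {
    fx <- generate_fixture(fixture_spec(start_group = grp, seed = 8))
    sigs[[grp]] <- distance_signature(process_genome(fx$genome))
  }
  for (grp in c("c", "f", "h")) expect_equal(sigs[[grp]], sigs$a)
})
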