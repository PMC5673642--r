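test_that("completeness and contamination follow the marker definitions", {
  markers <- paste0("m", 1:100)
  # 86 single-copy + 4 double-copy present: hand-enumerable from the
  # definitions -> completeness 90, contamination 4
  copies <- setNames(c(rep(1L, 86), rep(2L, 4)), markers[1:90])
  cc <- completeness_contamination(copies, markers)
  expect_equal(cc$completeness, 90)
  expect_equal(cc$contamination, 4)
  all1 <- completeness_contamination(setNames(rep(1L, 100), markers), markers)
  expect_equal(all1$completeness, 100)
  expect_equal(all1$contamination, 0)
  empty <- completeness_contamination(integer(0), markers)
  expect_equal(empty$completeness, 0)
  expect_equal(empty$contamination, 0)
  expect_error(completeness_contamination(copies, character(0)), "empty")
})

test_that("planting a fraction of the marker set is recovered exactly", {
  markers <- paste0("m", 1:50)
  sp <- genome_spec("gm", 3e5, 0.5, 61L, marker_ids = markers[1:40],
                    taxon = "T")
  g <- simulate_genome(sp)
  fr <- fragment_genome(g$seq, 10000L, 20000L, seed = 2L)
  genes <- map_genes_to_contigs(g$genes, fr$truth)
  copies <- marker_copies_in_bin(genes, fr$truth$contig_id)
  cc <- completeness_contamination(copies, markers)
  # boundary-spanning genes are dropped by the mapping; completeness is
  # 100 * planted-and-mapped / 50, always a multiple of 2
  expect_equal(cc$completeness, 100 * length(copies) / 50)
  expect_gte(cc$completeness, 100 * 30 / 50)
  expect_equal(cc$contamination, 0)
})

test_that("estimated genome size applies the contamination-corrected formula", {
  # identity case: complete, uncontaminated
  for (L in c(0.5, 1.9, 4.28)) expect_equal(estimated_genome_size(L, 100, 0), L)
  expect_error(estimated_genome_size(1, 0, 0), "undefined")
  # monotone: size estimate decreases as completeness rises and as
  # contamination rises
  est_c <- vapply(c(50, 60, 70, 80, 90, 100), function(comp)
    estimated_genome_size(2, comp, 0), numeric(1))
  expect_true(all(diff(est_c) < 0))
  est_k <- vapply(c(0, 10, 20, 30), function(k)
    estimated_genome_size(2, 80, k), numeric(1))
  expect_true(all(diff(est_k) < 0))
})

test_that("coding density uses the union of coding intervals", {
  contig <- setNames(paste(rep("A", 1000), collapse = ""), "c1")
  g1 <- gene_calls(c("c1", "c1"), c(0L, 500L), c(300L, 1000L), "+",
                   c("a", "b"))
  expect_equal(coding_density(contig, g1), 80)
  g2 <- gene_calls(c("c1", "c1"), c(0L, 200L), c(300L, 400L), "+",
                   c("a", "b"))
  expect_equal(coding_density(contig, g2), 40)  # union is 400, not 500
  expect_equal(coding_density(contig, g1[0, ]), 0)
  g3 <- gene_calls("c1", 900L, 1100L, "+", "a")
  expect_error(coding_density(contig, g3), "beyond contig end")
})

test_that("median intergenic spacer clamps overlaps at zero", {
  g <- gene_calls(rep("c1", 3), c(0L, 150L, 260L), c(100L, 250L, 300L),
                  "+", c("a", "b", "c"))
  expect_equal(median_intergenic_spacer(g), 30)  # spacers {50, 10}
  g2 <- gene_calls(rep("c1", 2), c(0L, 138L), c(100L, 200L), "+",
                   c("a", "b"))
  expect_equal(median_intergenic_spacer(g2), 38)
  gov <- gene_calls(rep("c1", 2), c(0L, 50L), c(100L, 200L), "+",
                    c("a", "b"))
  expect_equal(median_intergenic_spacer(gov), 0)  # overlap contributes 0
  g1 <- gene_calls("c1", 0L, 100L, "+", "a")
  expect_true(is.na(median_intergenic_spacer(g1)))
})

test_that("GC content excludes N from the denominator", {
  expect_equal(gc_content(c(x = "GGCC")), 100)
  expect_equal(gc_content(c(x = "ATGC")), 50)
  expect_equal(gc_content(c(x = "ATNN")), 0)
  expect_error(gc_content(c(x = "NNNN")), "no A/C/G/T")
})

test_that("MAG records satisfy the size-estimate invariant", {
  markers <- paste0("m", 1:30)
  sp <- genome_spec("gq", 2e5, 0.55, 71L, marker_ids = markers,
                    taxon = "T")
  g <- simulate_genome(sp)
  fr <- fragment_genome(g$seq, 10000L, 20000L, seed = 3L)
  genes <- map_genes_to_contigs(g$genes, fr$truth)
  bins <- data.frame(contig_id = fr$truth$contig_id, bin_id = "bin1",
                     stringsAsFactors = FALSE)
  tab <- suppressWarnings(mag_table(bins, fr$contigs, genes, markers))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$length_mb, 0.2)
  expect_gte(tab$est_size_mb,
             tab$length_mb * (1 - tab$contamination / 100) - 0.01)
  expect_true(tab$gc > 50 & tab$gc < 60)
  expect_identical(tab$n_cds, nrow(genes))
})
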