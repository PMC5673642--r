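test_that("recruitment filters are strict on identity, inclusive on length", {
  g <- simulate_genome(genome_spec("gr", 1e5, 0.5, 201L, taxon = "T"))$seq
  gs <- unname(g)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  # exact 100 bp read: identity 100 -> recruited
  r_exact <- substr(gs, 1001, 1100)
  # 5 interior mismatches, one per 20-block, block ends matching:
  # full-length alignment, identity exactly 95.0 -> rejected (strict > 95)
  v <- strsplit(r_exact, "")[[1]]
  at95 <- v; for (p in seq(10, 90, by = 20)) at95[p] <- flip(at95[p])
  r_95 <- paste(at95, collapse = "")
  # 4 mismatches: 96% -> recruited
  at96 <- v; for (p in seq(10, 70, by = 20)) at96[p] <- flip(at96[p])
  r_96 <- paste(at96, collapse = "")
  # only 49 bp of the read matches the genome -> aln_len < 50 -> rejected
  set.seed(1)
  r_49 <- paste0(substr(gs, 2001, 2049), random_dna(51))
  # 50 bp matching -> recruited (inclusive >= 50)
  r_50 <- paste0(substr(gs, 3001, 3050), random_dna(50))
  reads <- c(exact = r_exact, at95 = r_95, at96 = r_96, m49 = r_49,
             m50 = r_50)
  rec <- recruit(reads, g, seed_stride = 1L)
  expect_setequal(rec$read_ids, c("exact", "at96", "m50"))
  got95 <- best_hit_per_query(search_hits(reads["at95"], g))
  expect_equal(got95$identity, 95)  # confirms the boundary construction
  expect_error(recruit(c(x = "ACGT"), g), "50 bp")
})

test_that("RPKG is the exact normalizing quotient", {
  expect_equal(rpkg(10000, 1000, 1.0), 10)
  expect_equal(rpkg(10000, 2000, 0.5), 10)
  expect_equal(rpkg(5000, 1000, 2.0), rpkg(5000, 1000, 1.0) / 2)
  expect_equal(rpkg(0, 1000, 1), 0)
  expect_error(rpkg(10, 0, 1), "positive")
  expect_error(rpkg(10, 1000, 0), "positive")
})

test_that("RPKG converts to coverage with the 10-RPKG = 1x anchor", {
  expect_equal(rpkg_to_coverage(10, 100, 1.0), 1.0)
  expect_equal(rpkg_to_coverage(10, 150, 1.0), 1.5)
  expect_equal(rpkg_to_coverage(0, 100, 1.0), 0)
})

test_that("tightening any filter never increases the recruited count", {
  com <- fx_community()
  reads <- com$reads$s1$reads[1:4000]
  g <- com$genomes$gA$seq
  base <- recruit(reads, g)$reads_recruited
  tighter <- list(
    pipeline_thresholds(recruit_identity = 0.98),
    pipeline_thresholds(recruit_alnlen_bp = 90L),
    pipeline_thresholds(recruit_evalue = 1e-30))
  for (th in tighter)
    expect_lte(recruit(reads, g, thresholds = th)$reads_recruited, base)
})

test_that("RPKG is proportional to simulated coverage", {
  g <- simulate_genome(genome_spec("gp", 2e5, 0.55, 211L, taxon = "T"))
  covs <- c(0.5, 1, 2, 4)
  cov <- matrix(covs, 1, 4,
                dimnames = list("gp", paste0("s", 1:4)))
  # all samples padded to the same metagenome size, so RPKG tracks the
  # genome's coverage rather than its share of the sample
  des <- community_design(list(g), cov, read_length_bp = 100L,
                          per_base_error = 0.005,
                          metagenome_target_gbp = 0.005, seed = 31L)
  smps <- simulate_reads(des)
  ab <- abundance_matrix(list(gp = g$seq), smps)
  v <- ab$matrix["gp", ]
  fit <- summary(stats::lm(v ~ covs))
  expect_gte(fit$r.squared, 0.99)
})

test_that("an absent genome recruits essentially nothing", {
  g <- simulate_genome(genome_spec("gq2", 2e5, 0.55, 221L, taxon = "T"))
  absent <- simulate_genome(genome_spec("gabs", 2e5, 0.45, 223L,
                                        taxon = "T"))
  cov <- matrix(1, 1, 1, dimnames = list("gq2", "sA"))
  des <- community_design(list(g), cov, read_length_bp = 100L,
                          per_base_error = 0, seed = 33L)
  smp <- simulate_reads(des)
  rec <- recruit(smp$sA$reads, absent$seq)
  expect_lt(rec$reads_recruited / rec$reads_total, 0.001)
})

test_that("the abundance matrix is complete and sample-order invariant", {
  g1 <- simulate_genome(genome_spec("m1", 1e5, 0.5, 231L, taxon = "T"))
  g2 <- simulate_genome(genome_spec("m2", 1e5, 0.6, 233L, taxon = "T"))
  cov <- matrix(c(1, 0, 0, 2), 2, 2,
                dimnames = list(c("m1", "m2"), c("sA", "sB")))
  des <- community_design(list(g1, g2), cov, read_length_bp = 100L,
                          per_base_error = 0, seed = 35L)
  smps <- simulate_reads(des)
  ab <- abundance_matrix(list(m1 = g1$seq, m2 = g2$seq), smps)
  ab_rev <- abundance_matrix(list(m1 = g1$seq, m2 = g2$seq), rev(smps))
  expect_equal(ab$matrix, ab_rev$matrix[, colnames(ab$matrix)])
  expect_false(anyNA(ab$matrix))
  # equal coverage, different metagenome sizes -> comparable RPKG:
  # m1 at 1x in sA (0.1 Gbp of... desk scale) vs absent in sB
  expect_gt(ab$matrix["m1", "sA"], 100 * ab$matrix["m1", "sB"] + 1e-12)
})
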