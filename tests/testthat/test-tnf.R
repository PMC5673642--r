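test_that("canonical 4-mer classes match the brute-force enumeration", {
  # independent oracle: enumerate all 256 4-mers, pair each with its
  # reverse complement, count equivalence classes
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste,
                 collapse = "")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- vapply(kmers, function(k) paste(rev(comp[strsplit(k, "")[[1]]]),
                                        collapse = ""), character(1))
  classes <- unique(pmin(kmers, rc))
  expect_identical(length(classes), 136L)
  expect_identical(sum(kmers == rc), 16L)  # palindromes
  expect_identical(canonical_tetranucleotides(), sort(classes))
})

test_that("tetranucleotide profiles are normalized and handle edge cases", {
  p <- suppressWarnings(tnf_profile("AAAAA"))
  expect_equal(unname(p["AAAA"]), 1)
  expect_equal(sum(p), 1)
  expect_length(p, 136L)
  expect_error(suppressWarnings(tnf_profile("ACG")), "shorter than 4")
  # N windows are excluded
  pN <- suppressWarnings(tnf_profile("AAAANAAAA"))
  expect_equal(unname(pN["AAAA"]), 1)
})

test_that("profiles are exactly reverse-complement invariant (fuzzed)", {
  set.seed(11)
  for (i in 1:15) {
    s <- random_dna(sample(200:800, 1))
    if (i %% 3 == 0) substr(s, 50, 52) <- "NNN"
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_identical(suppressWarnings(tnf_profile(s)),
                     suppressWarnings(tnf_profile(rc)))
  }
})

test_that("the taxonomy vote applies strict > 60% and > 10 kb gates", {
  th <- pipeline_thresholds()
  v <- taxonomy_vote(15000, c(rep("V", 7), rep("W", 3)), "V", th)
  expect_equal(v$vote_fraction, 0.7)
  expect_true(v$passes)
  # 6/10 is not > 60%
  v6 <- taxonomy_vote(15000, c(rep("V", 6), rep("W", 4)), "V", th)
  expect_equal(v6$vote_fraction, 0.6)
  expect_false(v6$passes)
  # length gate: 8 kb fails regardless of the vote
  v8 <- taxonomy_vote(8000, c(rep("V", 9), "W"), "V", th)
  expect_false(v8$passes)
  # exactly 10 kb fails the strict length gate
  expect_false(taxonomy_vote(10000, rep("V", 10), "V", th)$passes)
  expect_true(taxonomy_vote(10001, rep("V", 10), "V", th)$passes)
  # unlabeled genes count in the denominator
  vNA <- taxonomy_vote(15000, c(rep("V", 6), rep(NA, 4)), "V", th)
  expect_equal(vNA$vote_fraction, 0.6)
  # zero genes: undefined vote, fails
  v0 <- taxonomy_vote(15000, character(0), "V", th)
  expect_true(is.na(v0$vote_fraction))
  expect_false(v0$passes)
})

test_that("PCA matches an independent eigen-decomposition oracle", {
  set.seed(13)
  x <- matrix(stats::rnorm(20 * 10), 20, 10)
  res <- tnf_pca(x, n_components = 4L)
  # oracle: covariance eigendecomposition with the same sign convention
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc), symmetric = TRUE)
  for (j in 1:4) {
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(res$loadings[, j]), unname(v), tolerance = 1e-8)
    expect_equal(unname(res$scores[, j]), unname(drop(xc %*% v)),
                 tolerance = 1e-8)
  }
  expect_equal(sum(res$variance_explained), 1, tolerance = 1e-9)
  # orthonormality
  g <- crossprod(res$loadings)
  expect_equal(unname(g), diag(4), tolerance = 1e-9)
  expect_error(tnf_pca(matrix(1, 10, 5), 2L), "degenerate")
})

test_that("coverage is alignment length over contig length", {
  hits <- data.frame(aln_len = rep(100L, 10))
  expect_equal(coverage_estimate(1000, hits), 1.0)
  expect_equal(coverage_estimate(1000, hits[0, , drop = FALSE]), 0)
})

test_that("simulated coverage is recovered through recruitment", {
  com <- fx_community()
  feat <- contig_features(com$contigs, com$genes, "Verrucomicrobia",
                          coverages = list(s1 = com$recruitment$hits))
  tg <- com$truth$genome_id[match(feat$contig_id, com$truth$contig_id)]
  means <- tapply(feat$cov_s1, tg, mean)
  expect_lt(abs(means[["gA"]] - 2), 2 * 0.05 * 2)
  expect_lt(abs(means[["gB"]] - 4), 2 * 0.05 * 4)
  expect_lt(abs(means[["gC"]] - 8), 2 * 0.05 * 8)
})

test_that("binning recovers the genomes and is deterministic", {
  com <- fx_community()
  feat <- contig_features(com$contigs, com$genes, "Verrucomicrobia",
                          coverages = list(s1 = com$recruitment$hits))
  expect_true(all(feat$passes_taxon_filter))
  b1 <- cluster_contigs(feat, seed = 42L)
  b2 <- cluster_contigs(feat, seed = 42L)
  expect_identical(b1, b2)
  tg <- com$truth$genome_id[match(b1$contig_id, com$truth$contig_id)]
  expect_gte(ari(b1$bin_id, tg), 0.95)
  # binning is a partition of the filtered set
  expect_false(anyNA(b1$bin_id))
  expect_identical(sort(b1$contig_id), sort(feat$contig_id))
})

test_that("a single genome collapses to one bin", {
  com <- fx_community()
  keep <- grepl("^gA_", names(com$contigs))
  feat <- contig_features(com$contigs[keep],
                          com$genes[grepl("^gA_", com$genes$contig_id), ],
                          "Verrucomicrobia",
                          coverages = list(s1 = com$recruitment$hits))
  bins <- cluster_contigs(feat, seed = 1L)
  expect_identical(length(unique(bins$bin_id)), 1L)
})

test_that("contigs failing the taxon filter are never binned", {
  com <- fx_community()
  genes <- com$genes
  # strip the labels of one genome's genes: its contigs must stay unbinned
  genes$taxon[grepl("^gC_", genes$contig_id)] <- NA
  feat <- contig_features(com$contigs, genes, "Verrucomicrobia",
                          coverages = list(s1 = com$recruitment$hits))
  bins <- cluster_contigs(feat, seed = 1L)
  gC <- grepl("^gC_", bins$contig_id)
  expect_true(all(is.na(bins$bin_id[gC])))
  expect_false(anyNA(bins$bin_id[!gC]))
})
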