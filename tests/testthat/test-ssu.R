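test_that("identical references collapse to one centroid; members conserve", {
  set.seed(1)
  s <- random_dna(900)
  db <- reference_db(setNames(rep(s, 5), paste0("r", 1:5)),
                     setNames(rep("TaxA", 5), paste0("r", 1:5)))
  cdb <- suppressWarnings(dereplicate_references(db))
  expect_identical(length(cdb$centroids$seqs), 1L)
  expect_identical(length(cdb$members), 5L)
  expect_identical(unname(unique(cdb$members)), names(cdb$centroids$seqs))
})

test_that("sequences at ~85% identity become separate centroids", {
  set.seed(2)
  a <- setNames(random_dna(1000), "a")
  b <- mutate_genome(a, 0.15, seed = 9, id = "b")
  db <- suppressWarnings(reference_db(c(a, b), c(a = "T", b = "T")))
  cdb <- suppressWarnings(dereplicate_references(db, identity = 0.90))
  expect_identical(length(cdb$centroids$seqs), 2L)
})

test_that("dereplication of the reference set partitions it by taxon", {
  refs <- fx_refs()
  cdb <- fx_cdb()
  # conservation: every record assigned, centroids are records
  expect_identical(sort(names(cdb$members)), sort(names(refs$seqs)))
  expect_true(all(names(cdb$centroids$seqs) %in% names(refs$seqs)))
  # at 12% between-taxon divergence members join same-taxon centroids
  expect_true(all(refs$taxa[cdb$members] == refs$taxa[names(cdb$members)]))
})

test_that("candidacy is sensitive to planted 16S and specific to genomic reads", {
  refs <- fx_refs(); cdb <- fx_cdb()
  set.seed(31)
  pos <- vapply(1:200, function(i)
    ssu_fragment(refs, sample(unique(refs$taxa), 1)), character(1))
  names(pos) <- paste0("p", 1:200)
  g <- simulate_genome(genome_spec("bgg", 2e5, 0.5, 301L, taxon = "x"))$seq
  st <- sample.int(2e5 - 99, 1000)
  neg <- setNames(substring(unname(g), st, st + 99), paste0("n", 1:1000))
  cand_pos <- detect_candidates(pos, cdb)
  cand_neg <- detect_candidates(neg, cdb)
  expect_gte(length(cand_pos) / 200, 0.99)
  expect_lte(length(cand_neg) / 1000, 0.01)  # >= 99% specificity
  expect_identical(detect_candidates(character(0), cdb), character(0))
  expect_error(detect_candidates(setNames("ACGT", "x"), cdb), "50 bp")
})

test_that("the candidacy e-value cutoff is strict", {
  refs <- fx_refs(); cdb <- fx_cdb()
  set.seed(37)
  r <- setNames(ssu_fragment(refs, "Verrucomicrobia"), "r1")
  best <- best_hit_per_query(search_hits(r, cdb$centroids$seqs))
  # at a cutoff equal to the read's own e-value the strict < excludes it
  expect_identical(detect_candidates(r, cdb, evalue_max = best$evalue),
                   character(0))
  expect_identical(detect_candidates(r, cdb,
                                     evalue_max = best$evalue * 1.01), "r1")
})

test_that("profile verification passes true 16S and rejects shuffles", {
  refs <- fx_refs(); prof <- fx_profile()
  expect_error(train_ssu_profile(reference_db(
    refs$seqs[1:10], refs$taxa[1:10])), "too few")
  set.seed(41)
  true_frags <- vapply(1:400, function(i)
    ssu_fragment(refs, sample(unique(refs$taxa), 1)), character(1))
  names(true_frags) <- paste0("t", 1:400)
  shuf <- vapply(unname(true_frags), dinucleotide_shuffle, character(1))
  names(shuf) <- paste0("s", 1:400)
  expect_gte(length(verify_ssu(true_frags, prof)) / 400, 0.95)
  expect_lte(length(verify_ssu(shuf, prof)) / 400, 0.03)
  # deterministic given profile and threshold
  expect_identical(verify_ssu(true_frags, prof),
                   verify_ssu(true_frags, prof))
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(43)
  for (i in 1:20) {
    s <- random_dna(100)
    sh <- dinucleotide_shuffle(s)
    di <- function(x) sort(table(substring(x, 1:(nchar(x) - 1),
                                           2:nchar(x))))
    expect_identical(di(sh), di(s))
  }
})

test_that("classification thresholds are inclusive at 80% and 90 bp", {
  set.seed(47)
  ref <- setNames(random_dna(1200), "refX")
  db <- suppressWarnings(reference_db(ref, c(refX = "TaxX")))
  # exact 90 bp copy: identity 100, aln_len 90 -> classified (boundary)
  r90 <- setNames(substr(ref, 101, 190), "r90")
  # exact 89 bp copy -> aln_len 89 -> discarded (boundary)
  r89 <- setNames(substr(ref, 101, 189), "r89")
  cls <- classify_reads(c(r90, r89), db)
  expect_identical(cls$status[cls$read_id == "r90"], "classified")
  expect_identical(cls$taxon[cls$read_id == "r90"], "TaxX")
  expect_identical(cls$status[cls$read_id == "r89"], "discarded")
  # identity threshold is inclusive: a read classified at an id_min equal
  # to its own best-hit identity, discarded the moment id_min exceeds it
  rdiv <- mutate_genome(setNames(substr(ref, 501, 620), "x"), 0.08,
                        seed = 77, id = "rdiv")
  obs <- best_hit_per_query(search_hits(rdiv, db$seqs))
  expect_lt(obs$identity, 100)
  at <- classify_reads(rdiv, db, id_min = obs$identity / 100)
  expect_identical(at$status, "classified")
  above <- classify_reads(rdiv, db, id_min = obs$identity / 100 + 1e-4)
  expect_identical(above$status, "discarded")
})

test_that("raising the identity threshold only shrinks the classified set", {
  refs <- fx_refs()
  set.seed(53)
  rr <- vapply(1:150, function(i)
    ssu_fragment(refs, sample(unique(refs$taxa), 1), div = 0.05),
    character(1))
  names(rr) <- paste0("q", seq_along(rr))
  sizes <- vapply(c(0.80, 0.90, 0.95, 0.99), function(idm)
    sum(classify_reads(rr, refs, id_min = idm)$status == "classified"),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("relative abundance arithmetic sums to 100", {
  cls <- data.frame(
    read_id = paste0("r", 1:150), status = "classified",
    taxon = c(rep("Verrucomicrobia", 30), rep("Other", 120)),
    stringsAsFactors = FALSE)
  ab <- taxon_relative_abundance(cls)
  expect_equal(ab$percent[ab$taxon == "Verrucomicrobia"], 20)
  expect_equal(sum(ab$percent), 100)
  one <- taxon_relative_abundance(cls[1:30, ])
  expect_equal(one$percent, 100)
  cls$status <- "discarded"
  expect_error(taxon_relative_abundance(cls), "no classified")
})

test_that("screening statuses partition the read set", {
  refs <- fx_refs()
  set.seed(59)
  pos <- vapply(1:50, function(i) ssu_fragment(refs, "Verrucomicrobia"),
                character(1))
  g <- simulate_genome(genome_spec("bg2", 1e5, 0.5, 401L, taxon = "x"))$seq
  st <- sample.int(1e5 - 99, 150)
  reads <- setNames(c(pos, substring(unname(g), st, st + 99)),
                    paste0("r", 1:200))
  res <- screen_ssu_reads(reads, refs, cdb = fx_cdb(), profile = fx_profile())
  expect_identical(nrow(res), 200L)
  expect_true(all(res$status %in% c("not_candidate", "candidate_rejected",
                                    "classified", "discarded")))
  expect_true(all(is.na(res$taxon) == (res$status != "classified")))
})
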