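# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# labeled synthetic 16S reference set (60 records, 6 taxa)
fx_refs <- function() fx("refs", function() synthetic_ssu_refs(seed = 3L))

fx_cdb <- function() fx("cdb", function() dereplicate_references(fx_refs()))

fx_profile <- function() fx("profile", function()
  train_ssu_profile(fx_refs(), seed = 11L))

# three-genome community at the study conditions for binning recovery:
# distinct composition seeds, GC 52/58/64% (>= 5 point gaps), coverages
# 2x/4x/8x, contigs >= 10 kb, 0.5% read error
fx_community <- function() fx("community", function() {
  specs <- list(
    genome_spec("gA", 4e5, 0.52, 11L, taxon = "Verrucomicrobia"),
    genome_spec("gB", 4e5, 0.58, 23L, taxon = "Verrucomicrobia"),
    genome_spec("gC", 4e5, 0.64, 37L, taxon = "Verrucomicrobia"))
  genomes <- lapply(specs, simulate_genome)
  names(genomes) <- vapply(genomes, function(g) g$spec$genome_id, "")
  frags <- lapply(genomes, function(g)
    fragment_genome(g$seq, min_bp = 10000L, mean_bp = 20000L, seed = 7L))
  contigs <- do.call(c, unname(lapply(frags, `[[`, "contigs")))
  truth <- do.call(rbind, lapply(frags, `[[`, "truth"))
  genes <- NULL
  for (cid in names(contigs)) {
    n <- 10L
    st <- round(seq(0, nchar(contigs[[cid]]) - 200, length.out = n))
    genes <- rbind(genes, gene_calls(cid, st, st + 150L, "+",
                                     paste0(cid, "_g", seq_len(n)),
                                     "Verrucomicrobia"))
  }
  cov <- matrix(c(2, 4, 8), 3, 1,
                dimnames = list(c("gA", "gB", "gC"), "s1"))
  design <- community_design(genomes, cov, read_length_bp = 100L,
                             per_base_error = 0.005, seed = 5L)
  reads <- simulate_reads(design)
  rec <- recruit(reads$s1$reads, contigs)
  list(genomes = genomes, contigs = contigs, truth = truth, genes = genes,
       reads = reads, recruitment = rec)
})

# random DNA of a given length from the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# adjusted Rand index between two labelings (independent of the binning
# implementation; mclust's reference version)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# full Smith-Waterman local alignment score oracle (Biostrings DP)
sw_oracle_score <- function(q, s, scheme = scoring_scheme()) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = submat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)@score)
}

# read-sized fragment of a random reference record of the given taxon,
# mutated at `div` (the planting divergence)
ssu_fragment <- function(refs, taxon, len = 100L, div = 0.02) {
  ids <- names(refs$taxa)[refs$taxa == taxon]
  src <- refs$seqs[[sample(ids, 1)]]
  s <- mutate_genome(setNames(src, "x"), div, seed = sample.int(1e6, 1))
  a <- sample.int(nchar(s) - len + 1L, 1)
  substr(s, a, a + len - 1L)
}
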