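# Ground-truthed synthetic communities.
#
# Genomes are emitted by per-genome order-2 Markov chains whose conditional
# G+C probability equals the GC target in every context, so realized GC is
# binomially tight around the target while the tetranucleotide profile
# differs between composition seeds — the signal the composition binner
# exploits. Mutation is substitution-only, which keeps true nucleotide
# identity analytic (1 - mu) for the ANI recovery checks.

#' Order-2 Markov transition matrix for a composition seed
#'
#' Row-stochastic 16 x 4 matrix (rows indexed by the two preceding bases in
#' A,C,G,T order). Within every context the conditional probability of
#' drawing G or C equals `gc_target` exactly; how that mass splits between
#' G/C (and A/T) is drawn from the seed, giving each genome its own
#' tetranucleotide signature.
#'
#' @param gc_target target GC fraction in `[0.2, 0.8]`.
#' @param composition_seed integer seed for the per-context splits.
#' @param concentration Dirichlet-like concentration of the splits; smaller
#'   values give more strongly skewed (more separable) compositions.
#' @return list with `trans` (16 x 4 matrix) and `init` (length-4 marginal).
#' @export
markov_transitions <- function(gc_target, composition_seed,
                               concentration = 0.5) {
  stopifnot(gc_target >= 0.2, gc_target <= 0.8)
  set.seed(as.integer(composition_seed))
  trans <- matrix(0, 16, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (r in 1:16) {
    w <- stats::rgamma(4, shape = concentration) + 1e-4
    at <- (1 - gc_target) * w[c(1, 4)] / (w[1] + w[4])
    gc <- gc_target * w[2:3] / (w[2] + w[3])
    trans[r, ] <- c(at[1], gc[1], gc[2], at[2])
  }
  init <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  list(trans = trans, init = init)
}

#' Specification of one synthetic genome
#'
#' @param genome_id unique token.
#' @param length_bp genome length; at least 50 kb for binnable genomes
#'   (shorter values are allowed but warned about).
#' @param gc_target GC fraction in `[0.2, 0.8]`.
#' @param composition_seed integer controlling both the tetranucleotide
#'   signature and the realized sequence (the generator's seed).
#' @param n_16s_copies number of 16S genes to plant.
#' @param marker_ids single-copy marker gene ids to plant.
#' @param taxon high-level taxon label for ground truth.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(genome_id, length_bp, gc_target, composition_seed,
                        n_16s_copies = 0L, marker_ids = character(),
                        taxon = "Unknown") {
  stopifnot(length_bp >= 1000, gc_target >= 0.2, gc_target <= 0.8,
            n_16s_copies >= 0)
  if (length_bp < 50000)
    warning("genomes shorter than 50 kb are not reliably binnable")
  structure(list(genome_id = as.character(genome_id),
                 length_bp = as.integer(length_bp),
                 gc_target = gc_target,
                 composition_seed = as.integer(composition_seed),
                 n_16s_copies = as.integer(n_16s_copies),
                 marker_ids = as.character(marker_ids),
                 taxon = as.character(taxon)),
            class = "genome_spec")
}

#' Simulate one genome with planted markers and 16S genes
#'
#' Deterministic given the spec (the composition seed is the RNG seed).
#' Single-copy markers are planted as non-overlapping gene intervals
#' (recorded as gene calls labeled with the genome's taxon); 16S copies are
#' mutated copies (at `ssu_mutation`, at most 2%) of a reference sequence of
#' the genome's taxon, spliced into the genome and recorded in the truth
#' table.
#'
#' @param spec a [genome_spec()].
#' @param ssu_refs a [reference_db()]; required when `n_16s_copies > 0`.
#' @param marker_len_bp planted marker gene length.
#' @param ssu_mutation per-site substitution rate applied to the planted 16S
#'   copy (`<= 0.02`).
#' @return list of class `sim_genome`: `seq` (named character), `genes`
#'   (gene calls of the planted markers), `ssu` (data.frame of planted 16S
#'   intervals with their source reference and taxon), `spec`.
#' @export
simulate_genome <- function(spec, ssu_refs = NULL, marker_len_bp = 900L,
                            ssu_mutation = 0.02) {
  stopifnot(inherits(spec, "genome_spec"), ssu_mutation <= 0.02)
  if (spec$n_16s_copies > 0 && is.null(ssu_refs))
    stop("ssu_refs required to plant 16S copies")
  if (marker_len_bp >= spec$length_bp)
    stop("marker longer than genome")
  mt <- markov_transitions(spec$gc_target, spec$composition_seed)
  # markov_transitions seeded the RNG; all draws below follow from it
  seq <- cpp_markov_chain(spec$length_bp, mt$trans, mt$init)

  # choose non-overlapping intervals for markers and 16S copies
  ssu_len <- 0L
  ssu_src <- character(0)
  if (spec$n_16s_copies > 0) {
    of_taxon <- names(ssu_refs$taxa)[ssu_refs$taxa == spec$taxon]
    if (length(of_taxon) == 0)
      stop("no 16S reference with taxon '", spec$taxon, "'")
    ssu_src <- sample(of_taxon, spec$n_16s_copies, replace = TRUE)
  }
  widths <- c(rep(as.integer(marker_len_bp), length(spec$marker_ids)),
              if (spec$n_16s_copies > 0) nchar(ssu_refs$seqs[ssu_src]))
  if (sum(widths) > spec$length_bp)
    stop("planted genes do not fit in the genome")
  starts <- place_intervals(spec$length_bp, widths)

  nm <- length(spec$marker_ids)
  genes <- NULL
  if (nm > 0) {
    genes <- gene_calls(
      contig_id = spec$genome_id, start = starts[seq_len(nm)],
      end = starts[seq_len(nm)] + marker_len_bp,
      strand = sample(c("+", "-"), nm, replace = TRUE),
      gene_id = paste0(spec$genome_id, "|", spec$marker_ids),
      taxon = spec$taxon)
    genes$marker_id <- spec$marker_ids
  }
  ssu <- data.frame(gene_id = character(), start = integer(),
                    end = integer(), ref_id = character(),
                    taxon = character(), stringsAsFactors = FALSE)
  if (spec$n_16s_copies > 0) {
    for (i in seq_len(spec$n_16s_copies)) {
      src <- ssu_src[i]
      copy <- cpp_mutate(unname(ssu_refs$seqs[src]), ssu_mutation)
      s <- starts[nm + i]
      substr(seq, s + 1, s + nchar(copy)) <- copy
      ssu <- rbind(ssu, data.frame(
        gene_id = sprintf("%s|ssu_%d", spec$genome_id, i),
        start = s, end = s + nchar(copy), ref_id = src,
        taxon = spec$taxon, stringsAsFactors = FALSE))
    }
  }
  out <- list(seq = setNames(seq, spec$genome_id), genes = genes,
              ssu = ssu, spec = spec)
  class(out) <- "sim_genome"
  out
}

# Greedy rejection placement of non-overlapping intervals; uses the current
# RNG stream.
place_intervals <- function(genome_len, widths) {
  if (length(widths) == 0) return(integer(0))
  starts <- integer(length(widths))
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in seq_along(widths)) {
    w <- widths[i]
    for (try in 1:1000) {
      s <- sample.int(genome_len - w + 1L, 1L) - 1L
      if (!any(s < taken_e & (s + w) > taken_s)) break
      if (try == 1000) stop("could not place planted genes without overlap")
    }
    starts[i] <- s
    taken_s <- c(taken_s, s); taken_e <- c(taken_e, s + w)
  }
  starts
}

#' Mutate a genome by point substitutions
#'
#' Substitution-only (no indels), so the expected nucleotide identity to the
#' input is exactly `1 - mu` — the analytic truth used to validate ANI.
#'
#' @param genome named character vector of length 1 (or plain string).
#' @param mu per-site substitution rate in `[0, 0.3]`.
#' @param seed integer seed.
#' @param id id for the mutant (default `<id>_mut`).
#' @return named character vector of length 1.
#' @export
mutate_genome <- function(genome, mu, seed = 1L, id = NULL) {
  stopifnot(mu >= 0, mu <= 0.3, length(genome) == 1)
  nm <- if (!is.null(id)) id
        else if (!is.null(names(genome))) paste0(names(genome), "_mut")
        else "mutant"
  set.seed(as.integer(seed))
  setNames(cpp_mutate(unname(unclass(genome)[1]), mu), nm)
}

#' Fragment a genome into assembly-like contigs
#'
#' Non-overlapping tiling fragments covering the genome exactly once, with
#' lengths drawn from a shifted geometric law (`min_bp` plus a geometric
#' with mean `mean_bp - min_bp`). The trailing remainder is merged into the
#' final fragment so lengths are conserved and every fragment is `>= min_bp`.
#'
#' @param genome named character vector of length 1.
#' @param min_bp minimum fragment length.
#' @param mean_bp mean fragment length (`>= min_bp`).
#' @param seed integer seed.
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame: contig_id, genome_id, start, end in genome coordinates).
#' @export
fragment_genome <- function(genome, min_bp = 10000L, mean_bp = 20000L,
                            seed = 1L) {
  stopifnot(length(genome) == 1, mean_bp >= min_bp)
  gid <- if (is.null(names(genome))) "genome" else names(genome)
  glen <- nchar(genome)
  if (glen < min_bp) stop("genome shorter than min_bp")
  set.seed(as.integer(seed))
  lens <- integer(0); total <- 0L
  p <- if (mean_bp > min_bp) 1 / (mean_bp - min_bp + 1) else 1
  while (total < glen) {
    l <- min_bp + (if (mean_bp > min_bp) stats::rgeom(1, p) else 0L)
    lens <- c(lens, as.integer(l)); total <- total + l
  }
  # clip the last fragment to the genome end; if that leaves it short,
  # merge it into the previous fragment
  over <- total - glen
  lens[length(lens)] <- lens[length(lens)] - over
  if (length(lens) > 1 && lens[length(lens)] < min_bp) {
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  ends <- cumsum(as.numeric(lens))
  starts <- ends - lens
  ids <- sprintf("%s_c%03d", gid, seq_along(lens))
  contigs <- setNames(substring(unname(genome), starts + 1, ends), ids)
  list(contigs = contigs,
       truth = data.frame(contig_id = ids, genome_id = gid,
                          start = as.integer(starts), end = as.integer(ends),
                          stringsAsFactors = FALSE))
}

#' Remap genome-coordinate gene calls onto fragments
#'
#' Genes falling entirely within one fragment are remapped to contig-local
#' coordinates; genes spanning a fragment boundary are dropped (as an
#' assembler would truncate them).
#'
#' @param genes gene calls in genome coordinates (see [gene_calls()]).
#' @param fragment_truth the `truth` table from [fragment_genome()].
#' @return gene calls in contig coordinates.
#' @export
map_genes_to_contigs <- function(genes, fragment_truth) {
  out <- NULL
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    f <- fragment_truth[fragment_truth$genome_id == g$contig_id &
                          fragment_truth$start <= g$start &
                          fragment_truth$end >= g$end, ]
    if (nrow(f) == 0) next
    g$contig_id <- f$contig_id[1]
    g$start <- g$start - f$start[1]
    g$end <- g$end - f$start[1]
    out <- if (is.null(out)) g else rbind(out, g)
  }
  if (is.null(out)) genes[0, , drop = FALSE] else out
}

#' Community design for read simulation
#'
#' @param genomes list of `sim_genome` objects (see [simulate_genome()]).
#' @param coverage numeric matrix, genomes x samples (dimnames give ids),
#'   of target per-genome sequencing depth in each sample.
#' @param read_length_bp read length.
#' @param per_base_error i.i.d. substitution error rate in `[0, 0.1]`.
#' @param metagenome_target_gbp optional total Gbp of read sequence per
#'   sample; shortfall is padded with reads from a background genome
#'   labeled `"noise"` in the truth, so recruitment specificity is
#'   measurable.
#' @param background a `sim_genome` used as filler (a default 2 Mb genome
#'   is generated when padding is requested and none is supplied).
#' @param seed integer seed.
#' @return object of class `community_design`.
#' @export
community_design <- function(genomes, coverage, read_length_bp = 100L,
                             per_base_error = 0,
                             metagenome_target_gbp = NULL,
                             background = NULL, seed = 1L) {
  stopifnot(is.matrix(coverage), all(coverage >= 0),
            per_base_error >= 0, per_base_error <= 0.1,
            read_length_bp >= 30)
  if (is.null(rownames(coverage)))
    rownames(coverage) <- vapply(genomes, function(g) g$spec$genome_id, "")
  if (is.null(colnames(coverage)))
    colnames(coverage) <- sprintf("sample%d", seq_len(ncol(coverage)))
  gids <- unname(vapply(genomes, function(g) g$spec$genome_id, ""))
  stopifnot(identical(sort(rownames(coverage)), sort(gids)))
  genomes <- genomes[match(rownames(coverage), gids)]
  if (!is.null(metagenome_target_gbp) && is.null(background)) {
    background <- simulate_genome(genome_spec(
      "noise", 2e6, 0.45, composition_seed = as.integer(seed) + 104729L,
      taxon = "noise"))
  }
  structure(list(genomes = genomes, coverage = coverage,
                 read_length_bp = as.integer(read_length_bp),
                 per_base_error = per_base_error,
                 metagenome_target_gbp = metagenome_target_gbp,
                 background = background, seed = as.integer(seed)),
            class = "community_design")
}

#' Simulate shotgun reads for every sample of a design
#'
#' Per genome `g` and sample `s` the read count is
#' `round(coverage[g, s] * genome_length / read_length)`; start positions
#' are uniform, strands random, and substitution errors i.i.d. at the
#' design's error rate. When `metagenome_target_gbp` is set, reads from the
#' background (`"noise"`) genome pad each sample to that total. A sample
#' requiring more than 1e7 reads is refused.
#'
#' @param design a [community_design()].
#' @param seed integer seed (defaults to the design's).
#' @return named list, one element per sample, each a list with `reads`
#'   (named character vector), `truth` (source genome id per read) and
#'   `total_bp` (total read sequence simulated for the sample).
#' @export
simulate_reads <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "community_design"))
  set.seed(as.integer(seed))
  rl <- design$read_length_bp
  cov <- design$coverage
  out <- list()
  for (s in colnames(cov)) {
    counts <- vapply(rownames(cov), function(g) {
      gl <- design$genomes[[which(rownames(cov) == g)]]$spec$length_bp
      as.integer(round(cov[g, s] * gl / rl))
    }, integer(1))
    n_fill <- 0L
    if (!is.null(design$metagenome_target_gbp)) {
      want <- design$metagenome_target_gbp * 1e9
      have <- sum(as.numeric(counts)) * rl
      if (have < want) n_fill <- as.integer(round((want - have) / rl))
    }
    if (sum(as.numeric(counts)) + n_fill > 1e7)
      stop("sample '", s, "' would require more than 1e7 reads; ",
           "reduce coverage or metagenome size")
    reads <- vector("list", length(counts) + 1L)
    truth <- vector("list", length(counts) + 1L)
    for (i in seq_along(counts)) {
      g <- design$genomes[[i]]
      reads[[i]] <- draw_reads(unname(g$seq), counts[i], rl)
      truth[[i]] <- rep(g$spec$genome_id, counts[i])
    }
    if (n_fill > 0) {
      reads[[length(reads)]] <- draw_reads(unname(design$background$seq),
                                           n_fill, rl)
      truth[[length(truth)]] <- rep("noise", n_fill)
    }
    reads <- unlist(reads, use.names = FALSE)
    truth <- unlist(truth, use.names = FALSE)
    if (design$per_base_error > 0)
      reads <- cpp_add_errors(reads, design$per_base_error)
    names(reads) <- sprintf("%s_r%07d", s, seq_along(reads))
    out[[s]] <- list(reads = reads, truth = truth,
                     total_bp = length(reads) * as.numeric(rl))
  }
  out
}

# Uniform single-end reads from one genome string, random strand.
draw_reads <- function(genome, n, read_len) {
  if (n == 0) return(character(0))
  glen <- nchar(genome)
  if (glen < read_len) stop("genome shorter than read length")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome)))
  starts <- sample.int(glen - read_len + 1L, n, replace = TRUE)
  minus <- runif(n) < 0.5
  reads <- character(n)
  if (any(!minus))
    reads[!minus] <- substring(genome, starts[!minus],
                               starts[!minus] + read_len - 1L)
  if (any(minus))
    reads[minus] <- substring(rc, starts[minus],
                              starts[minus] + read_len - 1L)
  reads
}
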