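# Fragment recruitment of metagenome reads against genomes and the RPKG
# abundance measure (reads recruited per kilobase of genome per gigabase of
# metagenome), comparable across metagenomes of different size.

#' Recruit metagenome reads against a genome
#'
#' A read is recruited iff its best hit against the genome satisfies
#' alignment length >= `recruit_alnlen_bp` (inclusive), identity strictly
#' greater than `recruit_identity`, and e-value <= `recruit_evalue`
#' (inclusive). Each read is counted at most once (best hit only, with the
#' deterministic tie rule of [best_hit_per_query()]). Reads are processed
#' in chunks so arbitrarily large read sets stream through.
#'
#' @param reads named character vector of reads (>= 50 bp).
#' @param genome named character vector of the genome's sequences.
#' @param thresholds a [pipeline_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp exact seed length for the search; 16 is a
#'   recruitment-style word size (long seeds are appropriate at the >95%
#'   identity filter and keep genome-scale seeding specific).
#' @param seed_stride query seed-position stride for the search; a
#'   qualifying alignment (>= 50 bp at > 95% identity) contains many exact
#'   16-mers, so sampling every 4th start position loses essentially no
#'   sensitivity while quartering the index lookups.
#' @param min_ungapped_score ungapped pre-filter score for the search (see
#'   [search_hits()]); the default 30 is far below the score any
#'   recruitable alignment (>= 50 bp at > 95% identity) must reach.
#' @param chunk_size reads per search batch.
#' @return list of class `recruitment`: `reads_recruited`, `reads_total`,
#'   `hits` (best-hit table of the recruited reads: subject_id, identity,
#'   aln_len, evalue, coordinates), `read_ids` of recruited reads.
#' @export
recruit <- function(reads, genome, thresholds = pipeline_thresholds(),
                    scheme = scoring_scheme(), min_seed_bp = 16L,
                    seed_stride = 4L, min_ungapped_score = 30L,
                    chunk_size = 500000L) {
  genome <- as_sequences(genome)
  if (length(reads) > 0 && any(nchar(reads) < 50))
    stop("reads must be >= 50 bp")
  n <- length(reads)
  hit_chunks <- list()
  i <- 1L
  while (i <= n) {
    j <- min(i + as.integer(chunk_size) - 1L, n)
    best <- best_hit_per_query(
      search_hits(reads[i:j], genome, scheme = scheme,
                  min_seed_bp = min_seed_bp, stride = seed_stride,
                  min_ungapped_score = min_ungapped_score,
                  best_only = TRUE))
    pass <- best$aln_len >= thresholds$recruit_alnlen_bp &
      best$identity > thresholds$recruit_identity * 100 &
      best$evalue <= thresholds$recruit_evalue
    hit_chunks[[length(hit_chunks) + 1L]] <- best[pass, , drop = FALSE]
    i <- j + 1L
  }
  hits <- if (length(hit_chunks)) do.call(rbind, hit_chunks) else empty_hits()
  rownames(hits) <- NULL
  structure(list(reads_recruited = nrow(hits), reads_total = n,
                 hits = hits, read_ids = hits$query_id),
            class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat(sprintf("recruitment: %d / %d reads recruited\n",
              x$reads_recruited, x$reads_total))
  invisible(x)
}

#' RPKG: reads recruited per kilobase of genome per gigabase of metagenome
#'
#' The exact quotient `reads_recruited / (genome_kb * metagenome_gb)`, where
#' `metagenome_gb` is the gigabase-pairs of read sequence in the sample.
#' 10 RPKG corresponds to 1x coverage for 100 bp reads in a 1 Gbp
#' metagenome (see [rpkg_to_coverage()]).
#'
#' @param reads_recruited recruited read count (>= 0).
#' @param genome_kb genome length in kb (> 0).
#' @param metagenome_gb metagenome size in Gbp of read sequence (> 0).
#' @return numeric RPKG.
#' @examples
#' rpkg(10000, 1000, 1.0)  # 10
#' @export
rpkg <- function(reads_recruited, genome_kb, metagenome_gb) {
  if (any(genome_kb <= 0) || any(metagenome_gb <= 0))
    stop("genome_kb and metagenome_gb must be positive")
  stopifnot(all(reads_recruited >= 0))
  reads_recruited / (genome_kb * metagenome_gb)
}

#' Convert RPKG to sequencing depth
#'
#' `coverage = rpkg * metagenome_gb * read_length_bp / 1000`: with 100 bp
#' reads in a 1 Gbp metagenome, 10 RPKG is exactly 1x coverage.
#'
#' @param rpkg RPKG value.
#' @param read_length_bp read length.
#' @param metagenome_gb metagenome size in Gbp.
#' @return depth (x).
#' @examples
#' rpkg_to_coverage(10, 100, 1.0)  # 1
#' @export
rpkg_to_coverage <- function(rpkg, read_length_bp, metagenome_gb) {
  stopifnot(all(read_length_bp > 0), all(metagenome_gb > 0))
  rpkg * metagenome_gb * read_length_bp / 1000
}

#' Genome x sample RPKG abundance matrix
#'
#' Runs recruitment for every genome against every sample and assembles the
#' complete long-form table plus the wide matrix. A missing recruitment run
#' is an error, never a silent zero.
#'
#' @param genomes named list of genome sequence sets.
#' @param samples named list of samples, each a list with `reads` (named
#'   character vector); total sample size is taken from `total_bp` when
#'   present, else from the reads themselves.
#' @param thresholds a [pipeline_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp,chunk_size passed to [recruit()].
#' @return list with `long` (data.frame: genome_id, sample_id, reads,
#'   genome_kb, metagenome_gb, rpkg) and `matrix` (genomes x samples RPKG).
#' @export
abundance_matrix <- function(genomes, samples,
                             thresholds = pipeline_thresholds(),
                             scheme = scoring_scheme(), min_seed_bp = 16L,
                             chunk_size = 500000L) {
  stopifnot(length(genomes) > 0, length(samples) > 0,
            !is.null(names(genomes)), !is.null(names(samples)))
  long <- NULL
  for (s in names(samples)) {
    smp <- samples[[s]]
    total_bp <- if (!is.null(smp$total_bp)) smp$total_bp
                else sum(nchar(smp$reads))
    for (g in names(genomes)) {
      rec <- recruit(smp$reads, genomes[[g]], thresholds, scheme,
                     min_seed_bp, chunk_size)
      row <- data.frame(
        genome_id = g, sample_id = s, reads = rec$reads_recruited,
        genome_kb = sum(nchar(as_sequences(genomes[[g]]))) / 1000,
        metagenome_gb = total_bp / 1e9, stringsAsFactors = FALSE)
      row$rpkg <- rpkg(row$reads, row$genome_kb, row$metagenome_gb)
      long <- if (is.null(long)) row else rbind(long, row)
    }
  }
  wide <- matrix(NA_real_, length(genomes), length(samples),
                 dimnames = list(names(genomes), names(samples)))
  for (i in seq_len(nrow(long)))
    wide[long$genome_id[i], long$sample_id[i]] <- long$rpkg[i]
  if (anyNA(wide)) stop("incomplete abundance matrix")
  list(long = long, matrix = wide)
}
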