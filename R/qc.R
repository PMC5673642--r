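# Per-bin quality and streamlining metrics: completeness / contamination
# from single-copy markers, contamination-corrected genome size estimation,
# GC, coding density, median intergenic spacer, CDS count.

#' Completeness and contamination from single-copy markers
#'
#' A simplified single-copy-marker estimator: completeness is the percent of
#' markers present at least once in the bin; contamination is the percent of
#' surplus copies, `100 * sum(max(0, copies - 1)) / n_markers`. (The
#' collocated-marker-set machinery of full lineage-aware tools is
#' deliberately not reproduced; downstream arithmetic consumes these two
#' percentages only.)
#'
#' @param marker_copies named integer vector: copies observed in the bin for
#'   each marker id present (markers absent from the vector count as 0).
#' @param markers character vector of the expected single-copy marker ids.
#' @return list with `completeness` and `contamination` (percent).
#' @examples
#' completeness_contamination(
#'   setNames(c(rep(1, 86), rep(2, 4)), paste0("m", 1:90)),
#'   paste0("m", 1:100))  # 90% complete, 4% contaminated
#' @export
completeness_contamination <- function(marker_copies, markers) {
  if (length(markers) == 0) stop("empty marker set")
  if (length(markers) < 20)
    warning("marker sets below 20 genes give unstable estimates")
  if (anyDuplicated(markers)) stop("marker ids must be unique")
  copies <- setNames(rep(0L, length(markers)), markers)
  present <- intersect(names(marker_copies), markers)
  copies[present] <- as.integer(marker_copies[present])
  list(completeness = 100 * sum(copies >= 1) / length(markers),
       contamination = 100 * sum(pmax(0L, copies - 1L)) / length(markers))
}

#' Count marker copies per bin from gene calls
#'
#' @param genes gene calls carrying a `marker_id` column (e.g. planted by
#'   [simulate_genome()], remapped to contigs), or a data.frame with
#'   `marker_id` and `contig_id`.
#' @param bin_contigs character vector of contig ids in the bin.
#' @return named integer vector of copies per marker id found in the bin.
#' @export
marker_copies_in_bin <- function(genes, bin_contigs) {
  stopifnot("marker_id" %in% names(genes))
  hit <- genes[genes$contig_id %in% bin_contigs &
                 !is.na(genes$marker_id), , drop = FALSE]
  if (nrow(hit) == 0) return(setNames(integer(0), character(0)))
  tab <- table(hit$marker_id)
  setNames(as.integer(tab), names(tab))
}

#' Contamination-corrected estimated genome size
#'
#' `est = length * (1 - contamination / 100) / (completeness / 100)`, in Mb,
#' reported at 2 decimals: the assembled length is first purged of the
#' contaminating fraction, then scaled up by the estimated completeness.
#'
#' @param length_mb assembled bin length in Mb.
#' @param completeness percent completeness (> 0).
#' @param contamination percent contamination.
#' @return estimated genome size in Mb (2 decimals).
#' @examples
#' estimated_genome_size(1.90, 85.58, 3.74)  # 2.14
#' estimated_genome_size(0.92, 50.16, 0)     # 1.83
#' @export
estimated_genome_size <- function(length_mb, completeness, contamination) {
  stopifnot(length_mb > 0, contamination >= 0, contamination <= 100)
  if (any(completeness <= 0)) stop("undefined for completeness = 0")
  round(length_mb * (1 - contamination / 100) / (completeness / 100), 2)
}

#' Coding density of a bin
#'
#' Percent of the total contig length covered by the union of coding
#' intervals (overlapping genes are not double-counted).
#'
#' @param contigs named character vector of the bin's contigs.
#' @param genes gene calls on those contigs (contig coordinates).
#' @return percent in `[0, 100]`.
#' @export
coding_density <- function(contigs, genes) {
  contigs <- as_sequences(contigs)
  total <- sum(nchar(contigs))
  genes <- genes[genes$contig_id %in% names(contigs), , drop = FALSE]
  if (nrow(genes) == 0) return(0)
  if (any(genes$end > nchar(contigs)[genes$contig_id]))
    stop("gene extends beyond contig end")
  coding <- 0
  for (cid in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == cid, ]
    red <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L,
                                            end = g$end))
    coding <- coding + sum(IRanges::width(red))
  }
  100 * coding / total
}

#' Median intergenic spacer of a bin
#'
#' Spacer between consecutive genes on the same contig (sorted by start) is
#' `max(0, next_start - prev_end)`; overlapping genes contribute 0. The
#' median is taken over all spacers in the bin (mean of the central pair for
#' even counts). With fewer than two genes on every contig the spacer is
#' undefined and `NA` is returned.
#'
#' @param genes gene calls (contig coordinates).
#' @return median spacer in bp, or `NA`.
#' @export
median_intergenic_spacer <- function(genes) {
  spacers <- numeric(0)
  for (cid in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    spacers <- c(spacers, pmax(0, g$start[-1] - g$end[-nrow(g)]))
  }
  if (length(spacers) == 0) return(NA_real_)
  median(spacers)
}

#' GC content
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. All-N input is an error.
#'
#' @param seqs character vector of sequences (pooled).
#' @return percent GC.
#' @export
gc_content <- function(seqs) {
  f <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(unname(seqs))),
    letters = c("A", "C", "G", "T")))
  if (sum(f) == 0) stop("no A/C/G/T base in input")
  100 * (f[["C"]] + f[["G"]]) / sum(f)
}

#' Summary record for one MAG
#'
#' Builds one summary-table row for a bin: CDS count, length (Mb), GC,
#' median intergenic spacer, coding density, completeness, contamination,
#' and contamination-corrected estimated genome size.
#'
#' @param bin_id bin identifier.
#' @param contigs named character vector of the bin's contigs.
#' @param genes gene calls on those contigs.
#' @param marker_copies named copies vector (see [marker_copies_in_bin()]).
#' @param markers expected single-copy marker ids.
#' @param origin,class_label optional provenance/taxon labels.
#' @return one-row `data.frame` (a MAG record).
#' @export
mag_record <- function(bin_id, contigs, genes, marker_copies, markers,
                       origin = NA_character_, class_label = NA_character_) {
  cc <- completeness_contamination(marker_copies, markers)
  length_mb <- sum(nchar(as_sequences(contigs))) / 1e6
  est <- if (cc$completeness > 0)
    estimated_genome_size(length_mb, cc$completeness, cc$contamination)
  else NA_real_
  data.frame(
    bin_id = bin_id,
    n_cds = nrow(genes),
    length_mb = round(length_mb, 2),
    gc = round(gc_content(contigs), 2),
    median_spacer_bp = median_intergenic_spacer(genes),
    coding_density = round(coding_density(contigs, genes), 0),
    completeness = round(cc$completeness, 2),
    contamination = round(cc$contamination, 2),
    est_size_mb = est,
    origin = origin, class_label = class_label,
    stringsAsFactors = FALSE)
}

#' MAG summary table for a set of bins
#'
#' @param bins data.frame with `contig_id` and `bin_id` (see
#'   [cluster_contigs()]).
#' @param contigs named character vector of all contigs.
#' @param genes gene calls (contig coordinates).
#' @param markers expected single-copy marker ids.
#' @param origin optional provenance label applied to all rows.
#' @return `data.frame` with one row per bin.
#' @export
mag_table <- function(bins, contigs, genes, markers,
                      origin = NA_character_) {
  contigs <- as_sequences(contigs)
  out <- NULL
  for (b in sort(unique(bins$bin_id[!is.na(bins$bin_id)]))) {
    cids <- bins$contig_id[!is.na(bins$bin_id) & bins$bin_id == b]
    g <- genes[genes$contig_id %in% cids, , drop = FALSE]
    mc <- if ("marker_id" %in% names(genes))
      marker_copies_in_bin(genes, cids) else integer(0)
    rec <- mag_record(b, contigs[cids], g, mc, markers, origin = origin)
    out <- if (is.null(out)) rec else rbind(out, rec)
  }
  out
}
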