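#' Pipeline thresholds
#'
#' All numeric cutoffs used by the pipeline, collected in one auditable
#' object. Defaults are the values used throughout the analysis:
#'
#' * `min_contig_bp` (10000): only contigs longer than this enter the
#'   taxonomy filter and binning (strict `>`).
#' * `vote_fraction` (0.60): a contig is assigned to the target phylum when
#'   more than this fraction of its genes hit that phylum (strict `>`).
#' * `derep_identity` (0.90): reference 16S sequences are dereplicated at
#'   this identity before candidate detection.
#' * `candidate_evalue` (1e-5): a read is a 16S candidate when its best hit
#'   against the dereplicated references has e-value strictly below this.
#' * `classify_identity` (0.80) and `classify_alnlen_bp` (90): a verified
#'   read is classified to its best hit's taxon when identity and alignment
#'   length meet these thresholds (both inclusive `>=`); otherwise discarded.
#' * `recruit_identity` (0.95, strict `>`), `recruit_alnlen_bp` (50,
#'   inclusive) and `recruit_evalue` (1e-5, inclusive `<=`): fragment
#'   recruitment filters.
#' * `ani_same_organism` (98.0): two bins with ANI strictly above this
#'   percent are treated as the same organism.
#' * `ani_fragment_bp` (1020): fragment length for ANI computation.
#'
#' @param ... named overrides for any of the defaults.
#' @return an object of class `pipeline_thresholds` (a named list).
#' @examples
#' th <- pipeline_thresholds()
#' th$recruit_identity
#' pipeline_thresholds(min_contig_bp = 5000)$min_contig_bp
#' @export
pipeline_thresholds <- function(...) {
  defaults <- list(
    min_contig_bp = 10000L,
    vote_fraction = 0.60,
    derep_identity = 0.90,
    candidate_evalue = 1e-5,
    classify_identity = 0.80,
    classify_alnlen_bp = 90L,
    recruit_identity = 0.95,
    recruit_alnlen_bp = 50L,
    recruit_evalue = 1e-5,
    ani_same_organism = 98.0,
    ani_fragment_bp = 1020L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad))
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  stopifnot(
    defaults$min_contig_bp > 0, defaults$vote_fraction >= 0,
    defaults$vote_fraction <= 1, defaults$derep_identity > 0,
    defaults$derep_identity <= 1, defaults$candidate_evalue > 0,
    defaults$classify_identity >= 0, defaults$classify_identity <= 1,
    defaults$classify_alnlen_bp > 0, defaults$recruit_identity >= 0,
    defaults$recruit_identity <= 1, defaults$recruit_alnlen_bp > 0,
    defaults$recruit_evalue > 0, defaults$ani_same_organism > 0,
    defaults$ani_same_organism <= 100, defaults$ani_fragment_bp > 0
  )
  structure(defaults, class = "pipeline_thresholds")
}

#' @export
print.pipeline_thresholds <- function(x, ...) {
  cat("Pipeline thresholds:\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], scientific = TRUE)))
  invisible(x)
}

#' Serialize thresholds as header comment lines
#'
#' Every report table written by the pipeline carries its thresholds as
#' `# key=value` header lines so results are auditable.
#'
#' @param thresholds a [pipeline_thresholds()] object.
#' @return character vector of `# key=value` lines.
#' @export
thresholds_header <- function(thresholds = pipeline_thresholds()) {
  stopifnot(inherits(thresholds, "pipeline_thresholds"))
  vapply(names(thresholds), function(nm) {
    sprintf("# %s=%s", nm, format(thresholds[[nm]], scientific = TRUE))
  }, character(1), USE.NAMES = FALSE)
}
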