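# Fragment-based average nucleotide identity and same-organism
# dereplication. Fragment scheme follows the classical ANI calculation:
# the query genome is cut into consecutive 1020 bp pieces, each searched
# against the other genome, and a fragment's best hit is retained when it
# covers at least 70% of the fragment at >= 30% identity; ANI is the mean
# identity of retained best hits.

#' Average nucleotide identity between two genomes
#'
#' One-directional ANI of `genome_a` against `genome_b`: `genome_a` is cut
#' into consecutive `ani_fragment_bp` fragments (trailing remainder
#' discarded), each aligned to `genome_b`; best hits with identity >= 30%
#' over >= 70% of the fragment length are retained. For a symmetric value
#' use [ani_symmetric()].
#'
#' @param genome_a,genome_b named character vectors of sequences (a genome
#'   may consist of several contigs).
#' @param thresholds a [pipeline_thresholds()] (`ani_fragment_bp` is used).
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp seed length passed to [search_hits()].
#' @return list of class `ani_result`: `ani` (percent; `NA` when no fragment
#'   is retained, signalling a non-homologous pair), `n_fragments_used`,
#'   `n_fragments_total`, `fraction_aligned`.
#' @export
ani <- function(genome_a, genome_b, thresholds = pipeline_thresholds(),
                scheme = scoring_scheme(), min_seed_bp = 14L) {
  genome_a <- as_sequences(genome_a)
  genome_b <- as_sequences(genome_b)
  frag_bp <- thresholds$ani_fragment_bp
  if (sum(nchar(genome_a)) < 2 * frag_bp ||
      sum(nchar(genome_b)) < 2 * frag_bp)
    stop("both genomes must be at least twice the fragment length")
  frags <- cut_fragments(genome_a, frag_bp)
  best <- best_hit_per_query(
    search_hits(frags, genome_b, scheme = scheme,
                min_seed_bp = min_seed_bp, best_only = TRUE))
  retained <- best[best$identity >= 30 &
                     best$aln_len >= 0.7 * frag_bp, , drop = FALSE]
  res <- list(
    ani = if (nrow(retained) > 0) mean(retained$identity) else NA_real_,
    n_fragments_used = nrow(retained),
    n_fragments_total = length(frags),
    fraction_aligned = nrow(retained) / length(frags))
  class(res) <- "ani_result"
  res
}

cut_fragments <- function(seqs, frag_bp) {
  out <- character(0)
  for (id in names(seqs)) {
    s <- seqs[[id]]
    n <- nchar(s) %/% frag_bp  # trailing fragment < frag_bp discarded
    if (n == 0) next
    starts <- (seq_len(n) - 1L) * frag_bp + 1L
    f <- substring(s, starts, starts + frag_bp - 1L)
    names(f) <- sprintf("%s|f%04d", id, seq_len(n))
    out <- c(out, f)
  }
  if (length(out) == 0) stop("no full-length fragment could be cut")
  out
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI: %s%% (%d/%d fragments retained, %.2f aligned)\n",
              ifelse(is.na(x$ani), "NA", sprintf("%.2f", x$ani)),
              x$n_fragments_used, x$n_fragments_total, x$fraction_aligned))
  invisible(x)
}

#' Symmetric ANI (maximum of the two directions)
#'
#' @inheritParams ani
#' @return numeric ANI percent (`NA` when neither direction retains a
#'   fragment).
#' @export
ani_symmetric <- function(genome_a, genome_b,
                          thresholds = pipeline_thresholds(),
                          scheme = scoring_scheme(), min_seed_bp = 14L) {
  ab <- ani(genome_a, genome_b, thresholds, scheme, min_seed_bp)$ani
  ba <- ani(genome_b, genome_a, thresholds, scheme, min_seed_bp)$ani
  if (is.na(ab) && is.na(ba)) return(NA_real_)
  max(ab, ba, na.rm = TRUE)
}

#' Pairwise ANI matrix for a set of bins
#'
#' @param bin_seqs named list of sequence sets, one per bin.
#' @inheritParams ani
#' @return square numeric matrix (percent; diagonal 100, `NA` for
#'   non-homologous pairs). Entry `[a, b]` is the symmetric
#'   (max-of-directions) ANI.
#' @export
ani_matrix <- function(bin_seqs, thresholds = pipeline_thresholds(),
                       scheme = scoring_scheme(), min_seed_bp = 14L) {
  n <- length(bin_seqs)
  ids <- names(bin_seqs)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- ani_symmetric(bin_seqs[[i]], bin_seqs[[j]], thresholds, scheme,
                         min_seed_bp)
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Dereplicate bins by the same-organism ANI rule
#'
#' Single-linkage grouping of bin pairs whose ANI is strictly above the
#' threshold (default 98%). Each group's representative is the bin with the
#' highest completeness, ties broken by larger assembled length, then
#' lexicographically smaller id.
#'
#' @param ani_mat square ANI matrix (see [ani_matrix()]).
#' @param threshold same-organism ANI percent (strict `>`).
#' @param completeness,length_bp optional named vectors used to pick
#'   representatives (defaults: all equal).
#' @return data.frame: bin_id, group_id, representative (logical).
#' @export
dereplicate_bins <- function(ani_mat, threshold = 98.0,
                             completeness = NULL, length_bp = NULL) {
  ids <- rownames(ani_mat)
  stopifnot(!is.null(ids), identical(ids, colnames(ani_mat)))
  if (is.null(completeness)) completeness <- setNames(rep(0, length(ids)), ids)
  if (is.null(length_bp)) length_bp <- setNames(rep(0, length(ids)), ids)
  # union-find single linkage
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j && !is.na(ani_mat[i, j]) && ani_mat[i, j] > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_along(ids), find, integer(1))
  groups <- match(root, sort(unique(root)))
  out <- data.frame(bin_id = ids, group_id = sprintf("org%02d", groups),
                    representative = FALSE, stringsAsFactors = FALSE)
  for (g in unique(out$group_id)) {
    members <- out$bin_id[out$group_id == g]
    ord <- order(-completeness[members], -length_bp[members], members)
    out$representative[out$bin_id == members[ord[1]]] <- TRUE
  }
  out
}
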