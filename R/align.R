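# Pairwise local alignment: the pipeline's internal replacement for an
# external nucleotide search tool. Exact k-mer seeding and banded affine-gap
# extension live in compiled code (src/align.cpp); significance follows
# Karlin-Altschul statistics, E = K * m * n * exp(-lambda * score).

#' Nucleotide scoring scheme
#'
#' Match/mismatch and affine gap costs (a gap of length `L` costs
#' `gap_open + L * gap_extend`), plus the Karlin-Altschul parameters:
#' `lambda` is solved from the scheme and base frequencies (see
#' [solve_lambda()]); `K` is kept as a fixed constant since its analytic
#' form is impractical for routine use.
#'
#' @param match match reward (positive integer).
#' @param mismatch mismatch penalty (negative integer).
#' @param gap_open,gap_extend affine gap costs (positive integers).
#' @param K Karlin-Altschul K constant.
#' @param base_freqs background base frequencies (A, C, G, T).
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()$lambda  # ~1.33 for +1/-2
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = 5L,
                           gap_extend = 2L, K = 0.621,
                           base_freqs = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0,
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-9)
  sc <- structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         K = K, base_freqs = base_freqs, lambda = NA_real_),
    class = "scoring_scheme")
  sc$lambda <- solve_lambda(sc, base_freqs)
  sc
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "scoring_scheme: match %+d, mismatch %+d, gap %d/%d, lambda %.4f, K %.3f\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

#' Solve the Karlin-Altschul lambda for a scoring scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i, j)) = 1` by bisection to an absolute
#' tolerance of 1e-6, where `s(i, j)` is `match` on the diagonal and
#' `mismatch` off it. A root exists iff the expected pair score is negative;
#' otherwise the scheme is invalid for local-alignment statistics.
#'
#' @param scheme a [scoring_scheme()] (only match/mismatch are used).
#' @param base_freqs background base frequencies (A, C, G, T).
#' @return the positive root `lambda`.
#' @examples
#' sc <- scoring_scheme()
#' solve_lambda(sc)                      # ~1.33
#' solve_lambda(scoring_scheme(mismatch = -1L))  # log(3)
#' @export
solve_lambda <- function(scheme, base_freqs = scheme$base_freqs) {
  stopifnot(inherits(scheme, "scoring_scheme") ||
              (is.list(scheme) && !is.null(scheme$match)))
  p <- base_freqs / sum(base_freqs)
  p_match <- sum(p^2)
  p_mismatch <- 1 - p_match
  escore <- p_match * scheme$match + p_mismatch * scheme$mismatch
  if (escore >= 0)
    stop("invalid scheme: expected pair score must be negative")
  f <- function(l) p_match * exp(l * scheme$match) +
    p_mismatch * exp(l * scheme$mismatch) - 1
  hi <- 1
  while (f(hi) <= 0) hi <- hi * 2
  # f(0) = 0 with negative slope (E[s] < 0), so the root is bracketed in
  # (0, hi]; bisect on the sign of f
  lo <- 0
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Search queries against a subject set
#'
#' Seed-and-extend local alignment of each query (both strands) against a
#' collection of subject sequences: exact `min_seed_bp`-mer seeds, diagonal
#' clustering, then banded affine-gap Smith-Waterman (band 16) with full
#' traceback. Per query, subject and strand the best local alignment is
#' reported. Identity is `matches / aln_len * 100`; the e-value is
#' `K * m * n * exp(-lambda * score)` with `m` the query length and `n` the
#' total subject length (database-size correction, as external search tools
#' apply it).
#'
#' Hits are sorted by query, then score descending, ties by
#' `(subject_id, s_start)` ascending. All coordinates are 0-based half-open;
#' subject coordinates are on the forward subject strand.
#'
#' @param queries,subjects named character vectors (or `DNAStringSet`).
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp exact seed length (>= 8).
#' @param band half-width of the alignment band around seed diagonals.
#' @param stride offset step between query seed positions (1 = every
#'   position; larger values trade seeding sensitivity for speed).
#' @param max_occ seeds occurring more often than this in the subject set
#'   are skipped (repeat masking).
#' @param max_clusters cap on seed clusters extended per query strand.
#' @param min_ungapped_score when positive, single-diagonal seed clusters
#'   whose ungapped X-drop extension scores below this skip the gapped
#'   extension entirely (a standard two-stage trigger; use only when weak
#'   hits are irrelevant, as in recruitment's high-identity filtering).
#' @param best_only return only the single best hit per query.
#' @return a `data.frame` with columns `query_id`, `subject_id`, `identity`,
#'   `aln_len`, `score`, `evalue`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `strand`.
#' @export
search_hits <- function(queries, subjects, scheme = scoring_scheme(),
                        min_seed_bp = 12L, band = 16L, stride = 1L,
                        max_occ = 256L, max_clusters = 32L,
                        min_ungapped_score = 0L, best_only = FALSE) {
  if (min_seed_bp < 8) stop("min_seed_bp must be >= 8")
  if (length(subjects) == 0 || length(queries) == 0)
    return(empty_hits())
  queries <- as_sequences(queries)
  subjects <- as_sequences(subjects)
  raw <- cpp_search(unname(queries), unname(subjects),
                    scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend, as.integer(min_seed_bp),
                    as.integer(band), as.integer(stride),
                    as.integer(max_occ), as.integer(max_clusters),
                    as.integer(min_ungapped_score), isTRUE(best_only))
  if (nrow(raw) == 0) return(empty_hits())
  n_db <- sum(nchar(subjects))
  m <- nchar(queries)[raw$query]
  hits <- data.frame(
    query_id = names(queries)[raw$query],
    subject_id = names(subjects)[raw$subject],
    identity = 100 * raw$matches / raw$aln_len,
    aln_len = raw$aln_len,
    score = raw$score,
    evalue = scheme$K * as.numeric(m) * as.numeric(n_db) *
      exp(-scheme$lambda * raw$score),
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    strand = raw$strand,
    stringsAsFactors = FALSE
  )
  ord <- order(match(hits$query_id, names(queries)), -hits$score,
               hits$subject_id, hits$s_start)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity = numeric(), aln_len = integer(), score = integer(),
             evalue = numeric(), q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Best hit per query
#'
#' Keeps at most one hit per query: the highest score wins, ties broken by
#' lexicographically smaller `subject_id`, then smaller `s_start`, then
#' forward strand — the deterministic order used for read counting.
#'
#' @param hits a hit table from [search_hits()].
#' @return a hit table with at most one row per `query_id`.
#' @export
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, -hits$score, hits$subject_id, hits$s_start,
               hits$strand)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits in BLAST-tabular-like TSV
#'
#' Columns: qseqid, sseqid, pident, length, score, evalue, qstart, qend,
#' sstart, send, strand (coordinates 0-based half-open, as used internally).
#'
#' @param hits a hit table from [search_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = formatC(hits$identity, format = "f", digits = 2),
    length = hits$aln_len, score = hits$score,
    evalue = formatC(hits$evalue, format = "e", digits = 2),
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end, strand = hits$strand,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
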