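# Taxonomy-guided composition/coverage binning: the >60% gene-vote phylum
# filter on >10 kb contigs, canonical tetranucleotide profiles, PCA, GC and
# coverage features, and k-medoids clustering into bins.

#' Canonical tetranucleotide classes
#'
#' The 136 equivalence classes of the 256 DNA 4-mers under reverse
#' complementation (120 complementary pairs + 16 palindromes), each named by
#' the lexicographically smaller member.
#'
#' @return character vector of 136 canonical 4-mers, sorted.
#' @export
canonical_tetranucleotides <- function() {
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases,
                             stringsAsFactors = FALSE)[, 4:1], 1, paste,
                 collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  sort(unique(pmin(kmers, rc)))
}

#' Tetranucleotide frequency profile of a sequence
#'
#' Slides a window of 4 over the sequence (windows containing `N` are
#' skipped), maps each 4-mer to its canonical strand-collapsed class, and
#' normalizes counts to frequencies. The profile is therefore exactly
#' invariant under reverse complementation — contig strand is arbitrary.
#'
#' @param seq a single sequence (character or `DNAString`).
#' @param warn_short warn below this length (composition is noisy on short
#'   contigs).
#' @return named numeric vector of length 136 summing to 1.
#' @export
tnf_profile <- function(seq, warn_short = 5000L) {
  if (methods::is(seq, "XString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) < 4) stop("sequence shorter than 4 bp")
  if (nchar(seq) < warn_short)
    warning("tetranucleotide profile of a sequence < ", warn_short,
            " bp is noisy")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(seq)), width = 4)
  canon <- canonical_map()
  collapsed <- tapply(counts[names(canon)], canon, sum)
  total <- sum(collapsed)
  if (total == 0) stop("no N-free 4-mer window in sequence")
  out <- as.numeric(collapsed) / total
  names(out) <- names(collapsed)
  out[canonical_tetranucleotides()]
}

# 4-mer -> canonical class lookup, memoised
canonical_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      kmers <- apply(expand.grid(bases, bases, bases, bases,
                                 stringsAsFactors = FALSE)[, 4:1], 1,
                     paste, collapse = "")
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(kmers)))
      cache <<- setNames(pmin(kmers, rc), kmers)
    }
    cache
  }
})

#' Tetranucleotide profiles for a contig set
#'
#' @param contigs named character vector of contigs.
#' @param warn_short see [tnf_profile()].
#' @return matrix (contigs x 136 canonical classes).
#' @export
tnf_profiles <- function(contigs, warn_short = 5000L) {
  contigs <- as_sequences(contigs)
  t(vapply(contigs, tnf_profile, numeric(136), warn_short = warn_short))
}

#' Taxonomic gene vote for a contig
#'
#' A contig passes the taxonomy filter when it is longer than
#' `min_contig_bp` (strict) and strictly more than `vote_fraction` of all
#' its genes — unlabeled genes count in the denominator — hit the target
#' taxon. With zero genes the vote is undefined (`NA`) and the contig fails.
#'
#' @param contig_len contig length in bp.
#' @param gene_taxa character vector of per-gene taxon labels on the contig
#'   (`NA` for genes without a hit).
#' @param target_taxon the phylum being binned.
#' @param thresholds a [pipeline_thresholds()].
#' @return list with `vote_fraction` and `passes`.
#' @export
taxonomy_vote <- function(contig_len, gene_taxa, target_taxon,
                          thresholds = pipeline_thresholds()) {
  n <- length(gene_taxa)
  if (n == 0)
    return(list(vote_fraction = NA_real_, passes = FALSE))
  vf <- sum(!is.na(gene_taxa) & gene_taxa == target_taxon) / n
  list(vote_fraction = vf,
       passes = contig_len > thresholds$min_contig_bp &&
         vf > thresholds$vote_fraction)
}

#' Principal component analysis of tetranucleotide profiles
#'
#' Columns are mean-centered; components are eigenvectors of the sample
#' covariance ordered by decreasing eigenvalue, with the sign convention
#' that each component's largest-magnitude loading is positive.
#'
#' @param profiles matrix (observations x features), e.g. from
#'   [tnf_profiles()].
#' @param n_components number of components to return.
#' @return list with `scores` (n x d), `loadings` (features x d,
#'   orthonormal), `variance_explained` (fractions of total variance, all
#'   components).
#' @export
tnf_pca <- function(profiles, n_components = 3L) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= n_components + 1)
  if (all(abs(sweep(profiles, 2, profiles[1, ])) < 1e-12))
    stop("degenerate: constant feature matrix")
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  d <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(d), drop = FALSE]
  scores <- pc$x[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = load, variance_explained = ve)
}

#' Per-contig coverage from recruited hits
#'
#' Depth = sum of best-hit alignment lengths on the contig divided by the
#' contig length; zero hits give 0.
#'
#' @param contig_len contig length in bp.
#' @param hits best-hit-per-read table restricted to this contig (needs an
#'   `aln_len` column).
#' @return numeric depth (x).
#' @export
coverage_estimate <- function(contig_len, hits) {
  stopifnot(contig_len > 0)
  if (is.null(hits) || nrow(hits) == 0) return(0)
  sum(as.numeric(hits$aln_len)) / contig_len
}

#' Assemble the per-contig feature table
#'
#' Computes, for every contig passing the taxonomy filter, the feature
#' vector used by [cluster_contigs()]: top PCA scores of the canonical
#' tetranucleotide profile, GC percent, and per-sample coverage.
#'
#' @param contigs named character vector of contigs.
#' @param genes gene calls with a `taxon` column (contig coordinates).
#' @param target_taxon phylum to bin.
#' @param coverages named list (per sample) of best-hit tables from
#'   [recruit()], or a precomputed contigs x samples coverage matrix.
#' @param thresholds a [pipeline_thresholds()].
#' @param n_components PCA components kept as features.
#' @return data.frame of class `contig_features`: contig_id, length,
#'   vote_fraction, passes_taxon_filter, gc, one `cov_*` column per sample
#'   and one `pc*` column per component (PCA computed on passing contigs
#'   only).
#' @export
contig_features <- function(contigs, genes, target_taxon, coverages = NULL,
                            thresholds = pipeline_thresholds(),
                            n_components = 3L) {
  contigs <- as_sequences(contigs)
  lens <- nchar(contigs)
  votes <- vapply(names(contigs), function(cid) {
    gt <- genes$taxon[genes$contig_id == cid]
    v <- taxonomy_vote(lens[[cid]], gt, target_taxon, thresholds)
    c(v$vote_fraction, as.numeric(v$passes))
  }, numeric(2))
  feat <- data.frame(
    contig_id = names(contigs), length = unname(lens),
    vote_fraction = votes[1, ], passes_taxon_filter = votes[2, ] > 0,
    gc = vapply(contigs, gc_content, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(coverages)) {
    if (is.matrix(coverages)) {
      for (s in colnames(coverages))
        feat[[paste0("cov_", s)]] <- coverages[feat$contig_id, s]
    } else {
      for (s in names(coverages)) {
        h <- coverages[[s]]
        feat[[paste0("cov_", s)]] <- vapply(feat$contig_id, function(cid) {
          coverage_estimate(lens[[cid]],
                            h[h$subject_id == cid, , drop = FALSE])
        }, numeric(1))
      }
    }
  }
  keep <- feat$passes_taxon_filter
  if (sum(keep) >= n_components + 1) {
    pca <- tnf_pca(tnf_profiles(contigs[keep]), n_components)
    for (j in seq_len(ncol(pca$scores)))
      feat[[paste0("pc", j)]] <- NA_real_
    for (j in seq_len(ncol(pca$scores)))
      feat[[paste0("pc", j)]][keep] <- pca$scores[, j]
  }
  class(feat) <- c("contig_features", class(feat))
  feat
}

#' Cluster filtered contigs into bins
#'
#' Feature vector per passing contig: top-3 PCA scores of the canonical
#' tetranucleotide profile, GC, and `log10(coverage + 0.1)` per sample.
#' GC and each coverage dimension are z-scored; the PCA block is scaled
#' jointly (all scores divided by the standard deviation of the first
#' component), preserving the eigenvalue weighting between components —
#' z-scoring each component separately would inflate noise-only trailing
#' components to unit variance and create spurious cluster structure.
#' Partitioning is k-medoids ([cluster::pam()])
#' for each `k` in `k_range`; `k` is chosen by maximum mean silhouette
#' width. When even the best silhouette is weak (below
#' `min_silhouette`), the contigs are returned as a single bin — the
#' trivial partition dominates when there is no cluster structure.
#' Contigs failing the taxonomy filter are never binned. The procedure is
#' deterministic given the seed.
#'
#' @param features a `contig_features` table (see [contig_features()]).
#' @param k_range candidate bin counts.
#' @param seed integer seed.
#' @param min_silhouette mean silhouette below which a single bin is
#'   returned.
#' @return data.frame: contig_id, bin_id (`NA` for unbinned contigs).
#' @export
cluster_contigs <- function(features, k_range = 2:8, seed = 1L,
                            min_silhouette = 0.25) {
  keep <- features$passes_taxon_filter
  ids <- features$contig_id[keep]
  if (length(ids) < 2) stop("need >= 2 contigs passing the taxon filter")
  pccols <- grep("^pc[0-9]+$", names(features), value = TRUE)
  cols <- c(pccols, "gc", grep("^cov_", names(features), value = TRUE))
  m <- as.matrix(features[keep, cols, drop = FALSE])
  covcols <- grep("^cov_", cols)
  m[, covcols] <- log10(m[, covcols] + 0.1)
  # PC block scaled jointly by sd(PC1); GC/coverage z-scored individually
  if (length(pccols) && stats::sd(m[, pccols[1]]) > 0)
    m[, pccols] <- m[, pccols] / stats::sd(m[, pccols[1]])
  other <- setdiff(cols, pccols)
  for (cc in other) {
    s <- stats::sd(m[, cc])
    m[, cc] <- if (s > 0) (m[, cc] - mean(m[, cc])) / s else 0
  }
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  if (ncol(m) == 0 || all(stats::dist(m) < 1e-12)) {
    warning("all contigs identical in feature space; single bin")
    return(data.frame(contig_id = features$contig_id,
                      bin_id = ifelse(keep, "bin1", NA_character_),
                      stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  ks <- k_range[k_range >= 2 & k_range <= length(ids) - 1]
  best_k <- NA_integer_; best_sil <- -Inf; best_fit <- NULL
  for (k in ks) {
    fit <- cluster::pam(m, k = k)
    sil <- fit$silinfo$avg.width
    if (sil > best_sil) { best_sil <- sil; best_k <- k; best_fit <- fit }
  }
  if (is.null(best_fit) || best_sil < min_silhouette) {
    assignment <- rep(1L, length(ids))
  } else {
    assignment <- best_fit$clustering
  }
  bins <- data.frame(contig_id = features$contig_id,
                     bin_id = NA_character_, stringsAsFactors = FALSE)
  bins$bin_id[keep] <- sprintf("bin%d", assignment)
  attr(bins, "silhouette") <- best_sil
  attr(bins, "k") <- length(unique(assignment))
  bins
}
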