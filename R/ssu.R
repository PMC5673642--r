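# Unassembled-read 16S rRNA screening cascade: reference dereplication,
# candidate detection by e-value, verification against a trained sequence
# profile, two-threshold classification, per-taxon relative abundance.

#' 16S reference database
#'
#' @param seqs named character vector of 16S/18S reference sequences.
#' @param taxa named character vector mapping record id to a high-level
#'   taxon; every record must be labeled.
#' @return object of class `reference_db`.
#' @export
reference_db <- function(seqs, taxa) {
  seqs <- as_sequences(seqs)
  if (!all(names(seqs) %in% names(taxa)))
    stop("every reference record must have a taxon label")
  taxa <- taxa[names(seqs)]
  lens <- nchar(seqs)
  if (any(lens < 800 | lens > 2000))
    warning(sum(lens < 800 | lens > 2000),
            " reference sequence(s) outside the typical 800-2000 bp range")
  structure(list(seqs = seqs, taxa = taxa), class = "reference_db")
}

#' Generate a synthetic labeled 16S reference set
#'
#' All references descend from one ancestral sequence emitted by a strongly
#' skewed order-2 Markov chain (so the set has genuine trigram structure for
#' the verification profile to learn); each taxon is an independently
#' diverged copy of the ancestor, and each record an independently diverged
#' copy of its taxon ancestor with small random end trims. With the default
#' divergences, records of one taxon are ~94% identical to each other and
#' ~78% identical across taxa, mimicking within/between-phylum 16S
#' similarity at the scale the screening thresholds assume. Synthetic
#' stand-in for a curated rRNA reference database.
#'
#' @param n_taxa number of high-level taxa.
#' @param n_per_taxon records per taxon.
#' @param length_bp ancestral sequence length.
#' @param seed integer seed.
#' @param taxa optional taxon names (first is conventionally the target
#'   phylum).
#' @param taxon_divergence per-site divergence of each taxon ancestor.
#' @param within_divergence per-site divergence of records within a taxon.
#' @return a [reference_db()].
#' @export
synthetic_ssu_refs <- function(n_taxa = 6L, n_per_taxon = 10L,
                               length_bp = 1500L, seed = 1L, taxa = NULL,
                               taxon_divergence = 0.12,
                               within_divergence = 0.03) {
  stopifnot(n_taxa >= 1, n_per_taxon >= 1)
  if (is.null(taxa)) {
    pool <- c("Verrucomicrobia", "Proteobacteria", "Actinobacteria",
              "Bacteroidetes", "Cyanobacteria", "Planctomycetes",
              "Firmicutes", "Chloroflexi", "Acidobacteria", "Chlorobi")
    taxa <- if (n_taxa <= length(pool)) pool[seq_len(n_taxa)]
            else c(pool, sprintf("Taxon%02d", seq_len(n_taxa - length(pool))))
  }
  stopifnot(length(taxa) == n_taxa)
  set.seed(as.integer(seed))
  mt <- markov_transitions(0.55, composition_seed = as.integer(seed),
                           concentration = 0.3)
  set.seed(as.integer(seed) + 1L)  # transitions consumed the seeded stream
  anc <- cpp_markov_chain(as.integer(length_bp), mt$trans, mt$init)
  seqs <- character(0); labels <- character(0)
  for (t in seq_len(n_taxa)) {
    tanc <- cpp_mutate(anc, taxon_divergence)
    for (r in seq_len(n_per_taxon)) {
      rec <- cpp_mutate(tanc, within_divergence)
      trim5 <- sample.int(40L, 1L) - 1L
      trim3 <- sample.int(40L, 1L) - 1L
      rec <- substr(rec, trim5 + 1L, nchar(rec) - trim3)
      seqs <- c(seqs, rec)
      labels <- c(labels, taxa[t])
    }
  }
  ids <- sprintf("ref_%s_%02d", rep(taxa, each = n_per_taxon),
                 rep(seq_len(n_per_taxon), n_taxa))
  names(seqs) <- ids
  reference_db(seqs, setNames(labels, ids))
}

#' Dereplicate a 16S reference database
#'
#' Greedy longest-first centroid clustering: records are processed in order
#' of decreasing length; a record joins the earliest-created centroid it
#' matches at `>= identity` over at least 80% of its own length, otherwise
#' it founds a new centroid. Centroids plus members partition the input.
#'
#' @param db a [reference_db()].
#' @param identity clustering identity fraction (default 0.90).
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp seed length passed to [search_hits()].
#' @return object of class `clustered_db`: `centroids` (a [reference_db()]
#'   restricted to centroid records) and `members` (named character vector
#'   mapping every input record id to its centroid id).
#' @export
dereplicate_references <- function(db, identity = 0.90,
                                   scheme = scoring_scheme(),
                                   min_seed_bp = 12L) {
  stopifnot(inherits(db, "reference_db"), length(db$seqs) > 0)
  ord <- order(-nchar(db$seqs))
  centroid_ids <- character(0)
  members <- character(0)
  for (i in ord) {
    id <- names(db$seqs)[i]
    rec <- db$seqs[i]
    assigned <- NA_character_
    if (length(centroid_ids) > 0) {
      hits <- search_hits(rec, db$seqs[centroid_ids], scheme = scheme,
                          min_seed_bp = min_seed_bp)
      ok <- hits[hits$identity >= identity * 100 &
                   hits$aln_len >= 0.8 * nchar(rec), , drop = FALSE]
      if (nrow(ok) > 0) {
        # earliest-created centroid wins
        pos <- match(ok$subject_id, centroid_ids)
        assigned <- centroid_ids[min(pos)]
      }
    }
    if (is.na(assigned)) {
      centroid_ids <- c(centroid_ids, id)
      assigned <- id
    }
    members[id] <- assigned
  }
  structure(list(
    centroids = reference_db(db$seqs[centroid_ids],
                             db$taxa[centroid_ids]),
    members = members), class = "clustered_db")
}

#' Detect candidate 16S reads
#'
#' A read is a candidate 16S fragment iff its best hit against the
#' dereplicated reference set has e-value strictly below `evalue_max`.
#'
#' @param reads named character vector of reads (>= 50 bp).
#' @param cdb a `clustered_db` from [dereplicate_references()].
#' @param evalue_max candidacy e-value cutoff (strict `<`).
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp seed length passed to [search_hits()].
#' @return character vector of candidate read ids.
#' @export
detect_candidates <- function(reads, cdb, evalue_max = 1e-5,
                              scheme = scoring_scheme(),
                              min_seed_bp = 12L) {
  stopifnot(inherits(cdb, "clustered_db"))
  if (length(reads) == 0) return(character(0))
  if (any(nchar(reads) < 50)) stop("reads must be >= 50 bp")
  hits <- search_hits(reads, cdb$centroids$seqs, scheme = scheme,
                      min_seed_bp = min_seed_bp, best_only = TRUE)
  hits$query_id[hits$evalue < evalue_max]
}

#' Train the 16S verification profile
#'
#' Markov log-odds sequence model of order `order` (default 4): the
#' probability of each base given the preceding `order` bases is estimated
#' from the reference set (with add-one pseudocounts) against a
#' base-composition background. A candidate's score is the mean
#' per-position log-odds; the acceptance threshold is calibrated on
#' dinucleotide-shuffled copies of reference fragments so that at most
#' `fpr` of shuffled sequences pass. This plays the role of the
#' covariance-model alignment step of rRNA screening pipelines: a
#' sequence-level true/false 16S discriminator with a construction-time
#' false-positive guarantee.
#'
#' @param db a [reference_db()] with at least `min_refs` records.
#' @param order Markov order (context length in bases).
#' @param fpr calibrated false-positive rate on shuffled fragments.
#' @param fragment_bp length of calibration fragments (read-sized).
#' @param n_shuffle number of shuffled calibration fragments.
#' @param seed integer seed for calibration.
#' @param min_refs minimum training set size.
#' @return object of class `ssu_profile` with the log-odds tables and the
#'   calibrated `threshold`.
#' @export
train_ssu_profile <- function(db, order = 4L, fpr = 0.01, fragment_bp = 100L,
                              n_shuffle = 1000L, seed = 1L, min_refs = 50L) {
  stopifnot(inherits(db, "reference_db"), order >= 1, order <= 6)
  if (length(db$seqs) < min_refs)
    stop("too few references to train (need >= ", min_refs, ")")
  nctx <- 4L^order
  counts <- matrix(1, nctx, 4)  # contexts x next base, add-one pseudocounts
  base <- rep(1, 4)
  for (s in db$seqs) {
    code <- match(utf8ToInt(s), utf8ToInt("ACGT")) - 1L  # NA for N
    n <- length(code)
    if (n <= order) next
    base <- base + tabulate(code + 1L, 4L)
    cn <- context_codes(code, order)
    ok <- !is.na(cn$ctx) & !is.na(cn$nxt)
    tab <- tabulate(cn$ctx[ok] * 4L + cn$nxt[ok] + 1L, nctx * 4L)
    counts <- counts + matrix(tab, nctx, 4, byrow = TRUE)
  }
  trans <- counts / rowSums(counts)
  bg <- base / sum(base)
  lo <- log(trans) - matrix(log(bg), nctx, 4, byrow = TRUE)
  prof <- structure(list(log_odds = lo, order = as.integer(order),
                         background = bg, threshold = NA_real_),
                    class = "ssu_profile")
  # calibration on dinucleotide-shuffled read-sized fragments
  set.seed(as.integer(seed))
  pool <- db$seqs[nchar(db$seqs) >= fragment_bp]
  src <- sample(seq_along(pool), n_shuffle, replace = TRUE)
  scores <- vapply(src, function(i) {
    s <- pool[[i]]
    a <- sample.int(nchar(s) - fragment_bp + 1L, 1L)
    frag <- substr(s, a, a + fragment_bp - 1L)
    ssu_profile_score(prof, dinucleotide_shuffle(frag))
  }, numeric(1))
  prof$threshold <- as.numeric(quantile(scores, 1 - fpr, names = FALSE))
  prof
}

#' Score a sequence under a 16S verification profile
#'
#' Mean per-position log-odds under the profile's Markov model; positions
#' involving `N` are skipped.
#'
#' @param profile an `ssu_profile` from [train_ssu_profile()].
#' @param seq a single sequence (character).
#' @return numeric score (nats per position).
#' @export
ssu_profile_score <- function(profile, seq) {
  code <- match(utf8ToInt(toupper(seq)), utf8ToInt("ACGT")) - 1L
  if (length(code) <= profile$order) return(-Inf)
  cn <- context_codes(code, profile$order)
  ok <- !is.na(cn$ctx) & !is.na(cn$nxt)
  if (!any(ok)) return(-Inf)
  mean(profile$log_odds[cbind(cn$ctx[ok] + 1L, cn$nxt[ok] + 1L)])
}

# (context, next-base) integer codes for a Markov model of a given order;
# NA propagates through positions containing non-ACGT bases
context_codes <- function(code, order) {
  n <- length(code)
  ctx <- rep(0L, n - order)
  for (d in seq_len(order))
    ctx <- ctx * 4L + code[d:(n - order - 1L + d)]
  list(ctx = ctx, nxt = code[(order + 1L):n])
}

#' Dinucleotide-preserving shuffle
#'
#' Random walk over the sequence's dinucleotide transition multiset (each
#' observed transition used exactly once), restarted until a complete
#' Eulerian walk is found, so the shuffled sequence has exactly the original
#' dinucleotide composition.
#'
#' @param seq a single sequence (character).
#' @param max_tries walk restarts before giving up.
#' @return shuffled sequence (character).
#' @export
dinucleotide_shuffle <- function(seq, max_tries = 200L) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  alpha <- unique(chars)
  from <- chars[-n]; to <- chars[-1]
  edges <- split(to, factor(from, levels = alpha))
  n_edges <- n - 1L
  for (try in seq_len(max_tries)) {
    avail <- lapply(edges, function(e) sample(e))  # shuffled adjacency
    used <- setNames(integer(length(alpha)), alpha)
    walk <- character(n); walk[1] <- chars[1]
    cur <- chars[1]; ok <- TRUE
    for (i in seq_len(n_edges)) {
      u <- used[cur] + 1L
      if (u > length(avail[[cur]])) { ok <- FALSE; break }
      nxt <- avail[[cur]][u]
      used[cur] <- u
      walk[i + 1L] <- nxt
      cur <- nxt
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  # extremely rare for DNA; fall back to the original order
  seq
}

#' Verify candidate 16S reads against a profile
#'
#' @param candidates named character vector of candidate reads.
#' @param profile an `ssu_profile` from [train_ssu_profile()].
#' @return character vector of verified read ids.
#' @export
verify_ssu <- function(candidates, profile) {
  stopifnot(inherits(profile, "ssu_profile"), !is.na(profile$threshold))
  if (length(candidates) == 0) return(character(0))
  scores <- vapply(candidates, function(s) ssu_profile_score(profile, s),
                   numeric(1))
  names(candidates)[scores >= profile$threshold]
}

#' Classify verified reads against the full reference database
#'
#' Each verified read is compared to the entire (non-dereplicated)
#' reference set; it is classified to its best hit's taxon iff identity is
#' `>= id_min` and alignment length `>= len_min` bp (both inclusive), and
#' discarded otherwise.
#'
#' @param verified named character vector of verified reads.
#' @param full_db the full [reference_db()].
#' @param id_min identity fraction threshold (inclusive).
#' @param len_min alignment length threshold in bp (inclusive).
#' @param scheme a [scoring_scheme()].
#' @param min_seed_bp seed length passed to [search_hits()].
#' @return data.frame: read_id, status (`classified` / `discarded`), taxon
#'   (`NA` unless classified), identity, aln_len.
#' @export
classify_reads <- function(verified, full_db, id_min = 0.80, len_min = 90L,
                           scheme = scoring_scheme(), min_seed_bp = 12L) {
  stopifnot(inherits(full_db, "reference_db"))
  if (length(verified) == 0)
    return(data.frame(read_id = character(), status = character(),
                      taxon = character(), identity = numeric(),
                      aln_len = integer(), stringsAsFactors = FALSE))
  best <- best_hit_per_query(
    search_hits(verified, full_db$seqs, scheme = scheme,
                min_seed_bp = min_seed_bp, best_only = TRUE))
  res <- data.frame(read_id = names(verified), status = "discarded",
                    taxon = NA_character_, identity = NA_real_,
                    aln_len = NA_integer_, stringsAsFactors = FALSE)
  m <- match(best$query_id, res$read_id)
  res$identity[m] <- best$identity
  res$aln_len[m] <- best$aln_len
  pass <- best$identity >= id_min * 100 & best$aln_len >= len_min
  res$status[m[pass]] <- "classified"
  res$taxon[m[pass]] <- unname(full_db$taxa[best$subject_id[pass]])
  res
}

#' Screen a read set for 16S fragments end to end
#'
#' Runs the full cascade — candidacy against the dereplicated references,
#' profile verification, two-threshold classification — and returns the
#' per-read status table. Statuses partition the input: `not_candidate`,
#' `candidate_rejected` (failed verification), `classified`, `discarded`
#' (verified but below the classification thresholds).
#'
#' @param reads named character vector of reads.
#' @param db the full [reference_db()].
#' @param cdb optional precomputed [dereplicate_references()] result.
#' @param profile optional precomputed [train_ssu_profile()] result.
#' @param thresholds a [pipeline_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @return data.frame: read_id, status, taxon, identity, aln_len.
#' @export
screen_ssu_reads <- function(reads, db, cdb = NULL, profile = NULL,
                             thresholds = pipeline_thresholds(),
                             scheme = scoring_scheme()) {
  if (is.null(cdb))
    cdb <- dereplicate_references(db, identity = thresholds$derep_identity,
                                  scheme = scheme)
  if (is.null(profile)) profile <- train_ssu_profile(db)
  cand_ids <- detect_candidates(reads, cdb,
                                evalue_max = thresholds$candidate_evalue,
                                scheme = scheme)
  verified_ids <- verify_ssu(reads[cand_ids], profile)
  cls <- classify_reads(reads[verified_ids], db,
                        id_min = thresholds$classify_identity,
                        len_min = thresholds$classify_alnlen_bp,
                        scheme = scheme)
  res <- data.frame(read_id = names(reads), status = "not_candidate",
                    taxon = NA_character_, identity = NA_real_,
                    aln_len = NA_integer_, stringsAsFactors = FALSE)
  res$status[res$read_id %in% cand_ids] <- "candidate_rejected"
  m <- match(cls$read_id, res$read_id)
  res$status[m] <- cls$status
  res$taxon[m] <- cls$taxon
  res$identity[m] <- cls$identity
  res$aln_len[m] <- cls$aln_len
  res
}

#' Per-taxon relative abundance of classified reads
#'
#' @param classified a status table from [screen_ssu_reads()] or
#'   [classify_reads()].
#' @return data.frame: taxon, reads, percent (sums to 100).
#' @export
taxon_relative_abundance <- function(classified) {
  cls <- classified[classified$status == "classified", , drop = FALSE]
  if (nrow(cls) == 0) stop("no classified reads")
  tab <- sort(table(cls$taxon), decreasing = TRUE)
  data.frame(taxon = names(tab), reads = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
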