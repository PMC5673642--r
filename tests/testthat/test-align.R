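test_that("lambda solves the Karlin-Altschul equation", {
  sc <- scoring_scheme()  # +1 / -2
  # independent oracle: root of the stated equation by uniroot
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  oracle <- stats::uniroot(f, c(0.5, 3), tol = 1e-9)$root
  expect_lt(abs(sc$lambda - oracle), 1e-5)
  expect_lt(abs(sc$lambda - 1.33), 0.01)
  # +1/-1: expected score -0.5 < 0, closed-form root exp(lambda) = 3
  expect_lt(abs(solve_lambda(scoring_scheme(mismatch = -1L)) - log(3)), 1e-5)
  # non-negative expected pair score has no positive root
  expect_error(solve_lambda(list(match = 1L, mismatch = 0L),
                            base_freqs = rep(0.25, 4)),
               "invalid scheme")
})

test_that("lambda strictly decreases as the match reward grows", {
  lams <- vapply(1:4, function(m)
    solve_lambda(scoring_scheme(match = m, mismatch = -2L)), numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("self-alignment returns a full-length perfect hit", {
  set.seed(42)
  for (len in c(60L, 100L, 150L)) {
    q <- setNames(random_dna(len), "q")
    h <- search_hits(q, q, min_seed_bp = 12L)
    top <- h[1, ]
    expect_equal(top$identity, 100)
    expect_identical(top$aln_len, len)
    expect_identical(top$q_start, 0L)
    expect_identical(top$q_end, len)
    expect_identical(top$strand, "+")
  }
})

test_that("the top score is strand-symmetric", {
  set.seed(43)
  for (i in 1:10) {
    s <- setNames(random_dna(300), "s")
    q <- setNames(substr(s, 100, 199), "q")
    qrc <- setNames(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(unname(q)))), "q")
    h1 <- search_hits(q, s, min_seed_bp = 10L)
    h2 <- search_hits(qrc, s, min_seed_bp = 10L)
    expect_identical(max(h1$score), max(h2$score))
    expect_identical(h2$strand[1], "-")
  }
})

test_that("e-value is monotone decreasing in score at fixed m, n", {
  sc <- scoring_scheme()
  ev <- function(score) sc$K * 100 * 1e5 * exp(-sc$lambda * score)
  expect_true(all(diff(ev(seq(10, 100, by = 5))) < 0))
})

test_that("top-hit score matches the exhaustive DP oracle on random pairs", {
  set.seed(7)
  n <- 120; agree <- 0
  for (i in seq_len(n)) {
    qlen <- sample(60:200, 1)
    q <- random_dna(qlen)
    a <- sort(sample(qlen, 2))
    while (a[2] - a[1] < 30) a <- sort(sample(qlen, 2))
    core <- mutate_genome(setNames(substr(q, a[1], a[2]), "c"),
                          stats::runif(1, 0, 0.15),
                          seed = sample.int(1e6, 1))
    # 0-2 single-base indels
    core <- unname(core)
    for (k in seq_len(sample(0:2, 1))) {
      p <- sample(nchar(core) - 2, 1)
      core <- if (stats::runif(1) < 0.5)
        paste0(substr(core, 1, p), substr(core, p + 2, nchar(core)))
      else paste0(substr(core, 1, p), random_dna(1),
                  substr(core, p + 1, nchar(core)))
    }
    s <- paste0(random_dna(sample(0:40, 1)), core,
                random_dna(sample(0:40, 1)))
    if (nchar(s) > 200) s <- substr(s, 1, 200)
    oracle <- sw_oracle_score(q, s)
    h <- search_hits(setNames(q, "q"), setNames(s, "s"), min_seed_bp = 8L)
    mine <- if (nrow(h)) max(c(h$score[h$strand == "+"], 0)) else 0
    if (mine == oracle) agree <- agree + 1
  }
  expect_gte(agree / n, 0.95)
})

test_that("best_hit_per_query applies the deterministic tie rules", {
  hits <- data.frame(
    query_id = c("r1", "r1", "r2"),
    subject_id = c("sB", "sA", "sC"),
    identity = c(99, 98, 97), aln_len = c(100L, 100L, 90L),
    score = c(80L, 80L, 50L), evalue = c(1e-30, 1e-30, 1e-10),
    q_start = 0L, q_end = 100L, s_start = c(5L, 9L, 0L), s_end = 100L,
    strand = "+", stringsAsFactors = FALSE)
  best <- best_hit_per_query(hits)
  expect_identical(nrow(best), 2L)
  # equal scores: lexicographically smaller subject wins
  expect_identical(best$subject_id[best$query_id == "r1"], "sA")
  expect_identical(best_hit_per_query(hits[0, ]), hits[0, ])
  one <- best_hit_per_query(hits[3, ])
  expect_identical(one$subject_id, "sC")
})

test_that("empty subject set and short seeds are handled", {
  expect_identical(nrow(search_hits(setNames("ACGTACGTACGT", "q"),
                                    character(0))), 0L)
  expect_error(search_hits(setNames("ACGT", "q"), setNames("ACGT", "s"),
                           min_seed_bp = 4L), ">= 8")
})

test_that("hit export writes the tabular format", {
  q <- setNames(random_dna(100), "readA")
  h <- search_hits(q, setNames(unname(q), "subjB"), min_seed_bp = 12L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(h, f)
  back <- read.delim(f)
  expect_identical(names(back)[1:4], c("qseqid", "sseqid", "pident", "length"))
  expect_identical(back$sseqid[1], "subjB")
})
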