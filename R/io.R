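# Sequence and table I/O.
#
# Internally every sequence set is a named character vector over
# {A,C,G,T,N} (upper case); ids are the names, with an optional
# "description" attribute. All coordinates inside the package are 0-based
# half-open; the GFF3 readers/writers are the single conversion site to the
# 1-based inclusive convention of that format.

#' Coerce to an internal sequence set
#'
#' Accepts a named character vector or a [Biostrings::DNAStringSet] /
#' `BStringSet` and returns the internal representation: an upper-cased
#' named character vector restricted to the `{A,C,G,T,N}` alphabet.
#'
#' @param x sequences (named character vector or an `XStringSet`).
#' @param validate check alphabet, non-empty sequences and unique ids.
#' @return named character vector of sequences.
#' @export
as_sequences <- function(x, validate = TRUE) {
  if (methods::is(x, "XStringSet")) {
    ids <- names(x)
    x <- as.character(x)
    names(x) <- ids
  }
  if (!is.character(x)) stop("sequences must be a named character vector")
  x[] <- toupper(x)
  if (validate) validate_sequences(x)
  x
}

validate_sequences <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must have an id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1])
  if (any(grepl("[[:space:]]", names(seqs))))
    stop("sequence ids must not contain whitespace")
  if (any(nchar(seqs) == 0))
    stop("empty sequence: ", names(seqs)[nchar(seqs) == 0][1])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid residue '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  invisible(seqs)
}

#' Read sequences from FASTA or FASTQ
#'
#' Order is preserved, residues are upper-cased and validated against the
#' `{A,C,G,T,N}` alphabet (any other letter is rejected with its position),
#' and duplicate ids are an error. Gzipped files are read transparently.
#'
#' @param path path to a FASTA or FASTQ file (optionally gzipped).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return named character vector of sequences; descriptions (text after the
#'   first whitespace of each header) in `attr(, "description")`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a contig", "ACGT", ">s2", "ggtt"), f)
#' read_sequences(f)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  validate_sequences(seqs)
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or `DNAStringSet`).
#' @param path output path (`.gz` suffix writes gzipped).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  seqs <- as_sequences(seqs)
  desc <- attr(seqs, "description")
  headers <- names(seqs)
  if (!is.null(desc)) {
    has <- nzchar(desc)
    headers[has] <- paste(headers[has], desc[has])
  }
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Construct a gene call table
#'
#' Gene coordinates are 0-based half-open on their contig. Invariants
#' (`0 <= start < end`, unique gene ids, strand in `{+,-}`) are enforced.
#'
#' @param contig_id,start,end,strand,gene_id,taxon vectors of equal length;
#'   `taxon` may be `NA` for genes without a taxonomic label.
#' @return a `data.frame` with one row per gene.
#' @export
gene_calls <- function(contig_id, start, end, strand, gene_id,
                       taxon = NA_character_) {
  df <- data.frame(
    contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), gene_id = as.character(gene_id),
    taxon = as.character(taxon),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 0)) stop("negative gene start")
  if (any(df$end <= df$start)) stop("gene end must exceed start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand required ('+' or '-')")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  df
}

#' Read gene calls from GFF3
#'
#' Imports CDS features and converts the 1-based inclusive GFF coordinates
#' to the package's 0-based half-open convention (GFF `start=1,end=100`
#' becomes `[0,100)`). Features without a strand are an error; a `taxon`
#' attribute is carried through when present.
#'
#' @param path path to a GFF3 file.
#' @return a gene call `data.frame` (see [gene_calls()]).
#' @export
read_gene_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% colnames(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("strand required for all CDS features")
  ids <- if ("ID" %in% colnames(S4Vectors::mcols(gr))) as.character(gr$ID)
         else NULL
  if (is.null(ids) || anyNA(ids)) stop("every CDS needs an ID attribute")
  taxon <- if ("taxon" %in% colnames(S4Vectors::mcols(gr)))
    as.character(gr$taxon) else NA_character_
  gene_calls(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # the single 1-based -> 0-based site
    end = GenomicRanges::end(gr),
    strand = strand, gene_id = ids, taxon = taxon
  )
}

#' Write gene calls to GFF3
#'
#' @param genes a gene call `data.frame` (see [gene_calls()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_calls <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  if (!all(is.na(genes$taxon))) gr$taxon <- genes$taxon
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a report table as TSV
#'
#' Tab-separated, UTF-8, `.` decimal separator, with an optional threshold
#' header (`# key=value` comment lines). Floating point columns are printed
#' at a fixed precision so round-trips are exact at the printed precision.
#'
#' @param rows a `data.frame` (may have zero rows).
#' @param path output path.
#' @param thresholds optional [pipeline_thresholds()] echoed in the header.
#' @param digits decimal places for numeric (double) columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, thresholds = NULL, digits = 2) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], format = "f",
                                                digits = digits)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(thresholds)) writeLines(thresholds_header(thresholds), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input path; `# ` comment headers are skipped.
#' @return a `data.frame`.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}
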