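#' Parse a tabular similarity hit table
#'
#' Reads the 12-column tab-separated hit format produced by all-against-all
#' local similarity searches (the classic \code{outfmt 6} dialect:
#' \code{qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore}), or the extended dialect with trailing \code{qlen slen}
#' columns from which query coverage is computed as
#' \code{100 * length / qlen}.
#'
#' @param input path to a file, or a character vector of lines.
#' @param dialect \code{"outfmt6_qlen"} (14 columns, coverage computable) or
#'   \code{"outfmt6"} (12 columns; query coverage is \code{NA} and must be
#'   supplied downstream before coverage filtering).
#' @return a \code{data.frame} hit table with columns \code{query_id,
#'   subject_id, identity_pct, aln_len, mismatches, gap_opens, q_start,
#'   q_end, s_start, s_end, evalue, score, query_coverage_pct}.  Row order
#'   follows line order.
#' @examples
#' lines <- "q1\ts1\t98.5\t100\t1\t0\t1\t100\t5\t104\t1e-50\t180\t100\t200"
#' parse_hit_table(lines)
#' @export
parse_hit_table <- function(input, dialect = c("outfmt6_qlen", "outfmt6")) {
  dialect <- match.arg(dialect)
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  ncol_exp <- if (dialect == "outfmt6") 12L else 14L
  out <- vector("list", length(idx))
  num_cols <- c(3:12, if (dialect == "outfmt6_qlen") 13:14)
  for (k in seq_along(idx)) {
    ln <- idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol_exp)
      stopf("hit table line %d: expected %d tab-separated columns, got %d",
            ln, ncol_exp, length(f))
    v <- suppressWarnings(as.numeric(f[num_cols]))
    if (anyNA(v))
      stopf("hit table line %d: non-numeric value in column %d",
            ln, num_cols[which(is.na(v))[1L]])
    out[[k]] <- c(f[1L], f[2L], v)
  }
  if (length(out) == 0L) return(empty_hit_table())
  m <- do.call(rbind, out)
  h <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    identity_pct = as.numeric(m[, 3L]), aln_len = as.numeric(m[, 4L]),
    mismatches = as.numeric(m[, 5L]), gap_opens = as.numeric(m[, 6L]),
    q_start = as.numeric(m[, 7L]), q_end = as.numeric(m[, 8L]),
    s_start = as.numeric(m[, 9L]), s_end = as.numeric(m[, 10L]),
    evalue = as.numeric(m[, 11L]), score = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  h$query_coverage_pct <- if (dialect == "outfmt6_qlen")
    100 * h$aln_len / as.numeric(m[, 13L]) else NA_real_
  if (any(h$evalue < 0)) stopf("negative e-value in hit table")
  h
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aln_len = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(),
             evalue = numeric(), score = numeric(),
             query_coverage_pct = numeric(), stringsAsFactors = FALSE)
}

#' Filter a hit table on e-value, identity and query coverage
#'
#' Retains hits with \code{evalue <= max_evalue}, \code{identity_pct >=
#' min_identity} (at least) and \code{query_coverage_pct > min_coverage}
#' (strictly above).  Row order is preserved; the filter is idempotent.
#'
#' @param hits hit table from [parse_hit_table()] or
#'   [local_similarity_search()].
#' @param max_evalue inclusive e-value ceiling (default \code{1e-10}).
#' @param min_identity inclusive percent-identity floor (default 30).
#' @param min_coverage exclusive query-coverage floor in percent (default
#'   70); coverage is of the query only.
#' @return the filtered hit table.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_identity = 30,
                        min_coverage = 70) {
  stopifnot(is.finite(max_evalue), is.finite(min_identity),
            is.finite(min_coverage))
  if (nrow(hits) == 0L) return(hits)
  if (anyNA(hits$query_coverage_pct))
    stopf(paste("query coverage is NA for some hits; parse with the qlen",
                "dialect or compute coverage before filtering"))
  keep <- hits$evalue <= max_evalue &
    hits$identity_pct >= min_identity &
    hits$query_coverage_pct > min_coverage
  hits[keep, , drop = FALSE]
}

# Karlin-Altschul-style constants used to express raw local-alignment scores
# in bits and derive a search-space e-value.  These are fixed surrogate
# constants (gapped BLOSUM62 / blastn-like values); downstream filtering in
# this package relies on identity and coverage, not on the absolute e-value.
.KA_CONST <- list(
  protein = list(lambda = 0.267, K = 0.041),
  dna     = list(lambda = 0.625, K = 0.410)
)

# blastn-like scoring; the fuzzy IUPAC matrix scores an ambiguity code as
# the expectation over the bases it denotes, so consensus queries with
# ambiguity codes remain alignable
.dna_subst <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE, type = "DNA")
}

# shared-kmer seed filter: returns logical subject candidates for one query
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' All-pairs local similarity search
#'
#' A desk-scale local aligner: every query is aligned against every subject
#' by affine-gap Smith-Waterman (via \code{Biostrings::pairwiseAlignment}),
#' and hits are reported in the same table layout as [parse_hit_table()].
#' Protein searches use BLOSUM62 with gap open 11 / extend 1; DNA searches
#' use match +2 / mismatch -3 with gap open 5 / extend 2.  Raw scores are
#' converted to bit scores with fixed Karlin-Altschul-style constants and
#' e-values follow \code{E = m n 2^-bits}; the e-value scale is therefore a
#' documented surrogate for a database search engine's.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param type \code{"protein"} or \code{"dna"}.
#' @param min_raw_score report only alignments with raw score strictly above
#'   this (default 0).
#' @param seed_filter if \code{TRUE}, only query/subject pairs sharing at
#'   least \code{min_shared_kmers} words of length \code{seed_k} are aligned
#'   (a seeded-search speedup; \code{FALSE} performs the exhaustive
#'   all-pairs scan).
#' @param seed_k word size for the seed filter (default 4 for protein, 11
#'   for DNA).
#' @param min_shared_kmers minimum shared words to trigger an alignment.
#' @param both_strands for DNA, also search the reverse complement of each
#'   subject; minus-strand hits are reported with \code{s_start > s_end}
#'   plus-strand coordinates, as in the tabular hit convention.
#' @return a hit table (see [parse_hit_table()]) with
#'   \code{query_coverage_pct} filled in.
#' @export
local_similarity_search <- function(queries, subjects,
                                    type = c("protein", "dna"),
                                    min_raw_score = 0,
                                    seed_filter = FALSE,
                                    seed_k = NULL,
                                    min_shared_kmers = 2L,
                                    both_strands = FALSE) {
  type <- match.arg(type)
  if (length(queries) == 0L || length(subjects) == 0L)
    return(empty_hit_table())
  if (is.null(names(queries)) || is.null(names(subjects)))
    stopf("queries and subjects must be named")
  if (both_strands && type != "dna")
    stopf("both_strands applies to DNA searches only")
  if (is.null(seed_k)) seed_k <- if (type == "protein") 4L else 11L

  qset <- if (type == "protein") Biostrings::AAStringSet(queries)
          else Biostrings::DNAStringSet(queries)
  ka <- .KA_CONST[[type]]
  total_n <- sum(nchar(subjects))
  qlens <- nchar(queries)

  qkmers <- if (seed_filter) lapply(queries, .kmer_set, k = seed_k)

  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (j in seq_along(subjects)) {
    s_name <- names(subjects)[j]
    s_len <- nchar(subjects[[j]])
    for (strand in strands) {
      s_seq <- if (strand == "+") subjects[[j]] else revcomp(subjects[[j]])
      qi <- seq_along(queries)
      if (seed_filter) {
        skmers <- .kmer_set(s_seq, seed_k)
        shared <- vapply(qkmers, function(kk)
          sum(kk %in% skmers), integer(1))
        qi <- which(shared >= min_shared_kmers)
        if (length(qi) == 0L) next
      }
      subj <- if (type == "protein") Biostrings::AAString(s_seq)
              else Biostrings::DNAString(s_seq)
      al <- if (type == "protein")
        Biostrings::pairwiseAlignment(qset[qi], subj, type = "local",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1)
      else
        Biostrings::pairwiseAlignment(qset[qi], subj, type = "local",
                                      substitutionMatrix = .dna_subst(),
                                      gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(al)
      ok <- which(sc > min_raw_score)
      if (length(ok) == 0L) next
      alo <- al[ok]
      bits <- (ka$lambda * sc[ok] - log(ka$K)) / log(2)
      ev <- qlens[qi[ok]] * total_n * 2^(-bits)
      nmat <- Biostrings::nmatch(alo)
      alen <- Biostrings::nchar(alo)
      qs <- BiocGenerics::start(Biostrings::pattern(alo))
      qe <- BiocGenerics::end(Biostrings::pattern(alo))
      ss <- BiocGenerics::start(Biostrings::subject(alo))
      se <- BiocGenerics::end(Biostrings::subject(alo))
      if (strand == "-") {                 # map back to plus-strand coords
        tmp <- s_len - ss + 1L
        ss <- s_len - se + 1L
        se <- tmp
        t2 <- ss; ss <- se; se <- t2      # s_start > s_end flags minus strand
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[qi[ok]], subject_id = s_name,
        identity_pct = 100 * nmat / alen, aln_len = alen,
        mismatches = alen - nmat - Biostrings::nindel(alo)@insertion[, 2L] -
          Biostrings::nindel(alo)@deletion[, 2L],
        gap_opens = Biostrings::nindel(alo)@insertion[, 1L] +
          Biostrings::nindel(alo)@deletion[, 1L],
        q_start = qs, q_end = qe, s_start = ss, s_end = se,
        evalue = ev, score = sc[ok],
        query_coverage_pct = 100 * (qe - qs + 1L) / qlens[qi[ok]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hit_table())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
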