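#' Retrieval thresholds for tag extraction from assemblies
#'
#' Defaults: e-value at most \code{1e-10}, identity at least 65 percent,
#' 100 percent coverage of the consensus query tag, and a query-subject
#' length difference of at most 20 percent.
#'
#' @param max_evalue inclusive e-value ceiling.
#' @param min_identity inclusive percent-identity floor.
#' @param required_query_coverage minimum percent of query columns that the
#'   hit alignment must span.
#' @param max_length_diff_frac maximum fractional difference between the
#'   ungapped subject span and the query length.
#' @return named list of thresholds.
#' @export
retrieval_thresholds <- function(max_evalue = 1e-10, min_identity = 65,
                                 required_query_coverage = 100,
                                 max_length_diff_frac = 0.20) {
  stopifnot(max_evalue >= 0, min_identity >= 0, min_identity <= 100,
            required_query_coverage >= 0, required_query_coverage <= 100,
            max_length_diff_frac >= 0)
  list(max_evalue = max_evalue, min_identity = min_identity,
       required_query_coverage = required_query_coverage,
       max_length_diff_frac = max_length_diff_frac)
}

# perfect-match occurrences (1-based starts) of `pat` in `seq`
.exact_matches <- function(pat, seq) {
  if (nchar(pat) > nchar(seq)) return(integer(0))
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq))
  BiocGenerics::start(m)
}

#' Check primer-pair specificity on a reference genome
#'
#' Scans every contig, on both strands, for perfect matches of the two
#' primers and enumerates convergently oriented site pairs whose implied
#' product length lies within \code{product_range}.  The pair passes when
#' exactly one such site pair exists genome-wide.
#'
#' @param pair one-row primer pair (see [design_primer_pairs()]).
#' @param genome named character vector of contig sequences.
#' @param product_range allowed product length range (default
#'   \code{c(300, 550)}).
#' @return list with \code{pass} (logical) and \code{sites}, a data.frame
#'   of all amplifiable site pairs (\code{contig, start, end, orientation}).
#' @export
check_primer_specificity <- function(pair, genome,
                                     product_range = c(300L, 550L)) {
  stopifnot(length(genome) > 0L)
  left <- toupper(pair$left_seq)
  right <- toupper(pair$right_seq)
  sites <- list()
  for (ct in names(genome)) {
    seq <- toupper(genome[[ct]])
    # forward amplicon: left on plus strand, right primer annealing to the
    # plus strand via its reverse complement downstream
    lf <- .exact_matches(left, seq)
    rr <- .exact_matches(revcomp(right), seq)
    for (a in lf) for (b in rr) {
      len <- (b + nchar(right) - 1L) - a + 1L
      if (b >= a && len >= product_range[1L] && len <= product_range[2L])
        sites[[length(sites) + 1L]] <- data.frame(
          contig = ct, start = a, end = a + len - 1L,
          orientation = "forward", stringsAsFactors = FALSE)
    }
    # reverse amplicon: the same product read off the minus strand
    rf <- .exact_matches(right, seq)
    lr <- .exact_matches(revcomp(left), seq)
    for (a in rf) for (b in lr) {
      len <- (b + nchar(left) - 1L) - a + 1L
      if (b >= a && len >= product_range[1L] && len <= product_range[2L])
        sites[[length(sites) + 1L]] <- data.frame(
          contig = ct, start = a, end = a + len - 1L,
          orientation = "reverse", stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites) > 0L) do.call(rbind, sites)
  else data.frame(contig = character(), start = integer(),
                  end = integer(), orientation = character(),
                  stringsAsFactors = FALSE)
  list(pass = nrow(sites) == 1L, sites = sites)
}

#' Reciprocal-best test of a tag against its reference genome
#'
#' The tag sequence is searched against the reference; the test passes only
#' when the single best-scoring hit overlaps the expected source locus and
#' no other hit scores as high elsewhere.  A failing tag rejects all
#' species sequences associated with it.
#'
#' @param tag_seq tag consensus sequence (DNA).
#' @param reference named character vector of reference contigs.
#' @param expected_locus list with \code{contig}, \code{start}, \code{end}
#'   (1-based closed interval of the design locus on the reference).
#' @return list with \code{pass} (logical) and \code{hits} (the hit table).
#' @export
tag_rbb_test <- function(tag_seq, reference, expected_locus) {
  stopifnot(nchar(tag_seq) > 0L)
  hits <- local_similarity_search(c(tag = tag_seq), reference,
                                  type = "dna", both_strands = TRUE)
  if (nrow(hits) == 0L) return(list(pass = FALSE, hits = hits))
  top <- hits[hits$score == max(hits$score), , drop = FALSE]
  ov <- top$subject_id == expected_locus$contig &
    pmin(top$s_start, top$s_end) <= expected_locus$end &
    pmax(top$s_start, top$s_end) >= expected_locus$start
  list(pass = nrow(top) == 1L && all(ov), hits = hits)
}

#' Check that the number of distinct alleles is compatible with ploidy
#'
#' Contigs are uppercased and gap-stripped; the check passes when the
#' number of distinct sequences does not exceed the declared ploidy.
#'
#' @param contigs character vector of contig sequences covering one tag.
#' @param ploidy integer ploidy level of the species (1-8).
#' @return list with \code{pass}, \code{n_alleles} and \code{reason}
#'   (\code{"missing"} for an empty contig list).
#' @export
allele_count_check <- function(contigs, ploidy) {
  stopifnot(ploidy >= 1L, ploidy <= 8L)
  if (length(contigs) == 0L)
    return(list(pass = FALSE, n_alleles = 0L, reason = "missing"))
  alleles <- unique(gsub("-", "", toupper(contigs), fixed = TRUE))
  n <- length(alleles)
  list(pass = n <= ploidy, n_alleles = n,
       reason = if (n <= ploidy) NA_character_ else "too_many_alleles")
}

#' Retrieve a tag sequence from an assembled genome or transcriptome
#'
#' Searches the tag consensus against the assembly and keeps hits passing
#' all four retrieval thresholds.  Hits tied at the top score form the
#' best-hit set: if \code{enforce_ploidy} and more best hits exist than the
#' ploidy allows, the whole tag is rejected for this species set
#' (tag-level); otherwise one best hit is chosen deterministically
#' (lexicographically smallest contig id, then smallest start -- a
#' reproducible determinization of an otherwise arbitrary choice).  With
#' \code{check_edges}, the retrieved sequence must begin with the left
#' primer and end with the reverse complement of the right primer
#' (species-level rejection otherwise).  Outgroup species are handled by
#' \code{check_edges = FALSE, enforce_ploidy = FALSE}.
#'
#' @param tag_consensus tag consensus sequence (DNA, unambiguous or IUPAC).
#' @param assembly named character vector of contig sequences.
#' @param ploidy integer ploidy of the assembly.
#' @param thresholds a [retrieval_thresholds()] list.
#' @param check_edges require exact primer sequences at both ends.
#' @param enforce_ploidy reject the tag when best hits exceed ploidy.
#' @param primer_pair one-row primer pair (needed when
#'   \code{check_edges = TRUE}).
#' @return list with \code{status} (\code{"ok"} or \code{"reject"}),
#'   \code{sequence}, \code{contig}, \code{start}, \code{end},
#'   \code{strand}, and on rejection \code{level}
#'   (\code{"tag"}/\code{"species"}) and \code{reason}.
#' @export
retrieve_tag_from_assembly <- function(tag_consensus, assembly, ploidy,
                                       thresholds = retrieval_thresholds(),
                                       check_edges = TRUE,
                                       enforce_ploidy = TRUE,
                                       primer_pair = NULL) {
  hits <- local_similarity_search(c(tag = toupper(tag_consensus)), assembly,
                                  type = "dna", both_strands = TRUE)
  if (nrow(hits) > 0L) {
    qlen <- nchar(tag_consensus)
    subj_span <- abs(hits$s_end - hits$s_start) + 1L
    keep <- hits$evalue <= thresholds$max_evalue &
      hits$identity_pct >= thresholds$min_identity &
      hits$query_coverage_pct >= thresholds$required_query_coverage &
      abs(subj_span - qlen) / qlen <= thresholds$max_length_diff_frac
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) == 0L)
    return(list(status = "reject", level = "species", reason = "no_hit"))
  best <- hits[hits$score == max(hits$score), , drop = FALSE]
  if (enforce_ploidy && nrow(best) > ploidy)
    return(list(status = "reject", level = "tag",
                reason = "best_hits_exceed_ploidy"))
  o <- order(best$subject_id, pmin(best$s_start, best$s_end),
             method = "radix")
  h <- best[o[1L], , drop = FALSE]
  minus <- h$s_start > h$s_end
  s1 <- min(h$s_start, h$s_end); s2 <- max(h$s_start, h$s_end)
  seq <- substr(toupper(assembly[[h$subject_id]]), s1, s2)
  if (minus) seq <- revcomp(seq)
  if (check_edges) {
    if (is.null(primer_pair))
      stopf("primer_pair is required when check_edges = TRUE")
    lp <- toupper(primer_pair$left_seq)
    rp <- revcomp(toupper(primer_pair$right_seq))
    ok <- nchar(seq) >= nchar(lp) + nchar(rp) &&
      substr(seq, 1L, nchar(lp)) == lp &&
      substr(seq, nchar(seq) - nchar(rp) + 1L, nchar(seq)) == rp
    if (!ok)
      return(list(status = "reject", level = "species",
                  reason = "edge_mismatch"))
  }
  list(status = "ok", sequence = seq, contig = h$subject_id,
       start = s1, end = s2, strand = if (minus) "-" else "+")
}
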