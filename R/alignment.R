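#' Multi-species alignment container
#'
#' An aligned set of nucleotide sequences is stored as a character matrix
#' with one row per taxon (rownames are the taxon labels) and one column per
#' alignment position, over the alphabet \code{A,C,G,T,-,N} plus IUPAC
#' ambiguity codes.  All coordinates used on alignments in this package are
#' 0-based half-open column intervals.
#'
#' @param seqs named character vector of equal-length (gapped) sequences, or
#'   a character matrix with rownames.
#' @param locus_id optional identifier of the locus the alignment covers.
#' @return a \code{multi_aln}: character matrix with attributes
#'   \code{locus_id}.
#' @examples
#' aln <- multi_aln(c(s1 = "ACGT-A", s2 = "ACGTTA"), locus_id = "loc1")
#' dim(aln)
#' @export
multi_aln <- function(seqs, locus_id = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stopf("sequences must carry unique taxon names")
    n <- unique(nchar(seqs))
    if (length(n) != 1L)
      stopf("aligned sequences must all have the same length (got %s)",
            paste(n, collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("alignment matrix must have unique rownames")
  m[] <- toupper(m)
  structure(m, class = c("multi_aln", "matrix", "array"),
            locus_id = locus_id)
}

#' @export
print.multi_aln <- function(x, ...) {
  cat(sprintf("multi_aln: %d taxa x %d columns%s\n", nrow(x), ncol(x),
              if (!is.null(attr(x, "locus_id")))
                paste0(" [", attr(x, "locus_id"), "]") else ""))
  invisible(x)
}

# collapse alignment rows back to strings
aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

# per-taxon sequence extent: first..last non-gap column (1-based), NA if all gap
aln_extents <- function(aln) {
  t(apply(unclass(aln) != "-", 1L, function(ng) {
    w <- which(ng)
    if (length(w) == 0L) c(NA_integer_, NA_integer_) else range(w)
  }))
}

# logical taxa x columns matrix: TRUE where the column lies inside the
# taxon's first..last non-gap extent (internal gaps still count as covering)
aln_coverage <- function(aln) {
  ext <- aln_extents(aln)
  nc <- ncol(aln)
  cov <- matrix(FALSE, nrow(aln), nc, dimnames = list(rownames(aln), NULL))
  for (i in seq_len(nrow(aln))) {
    if (!is.na(ext[i, 1L])) cov[i, ext[i, 1L]:ext[i, 2L]] <- TRUE
  }
  cov
}

#' Read an aligned FASTA file into a multi_aln
#' @param path FASTA file of equal-length gapped sequences.
#' @param locus_id optional locus identifier (defaults to the file stem).
#' @return a [multi_aln()].
#' @export
read_alignment <- function(path, locus_id = NULL) {
  x <- Biostrings::readBStringSet(path)
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  multi_aln(stats::setNames(as.character(x), names(x)), locus_id = locus_id)
}

#' Write sequences to FASTA
#' @param seqs named character vector (gapped or ungapped).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @param type "dna" or "protein" (controls parsing strictness only).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a multi_aln to aligned FASTA
#' @param aln a [multi_aln()].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(aln_strings(aln), path)
}

# slice a window of alignment columns (0-based half-open)
aln_slice <- function(aln, start, end) {
  stopifnot(start >= 0L, end <= ncol(aln), start < end)
  multi_aln(unclass(aln)[, (start + 1L):end, drop = FALSE],
            locus_id = attr(aln, "locus_id"))
}
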