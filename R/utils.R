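# Internal helpers shared across modules.

# IUPAC nucleotide ambiguity codes keyed by the sorted base set they denote.
.IUPAC_BY_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

# base sets denoted by each IUPAC code (gap excluded on purpose)
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of an unambiguous or IUPAC DNA string
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
                 "TGCAKYWSRMBDHVNtgcakywsrmbdhvn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# run expr with a private RNG stream seeded by `seed`; the caller's global
# RNG state is untouched (generators must be pure functions of their seed)
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# longest homopolymer run length in a sequence
max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  if (length(r$lengths) == 0L) return(0L)
  max(r$lengths)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# canonical string form of a taxon set, used for deterministic tie-breaking
taxon_set_key <- function(taxa) paste(sort(taxa), collapse = ",")
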