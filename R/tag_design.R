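#' Find well-covered windows of a multi-species alignment
#'
#' A taxon covers a column when the column lies within the taxon's
#' first-to-last non-gap extent (internal gaps do not interrupt coverage).
#' Windows are maximal runs of columns covered by at least \code{min_taxa}
#' taxa including every \code{required} anchor taxon, kept when at least
#' \code{min_len} columns long.
#'
#' @param aln a [multi_aln()].
#' @param min_len minimum window length in columns (default 300).
#' @param min_taxa minimum number of covering taxa per column (default 4).
#' @param required character vector of anchor taxa that must cover every
#'   column of a window; if any is absent from the alignment no window is
#'   returned.
#' @return list of windows, each a list with \code{start}, \code{end}
#'   (0-based half-open column interval) and \code{covering_taxa} (taxa
#'   covering every column of the window).
#' @export
find_tag_windows <- function(aln, min_len = 300L, min_taxa = 4L,
                             required = character(0)) {
  if (!all(required %in% rownames(aln))) return(list())
  cov <- aln_coverage(aln)
  counts <- colSums(cov)
  req_ok <- if (length(required) > 0L)
    colSums(cov[required, , drop = FALSE]) == length(required)
  else rep(TRUE, ncol(aln))
  ok <- counts >= min_taxa & req_ok
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wins <- list()
  for (k in which(r$values)) {
    if (r$lengths[k] < min_len) next
    s <- starts[k]; e <- ends[k]
    covering <- rownames(aln)[rowSums(cov[, s:e, drop = FALSE]) == (e - s + 1L)]
    wins[[length(wins) + 1L]] <-
      list(start = s - 1L, end = e, covering_taxa = covering)
  }
  wins
}

#' Strict consensus of an alignment window
#'
#' Per column, over the taxa covering the window: if all covering taxa carry
#' the same base it is emitted; if two or more distinct bases occur (and no
#' gap) the IUPAC ambiguity code of the observed base set is emitted; any
#' gap among covering taxa yields \code{N}.  Input ambiguity codes
#' contribute their base sets; input \code{N} forces \code{N}.
#'
#' @param aln a [multi_aln()].
#' @param window a window from [find_tag_windows()], or \code{NULL} for the
#'   whole alignment (all taxa covering).
#' @return consensus string of length \code{window$end - window$start}.
#' @export
strict_consensus <- function(aln, window = NULL) {
  if (is.null(window))
    window <- list(start = 0L, end = ncol(aln),
                   covering_taxa = rownames(aln))
  stopifnot(window$start >= 0L, window$end <= ncol(aln),
            window$start < window$end)
  m <- unclass(aln)[window$covering_taxa,
                    (window$start + 1L):window$end, drop = FALSE]
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-" | col == "N")) {
      out[j] <- "N"
      next
    }
    bases <- sort(unique(unlist(.IUPAC_SETS[col], use.names = FALSE)))
    out[j] <- .IUPAC_BY_SET[[paste(bases, collapse = "")]]
  }
  paste(out, collapse = "")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); dinucleotides read 5'->3' on one strand
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameter set, with the entropic salt correction
#' \code{dS + 0.368 (L-1) ln[Na+]} and
#' \code{Tm = 1000 dH / (dS + R ln(C/4)) - 273.15}.
#'
#' @param seq unambiguous DNA string (A/C/G/T), length >= 8.
#' @param Na monovalent cation concentration in mol/L (default 0.05).
#' @param oligo_conc total oligo concentration in mol/L (default 5e-7,
#'   i.e. 0.5 uM).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, Na = 0.05, oligo_conc = 5e-7) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L) stopf("sequence too short for a meaningful Tm (length %d)", n)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stopf("ambiguous base in primer sequence: %s", seq)
  dinucs <- paste0(chars[-n], chars[-1L])
  dH <- sum(.NN_DH[dinucs])
  dS <- sum(.NN_DS[dinucs])
  # initiation terms per terminal base pair
  for (b in chars[c(1L, n)]) {
    if (b %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1L) * log(Na)
  R <- 1.9872
  dH * 1000 / (dS + R * log(oligo_conc / 4)) - 273.15
}

#' Default primer-pair design constraints
#'
#' Melting temperature 59-61 degrees C, maximal homopolymer run of 3, a
#' 3'-terminal G or C (GC clamp), product size 300-550 bp, primer length
#' 18-25 nt, and at most 100 pairs per consensus.
#'
#' @param product_min,product_max amplicon length bounds in bp.
#' @param tm_min,tm_max primer melting-temperature window in degrees C.
#' @param max_homopolymer longest allowed single-base run in a primer.
#' @param primer_min,primer_max primer length bounds in nt.
#' @param max_pairs cap on emitted pairs per consensus.
#' @param product_opt product length targeted when ranking pairs.
#' @return a named list of constraints.
#' @export
primer_constraints <- function(product_min = 300L, product_max = 550L,
                               tm_min = 59, tm_max = 61,
                               max_homopolymer = 3L,
                               primer_min = 18L, primer_max = 25L,
                               max_pairs = 100L, product_opt = 425L) {
  list(product_min = product_min, product_max = product_max,
       tm_min = tm_min, tm_max = tm_max,
       max_homopolymer = max_homopolymer,
       primer_min = primer_min, primer_max = primer_max,
       max_pairs = max_pairs, product_opt = product_opt)
}

# enumerate single-primer candidates in ambiguity-free stretches of `seq`.
# side = "left": primer equals the consensus substring (3' end rightmost);
# side = "right": primer is the reverse complement (3' end leftmost).
.primer_candidates <- function(seq, cons, side) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  clean <- chars %in% c("A", "C", "G", "T")
  cands <- list()
  for (len in cons$primer_min:cons$primer_max) {
    if (n < len) next
    for (s in 1:(n - len + 1L)) {
      e <- s + len - 1L
      if (!all(clean[s:e])) next
      p <- substr(seq, s, e)
      if (side == "right") p <- revcomp(p)
      last <- substr(p, len, len)
      if (!(last %in% c("G", "C"))) next
      if (max_homopolymer(p) > cons$max_homopolymer) next
      tm <- melting_temperature(p)
      if (tm < cons$tm_min || tm > cons$tm_max) next
      cands[[length(cands) + 1L]] <-
        list(seq = p, start0 = s - 1L, end0 = e, tm = tm)
    }
  }
  cands
}

#' Design conserved primer pairs on a consensus sequence
#'
#' Candidate primers are 18-25-mers lying entirely in ambiguity-free
#' (A/C/G/T-only) stretches of the consensus, so that they are conserved
#' across the taxa that built it.  Every returned pair satisfies the full
#' constraint set of [primer_constraints()].  Pairs are scored by the
#' melting-temperature difference of the two primers and then by distance of
#' the product length from the optimum; at most \code{max_pairs} are
#' returned, chosen greedily (in score order) to cover the consensus with
#' their product intervals, and are returned best-first.
#'
#' @param consensus consensus string (may contain IUPAC codes and N).
#' @param constraints a [primer_constraints()] list.
#' @return data.frame of primer pairs: \code{left_seq, right_seq,
#'   left_start, right_end, tm_left, tm_right, product_len} with
#'   \code{left_start}/\code{right_end} a 0-based half-open product interval
#'   on the consensus.  The right primer is given 5'->3' on the reverse
#'   strand.
#' @export
design_primer_pairs <- function(consensus,
                                constraints = primer_constraints()) {
  cons <- constraints
  if (nchar(consensus) < cons$product_min)
    return(.empty_pair_table())
  lefts <- .primer_candidates(toupper(consensus), cons, "left")
  rights <- .primer_candidates(toupper(consensus), cons, "right")
  if (length(lefts) == 0L || length(rights) == 0L)
    return(.empty_pair_table())
  r_end0 <- vapply(rights, `[[`, 0L, "end0")
  rows <- list()
  for (L in lefts) {
    prod <- r_end0 - L$start0
    ok <- which(prod >= cons$product_min & prod <= cons$product_max)
    for (k in ok) {
      Rp <- rights[[k]]
      if (Rp$start0 < L$end0) next      # primers must not overlap
      rows[[length(rows) + 1L]] <- data.frame(
        left_seq = L$seq, right_seq = Rp$seq,
        left_start = L$start0, right_end = Rp$end0,
        tm_left = L$tm, tm_right = Rp$tm,
        product_len = Rp$end0 - L$start0, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_pair_table())
  pairs <- do.call(rbind, rows)
  sc1 <- abs(pairs$tm_left - pairs$tm_right)
  sc2 <- abs(pairs$product_len - cons$product_opt)
  o <- order(sc1, sc2, pairs$left_start, pairs$right_end, method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  # greedy coverage of the consensus by product intervals, in score order
  if (nrow(pairs) > cons$max_pairs) {
    covered <- rep(FALSE, nchar(consensus))
    take <- logical(nrow(pairs))
    n_taken <- 0L
    for (i in seq_len(nrow(pairs))) {
      span <- (pairs$left_start[i] + 1L):pairs$right_end[i]
      if (any(!covered[span])) {
        take[i] <- TRUE
        covered[span] <- TRUE
        n_taken <- n_taken + 1L
        if (n_taken >= cons$max_pairs) break
      }
    }
    if (n_taken < cons$max_pairs) {
      fill <- which(!take)[seq_len(min(cons$max_pairs - n_taken,
                                       sum(!take)))]
      take[fill] <- TRUE
    }
    pairs <- pairs[take, , drop = FALSE]
    o <- order(abs(pairs$tm_left - pairs$tm_right),
               abs(pairs$product_len - cons$product_opt),
               pairs$left_start, pairs$right_end, method = "radix")
    pairs <- pairs[o, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

.empty_pair_table <- function() {
  data.frame(left_seq = character(), right_seq = character(),
             left_start = integer(), right_end = integer(),
             tm_left = numeric(), tm_right = numeric(),
             product_len = integer(), stringsAsFactors = FALSE)
}

#' Count variable sites in an alignment window
#'
#' A column is variable when at least two distinct states occur among the
#' taxa covering it; the gap is a fifth state, and \code{N}/IUPAC ambiguity
#' codes are treated as missing.
#'
#' @param aln a [multi_aln()].
#' @param window window from [find_tag_windows()], or \code{NULL} for the
#'   full alignment.
#' @return integer count of variable columns.
#' @export
count_variable_sites <- function(aln, window = NULL) {
  if (is.null(window))
    window <- list(start = 0L, end = ncol(aln),
                   covering_taxa = rownames(aln))
  cov <- aln_coverage(aln)
  m <- unclass(aln)[, (window$start + 1L):window$end, drop = FALSE]
  cv <- cov[, (window$start + 1L):window$end, drop = FALSE]
  states <- c("A", "C", "G", "T", "-")
  nv <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[cv[, j], j]
    col <- col[col %in% states]
    if (length(unique(col)) >= 2L) nv <- nv + 1L
  }
  nv
}

#' Greedy selection of the most variable non-overlapping tags
#'
#' Candidates are sorted by variability (descending), then longer amplicon,
#' then leftmost start, then tag id, and accepted greedily when their
#' interval overlaps no previously accepted interval of the same SCO
#' region.  Deterministic.
#'
#' @param candidates data.frame with columns \code{tag_id, sco_id, start,
#'   end, variability} (plus any carried columns); \code{start}/\code{end}
#'   are 0-based half-open intervals in a coordinate system shared within
#'   each \code{sco_id}.
#' @return the selected subset, in selection order.
#' @export
rank_and_select_tags <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  o <- order(-candidates$variability,
             -(candidates$end - candidates$start),
             candidates$start, candidates$tag_id, method = "radix")
  cand <- candidates[o, , drop = FALSE]
  sel <- logical(nrow(cand))
  for (g in unique(cand$sco_id)) {
    idx <- which(cand$sco_id == g)
    acc_s <- integer(0); acc_e <- integer(0)
    for (i in idx) {
      s <- cand$start[i]; e <- cand$end[i]
      if (all(e <= acc_s | s >= acc_e)) {
        sel[i] <- TRUE
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a tag interval against a gene model
#'
#' A tag is \code{coding} when its interval is entirely inside the union of
#' CDS features, \code{non_coding} when it does not intersect any CDS
#' (introns and UTRs count as non-coding), and \code{mixed} otherwise.
#'
#' @param start,end 0-based half-open tag interval on the reference
#'   sequence.
#' @param features data.frame of gene-model features with columns
#'   \code{type, start, end} in GFF3 convention (1-based closed
#'   coordinates); must include the gene's CDS features and at least one
#'   feature spanning the gene.
#' @return one of \code{"coding"}, \code{"non_coding"}, \code{"mixed"}.
#' @export
annotate_tag <- function(start, end, features) {
  stopifnot(start < end)
  span <- c(min(features$start) - 1L, max(features$end))  # 0-based half-open
  if (start < span[1L] || end > span[2L])
    stopf("tag interval [%d,%d) lies outside the annotated gene span [%d,%d)",
          start, end, span[1L], span[2L])
  cds <- features[features$type == "CDS", , drop = FALSE]
  pos <- (start + 1L):end                     # 1-based positions of the tag
  in_cds <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(cds)))
    in_cds <- in_cds | (pos >= cds$start[i] & pos <= cds$end[i])
  if (all(in_cds)) "coding"
  else if (!any(in_cds)) "non_coding"
  else "mixed"
}

#' Build candidate tags for one SCO alignment
#'
#' For each qualifying window: builds the strict consensus, designs primer
#' pairs, scores each resulting amplicon by its variable-site count, and
#' returns all candidates (selection is done by [rank_and_select_tags()]).
#'
#' @param aln a [multi_aln()] of one SCO locus.
#' @param sco_id locus identifier used in tag ids.
#' @param min_len,min_taxa,required window screening parameters, see
#'   [find_tag_windows()].
#' @param constraints a [primer_constraints()] list.
#' @return data.frame of candidate tags: \code{tag_id, sco_id, start, end}
#'   (amplicon interval in alignment columns), \code{win_start, win_end},
#'   primer columns as in [design_primer_pairs()], and \code{variability}.
#' @export
build_candidate_tags <- function(aln, sco_id,
                                 min_len = 300L, min_taxa = 4L,
                                 required = character(0),
                                 constraints = primer_constraints()) {
  wins <- find_tag_windows(aln, min_len = min_len, min_taxa = min_taxa,
                           required = required)
  rows <- list()
  for (w in seq_along(wins)) {
    win <- wins[[w]]
    cons <- strict_consensus(aln, win)
    pairs <- design_primer_pairs(cons, constraints)
    if (nrow(pairs) == 0L) next
    for (i in seq_len(nrow(pairs))) {
      a_start <- win$start + pairs$left_start[i]
      a_end <- win$start + pairs$right_end[i]
      amp_win <- list(start = a_start, end = a_end,
                      covering_taxa = win$covering_taxa)
      v <- count_variable_sites(aln, amp_win)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(tag_id = sprintf("%s_w%d_p%03d", sco_id, w, i),
                   sco_id = sco_id, start = a_start, end = a_end,
                   win_start = win$start, win_end = win$end,
                   variability = v, stringsAsFactors = FALSE),
        pairs[i, , drop = FALSE])
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tag_id = character(), sco_id = character(),
                      start = integer(), end = integer(),
                      win_start = integer(), win_end = integer(),
                      variability = integer(), .empty_pair_table(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
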