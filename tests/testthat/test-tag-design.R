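test_that("window finding honors coverage, anchors and minimum length", {
  m <- matrix("A", 5, 400,
              dimnames = list(c("ref", "far", "x", "y", "z"), NULL))
  aln <- multi_aln(m)
  w <- find_tag_windows(aln, min_len = 300, min_taxa = 4,
                        required = c("ref", "far"))
  expect_length(w, 1L)
  expect_equal(w[[1]]$start, 0L)
  expect_equal(w[[1]]$end, 400L)
  expect_setequal(w[[1]]$covering_taxa, rownames(m))

  # required taxon absent: no windows
  expect_length(find_tag_windows(aln, required = "missing"), 0L)
})

test_that("windows match a per-column scan and are maximal", {
  set.seed(61)
  for (rep in 1:10) {
    n_taxa <- 6; n_cols <- 80
    m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, TRUE),
                n_taxa, dimnames = list(sprintf("t%d", 1:n_taxa), NULL))
    # staggered terminal gaps
    for (i in 1:n_taxa) {
      s <- sample(0:25, 1); e <- sample(0:25, 1)
      if (s > 0) m[i, 1:s] <- "-"
      if (e > 0) m[i, (n_cols - e + 1):n_cols] <- "-"
    }
    aln <- multi_aln(m)
    req <- "t1"
    wins <- find_tag_windows(aln, min_len = 10, min_taxa = 4,
                             required = req)
    # oracle: per-column covering sets from first..last non-gap extents
    covers <- sapply(1:n_cols, function(j) {
      vapply(1:n_taxa, function(i) {
        ng <- which(m[i, ] != "-")
        length(ng) > 0 && j >= min(ng) && j <= max(ng)
      }, logical(1))
    })
    ok <- colSums(covers) >= 4 & covers[1, ]
    r <- rle(as.vector(ok)); ends <- cumsum(r$lengths)
    oracle <- list()
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < 10) next
      oracle[[length(oracle) + 1]] <-
        c(ends[k] - r$lengths[k], ends[k])
    }
    expect_equal(lapply(wins, function(w) c(w$start, w$end)), oracle)
    # maximality: extending by one column breaks a criterion
    for (w in wins) {
      if (w$start > 0) expect_false(ok[w$start])
      if (w$end < n_cols) expect_false(ok[w$end + 1])
    }
  }
})

test_that("strict consensus applies the base/IUPAC/gap rules", {
  aln <- multi_aln(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(strict_consensus(aln), "ACGT")

  # {A,A,G} -> R; {A,C} -> M; gap in column -> N
  aln2 <- multi_aln(c(a = "AAGA", b = "ACGA", c = "GCG-"))
  expect_equal(strict_consensus(aln2), "RMGN")

  # consensus over a single covering taxon equals its subsequence
  w <- list(start = 1L, end = 3L, covering_taxa = "a")
  expect_equal(strict_consensus(aln2, w), "AG")

  # length always equals window length
  expect_equal(nchar(strict_consensus(aln2)), 4L)

  # input ambiguity codes contribute their base sets; N forces N
  aln3 <- multi_aln(c(a = "RN", b = "GA"))
  expect_equal(strict_consensus(aln3), "RN")
})

test_that("melting temperature matches the nearest-neighbor oracle", {
  # frozen value from an independent summation of the parameter table
  expect_equal(melting_temperature("AGCTGACCTGAAGCTGATCG"),
               57.20701989700672, tolerance = 1e-10)
  # duplex symmetry: Tm(s) == Tm(revcomp(s))
  set.seed(71)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_equal(melting_temperature(s),
                 melting_temperature(revcomp(s)), tolerance = 1e-9)
  }
  # A/T -> G/C substitution never decreases Tm
  set.seed(72)
  for (k in 1:100) {
    s <- strsplit(paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                        collapse = ""), "")[[1]]
    at <- which(s %in% c("A", "T"))
    if (length(at) == 0) next
    i <- sample(at, 1)
    s2 <- s
    s2[i] <- sample(c("G", "C"), 1)
    expect_gte(melting_temperature(paste(s2, collapse = "")),
               melting_temperature(paste(s, collapse = "")))
  }
  expect_error(melting_temperature("ACGTACGN"), "ambiguous")
  expect_error(melting_temperature("ACGT"), "too short")
})

primer_ok <- function(p, cons = primer_constraints()) {
  # independent constraint validator
  check1 <- function(seq, tm) {
    n <- nchar(seq)
    n >= cons$primer_min && n <= cons$primer_max &&
      substr(seq, n, n) %in% c("G", "C") &&
      max(rle(strsplit(seq, "")[[1]])$lengths) <= cons$max_homopolymer &&
      tm >= cons$tm_min && tm <= cons$tm_max
  }
  all(vapply(seq_len(nrow(p)), function(i)
    check1(p$left_seq[i], p$tm_left[i]) &&
      check1(p$right_seq[i], p$tm_right[i]) &&
      p$product_len[i] >= cons$product_min &&
      p$product_len[i] <= cons$product_max, logical(1)))
}

test_that("primer design obeys every constraint and caps at 100 pairs", {
  expect_equal(nrow(design_primer_pairs(strrep("N", 600))), 0L)

  set.seed(81)
  st <- simulate_study(n_sco = 2, n_taxa = 6, seed = 91)
  for (id in names(st$alignments)) {
    cons <- strict_consensus(st$alignments[[id]])
    p <- design_primer_pairs(cons)
    expect_gt(nrow(p), 0L)
    expect_lte(nrow(p), 100L)
    expect_true(primer_ok(p))
    # amplicon interval starts with the left primer on the consensus
    for (i in seq_len(min(nrow(p), 5))) {
      expect_equal(substr(cons, p$left_start[i] + 1,
                          p$left_start[i] + nchar(p$left_seq[i])),
                   p$left_seq[i])
      expect_equal(revcomp(substr(cons,
                                  p$right_end[i] - nchar(p$right_seq[i]) + 1,
                                  p$right_end[i])),
                   p$right_seq[i])
    }
  }
})

test_that("a consensus with a single valid site pair yields exactly that pair", {
  # two 18-nt ambiguity-free anchors separated by an N run: each side
  # admits exactly one candidate placement (one position, one length),
  # both verified to satisfy Tm/clamp/homopolymer constraints
  left <- "CGCGGAGGACGAGAGGTC"
  right_site <- "CGGCACAAGGCCCTACGA"  # right primer = its revcomp
  cons <- paste0(left, strrep("N", 384), right_site)
  stopifnot(nchar(cons) == 420)
  p <- design_primer_pairs(cons)
  expect_equal(nrow(p), 1L)
  expect_equal(p$left_seq, left)
  expect_equal(p$right_seq, scotags:::revcomp(right_site))
  expect_equal(p$product_len, 420L)
  # oracle: exhaustive enumeration over every 18-25-mer placement pair
  cands <- function(seq, side) {
    out <- list()
    for (len in 18:25) for (s in 1:(nchar(seq) - len + 1)) {
      sub <- substr(seq, s, s + len - 1)
      if (grepl("[^ACGT]", sub)) next
      pr <- if (side == "left") sub else revcomp(sub)
      if (!substr(pr, len, len) %in% c("G", "C")) next
      if (max(rle(strsplit(pr, "")[[1]])$lengths) > 3) next
      tm <- melting_temperature(pr)
      if (tm < 59 || tm > 61) next
      out[[length(out) + 1]] <- c(start = s - 1, end = s + len - 1)
    }
    out
  }
  ls <- cands(cons, "left"); rs <- cands(cons, "right")
  valid <- 0
  for (a in ls) for (b in rs) {
    len <- b["end"] - a["start"]
    if (len >= 300 && len <= 550 && b["start"] >= a["end"])
      valid <- valid + 1
  }
  expect_equal(nrow(p), valid)
  expect_equal(valid, 1)
})

test_that("variable-site counting treats gaps as a state, ambiguity as missing", {
  aln <- multi_aln(c(a = "ACGT", b = "ACGT"))
  expect_equal(count_variable_sites(aln), 0L)
  aln2 <- multi_aln(c(a = "ACGT", b = "TCGT"))
  expect_equal(count_variable_sites(aln2), 1L)
  # gap is a fifth state; N is missing
  aln3 <- multi_aln(c(a = "A-GT", b = "ACGN", c = "ACGT"))
  expect_equal(count_variable_sites(aln3), 1L)

  set.seed(92)
  for (rep in 1:10) {
    aln <- random_aln(5, 60, gap_frac = 0.15)
    got <- count_variable_sites(aln)
    # brute force restricted to covering taxa
    cov <- sapply(1:60, function(j) {
      vapply(1:5, function(i) {
        ng <- which(unclass(aln)[i, ] != "-")
        length(ng) > 0 && j >= min(ng) && j <= max(ng)
      }, logical(1))
    })
    want <- 0
    for (j in 1:60) {
      col <- unclass(aln)[cov[, j], j]
      col <- col[col %in% c("A", "C", "G", "T", "-")]
      if (length(unique(col)) >= 2) want <- want + 1
    }
    expect_equal(got, want)
  }
})

test_that("tag selection is greedy on variability with documented tie-breaks", {
  one <- data.frame(tag_id = "t1", sco_id = "s", start = 0L, end = 100L,
                    variability = 5L)
  expect_equal(rank_and_select_tags(one)$tag_id, "t1")

  two <- rbind(one,
               data.frame(tag_id = "t2", sco_id = "s", start = 50L,
                          end = 150L, variability = 10L))
  expect_equal(rank_and_select_tags(two)$tag_id, "t2")

  set.seed(93)
  cand <- data.frame(tag_id = sprintf("t%03d", 1:50), sco_id = "s",
                     start = sample(0:500, 50, TRUE))
  cand$end <- cand$start + sample(50:150, 50, TRUE)
  cand$variability <- sample(0:30, 50, TRUE)
  got <- rank_and_select_tags(cand)
  # independent re-implementation of the same greedy rule
  o <- order(-cand$variability, -(cand$end - cand$start), cand$start,
             cand$tag_id)
  acc <- list()
  for (i in o) {
    ok <- all(vapply(acc, function(iv)
      cand$end[i] <= iv[1] || cand$start[i] >= iv[2], logical(1)))
    if (ok) acc[[length(acc) + 1]] <- c(cand$start[i], cand$end[i],
                                        id = i)
  }
  expect_setequal(got$tag_id, cand$tag_id[vapply(acc, `[`, 0, 3)])
  # accepted tags pairwise non-overlapping
  if (nrow(got) > 1) {
    o2 <- order(got$start)
    expect_true(all(got$start[o2][-1] >= got$end[o2][-nrow(got)]))
  }
})

test_that("tag structural classification follows the CDS overlap rules", {
  feats <- data.frame(
    type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
             "three_prime_UTR"),
    start = c(1, 1, 51, 251, 331, 481),
    end = c(550, 50, 250, 330, 480, 550))
  expect_equal(annotate_tag(60, 200, feats), "coding")
  expect_equal(annotate_tag(255, 320, feats), "non_coding")  # intron
  expect_equal(annotate_tag(5, 40, feats), "non_coding")     # UTR
  expect_equal(annotate_tag(200, 300, feats), "mixed")
  expect_error(annotate_tag(500, 600, feats), "outside")
})
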