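# a primer pair and an amplicon planted in synthetic contigs
make_amplicon <- function(seed = 1) {
  set.seed(seed)
  left <- "CGCGGAGGACGAGAGGTC"
  right <- "TCGTAGGGCCTTGTGCCG"   # 5'->3' on the reverse strand
  core <- paste(sample(c("A", "C", "G", "T"), 384, TRUE), collapse = "")
  amplicon <- paste0(left, core, scotags:::revcomp(right))
  list(pair = data.frame(left_seq = left, right_seq = right,
                         left_start = 0L, right_end = 420L,
                         tm_left = 59.7, tm_right = 59.9,
                         product_len = 420L, stringsAsFactors = FALSE),
       amplicon = amplicon)
}

pad <- function(seq, seed = 2, n = 60) {
  set.seed(seed)
  paste0(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
         seq,
         paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

test_that("primer specificity requires a single convergent site pair", {
  fx <- make_amplicon()
  genome1 <- c(ctg1 = pad(fx$amplicon))
  r <- check_primer_specificity(fx$pair, genome1)
  expect_true(r$pass)
  expect_equal(nrow(r$sites), 1L)
  expect_equal(r$sites$start, 61L)

  # amplicon duplicated on two contigs: two site pairs, fail
  genome2 <- c(ctg1 = pad(fx$amplicon), ctg2 = pad(fx$amplicon, seed = 9))
  r2 <- check_primer_specificity(fx$pair, genome2)
  expect_false(r2$pass)
  expect_equal(nrow(r2$sites), 2L)

  # reverse-orientation copy is still found
  genome3 <- c(ctg1 = pad(scotags:::revcomp(fx$amplicon)))
  r3 <- check_primer_specificity(fx$pair, genome3)
  expect_true(r3$pass)
  expect_equal(r3$sites$orientation, "reverse")

  # product outside the allowed range does not count as a site pair
  stretched <- paste0(fx$pair$left_seq, strrep("A", 600),
                      scotags:::revcomp(fx$pair$right_seq))
  r4 <- check_primer_specificity(fx$pair, c(ctg1 = pad(stretched)))
  expect_false(r4$pass)
  expect_equal(nrow(r4$sites), 0L)
})

test_that("specificity equals an exhaustive sliding-window scan", {
  fx <- make_amplicon(3)
  set.seed(33)
  genome <- c(ctg1 = pad(fx$amplicon, 4), ctg2 = pad(fx$amplicon, 5))
  r <- check_primer_specificity(fx$pair, genome)
  # oracle: scan every position of every contig on both strands
  count <- 0
  for (ct in names(genome)) {
    g <- genome[[ct]]
    occ <- function(pat) {
      hits <- integer(0)
      for (i in seq_len(nchar(g) - nchar(pat) + 1))
        if (substr(g, i, i + nchar(pat) - 1) == pat)
          hits <- c(hits, i)
      hits
    }
    for (combo in list(c(fx$pair$left_seq,
                         scotags:::revcomp(fx$pair$right_seq)),
                       c(fx$pair$right_seq,
                         scotags:::revcomp(fx$pair$left_seq)))) {
      for (a in occ(combo[1])) for (b in occ(combo[2])) {
        len <- b + nchar(combo[2]) - a
        if (b >= a && len >= 300 && len <= 550) count <- count + 1
      }
    }
  }
  expect_equal(nrow(r$sites), count)
})

test_that("tag reciprocal-best test rejects equal-scoring paralogs", {
  fx <- make_amplicon(11)
  ref <- c(locus = pad(fx$amplicon, 12))
  locus_iv <- list(contig = "locus", start = 61,
                   end = 60 + nchar(fx$amplicon))
  expect_true(tag_rbb_test(fx$amplicon, ref, locus_iv)$pass)

  # identical copy elsewhere: tie at the top, fail
  ref2 <- c(ref, decoy = pad(fx$amplicon, 13))
  expect_false(tag_rbb_test(fx$amplicon, ref2, locus_iv)$pass)

  # near-identical (95%) decoy: true locus still the unique best hit
  set.seed(14)
  ch <- strsplit(fx$amplicon, "")[[1]]
  mut <- sample(length(ch), round(0.05 * length(ch)))
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  ref3 <- c(ref, decoy = pad(paste(ch, collapse = ""), 15))
  r3 <- tag_rbb_test(fx$amplicon, ref3, locus_iv)
  # oracle: exhaustive best-hit comparison from the raw hit table
  best <- r3$hits[r3$hits$score == max(r3$hits$score), ]
  expect_equal(r3$pass,
               nrow(best) == 1 && best$subject_id == "locus")
  expect_true(r3$pass)
})

test_that("allele counting compares distinct sequences to ploidy", {
  expect_true(allele_count_check(c("ACGT", "ACgt"), 2)$pass)   # 1 distinct
  expect_true(allele_count_check(c("ACGT", "ACTT"), 2)$pass)   # 2 alleles
  r <- allele_count_check(c("ACGT", "ACTT", "AGTT"), 2)
  expect_false(r$pass)
  expect_equal(r$n_alleles, 3L)
  # tetraploid tolerates four alleles
  expect_true(allele_count_check(c("AAAA", "AAAT", "AATT", "ATTT"),
                                 4)$pass)
  # gaps stripped before comparison
  expect_true(allele_count_check(c("AC-GT", "ACGT"), 1)$pass)
  r0 <- allele_count_check(character(0), 2)
  expect_false(r0$pass)
  expect_equal(r0$reason, "missing")
})

test_that("tag retrieval enforces thresholds, ploidy and primer edges", {
  fx <- make_amplicon(21)
  asm <- c(ctgA = pad(fx$amplicon, 22))
  r <- retrieve_tag_from_assembly(fx$amplicon, asm, ploidy = 2,
                                  primer_pair = fx$pair)
  expect_equal(r$status, "ok")
  expect_equal(r$sequence, fx$amplicon)
  expect_equal(c(r$start, r$end), c(61, 60 + nchar(fx$amplicon)))

  # ~60% identity: below the 65% floor, no hit survives
  set.seed(23)
  ch <- strsplit(fx$amplicon, "")[[1]]
  mut <- sample(length(ch), round(0.40 * length(ch)))
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  asm_far <- c(ctgA = pad(paste(ch, collapse = ""), 24))
  r2 <- retrieve_tag_from_assembly(fx$amplicon, asm_far, ploidy = 2,
                                   primer_pair = fx$pair)
  expect_equal(r2$status, "reject")

  # subject 125% of the query length: length-difference filter rejects
  long <- paste0(substr(fx$amplicon, 1, 210),
                 paste(rep("ACGT", 27), collapse = ""),
                 substr(fx$amplicon, 211, nchar(fx$amplicon)))
  r3 <- retrieve_tag_from_assembly(fx$amplicon, c(ctgA = pad(long, 25)),
                                   ploidy = 2, primer_pair = fx$pair)
  expect_equal(r3$status, "reject")

  # three equal best hits on a diploid: tag-level rejection
  asm3 <- c(c1 = pad(fx$amplicon, 26), c2 = pad(fx$amplicon, 27),
            c3 = pad(fx$amplicon, 28))
  r4 <- retrieve_tag_from_assembly(fx$amplicon, asm3, ploidy = 2,
                                   primer_pair = fx$pair)
  expect_equal(r4$status, "reject")
  expect_equal(r4$level, "tag")
  # outgroup mode relaxes the ploidy discard and the edge check
  r5 <- retrieve_tag_from_assembly(fx$amplicon, asm3, ploidy = 2,
                                   check_edges = FALSE,
                                   enforce_ploidy = FALSE)
  expect_equal(r5$status, "ok")
  expect_equal(r5$contig, "c1")   # deterministic choice

  # mutation inside the left primer (kept aligned, coverage still 100%):
  # species-level rejection when edges are checked
  stopifnot(substr(fx$amplicon, 5, 5) != "T")
  edge_mut <- paste0(substr(fx$amplicon, 1, 4), "T",
                     substr(fx$amplicon, 6, nchar(fx$amplicon)))
  r6 <- retrieve_tag_from_assembly(fx$amplicon,
                                   c(ctgA = pad(edge_mut, 29)),
                                   ploidy = 2, primer_pair = fx$pair)
  expect_equal(r6$status, "reject")
  expect_equal(r6$level, "species")
  expect_equal(r6$reason, "edge_mismatch")

  # minus-strand copies are retrieved in query orientation
  r7 <- retrieve_tag_from_assembly(
    fx$amplicon, c(ctgA = pad(scotags:::revcomp(fx$amplicon), 30)),
    ploidy = 2, primer_pair = fx$pair)
  expect_equal(r7$status, "ok")
  expect_equal(r7$sequence, fx$amplicon)
  expect_equal(r7$strand, "-")
})

test_that("every filter verdict is reproducible (pure functions)", {
  fx <- make_amplicon(31)
  genome <- c(ctg1 = pad(fx$amplicon, 32))
  a <- check_primer_specificity(fx$pair, genome)
  b <- check_primer_specificity(fx$pair, genome)
  expect_identical(a, b)
  r1 <- retrieve_tag_from_assembly(fx$amplicon, genome, 2,
                                   primer_pair = fx$pair)
  r2 <- retrieve_tag_from_assembly(fx$amplicon, genome, 2,
                                   primer_pair = fx$pair)
  expect_identical(r1, r2)
})
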