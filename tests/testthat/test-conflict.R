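test_that("outgroup rooting handles monophyly, singletons and failures", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rooted <- root_on_outgroup(tr, c("C", "D"))
  has_clade <- function(tree, taxa)
    any(vapply(oracle_clades(tree), identical, logical(1), sort(taxa)))
  expect_true(has_clade(rooted, c("C", "D")) ||
                has_clade(rooted, c("A", "B")))
  expect_true(ape::is.rooted(rooted))

  # interleaved outgroup: typed error
  expect_error(root_on_outgroup(tr, c("A", "C")),
               class = "scotags_outgroup_error")
  expect_error(root_on_outgroup(tr, c("X", "Y")),
               class = "scotags_outgroup_error")

  # single outgroup taxon roots on its pendant edge
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,O:1):1);")
  r2 <- root_on_outgroup(tr2, "O")
  expect_true(ape::is.rooted(r2))
  expect_true(any(vapply(oracle_clades(r2), identical, logical(1),
                         sort(c("A", "B", "C")))))

  # outgroup clade straddling the stored trifurcation still roots
  tr3 <- ape::read.tree(text = "(O1:1,O2:1,(A:1,(B:1,C:1):1):1);")
  r3 <- root_on_outgroup(tr3, c("O1", "O2"))
  expect_true(any(vapply(oracle_clades(r3), identical, logical(1),
                         sort(c("A", "B", "C")))))
})

test_that("low-support collapsing contracts exactly the weak branches", {
  t1 <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)100:1)100;")
  c1 <- collapse_low_support(t1)
  expect_equal(sort(sapply(oracle_clades(c1), paste, collapse = ",")),
               sort(sapply(oracle_clades(t1), paste, collapse = ",")))

  t2 <- ape::read.tree(text = "((A:1,B:1)69:1,C:1,D:1)100;")
  c2 <- collapse_low_support(t2, 70)
  expect_equal(c2$Nnode, 1L)          # star

  # absent support values are kept
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  c3 <- collapse_low_support(t3, 70)
  expect_equal(c3$Nnode, t3$Nnode)

  set.seed(301)
  for (rep in 1:15) {
    taxa <- sprintf("s%02d", 1:8)
    tr <- random_support_tree(taxa)
    col <- collapse_low_support(tr, 70)
    # oracle: surviving non-trivial clades = clades whose support >= 70
    sup <- suppressWarnings(as.numeric(tr$node.label))
    clades <- oracle_clades(tr)
    keep <- character(0)
    for (k in seq_along(clades)) {
      if (length(clades[[k]]) == length(taxa)) next   # root
      if (!is.na(sup[k]) && sup[k] < 70) next
      keep <- c(keep, paste(clades[[k]], collapse = ","))
    }
    got <- setdiff(sapply(oracle_clades(col), paste, collapse = ","),
                   paste(sort(taxa), collapse = ","))
    expect_setequal(got, keep)
    # tips untouched
    expect_setequal(col$tip.label, taxa)
  }
})

test_that("identical gene trees are concordant everywhere", {
  sp <- ape::read.tree(text =
    "(((((A:1,B:1)100:1,C:2)100:1,D:3)100:1,E:4)100:1,O:5)100;")
  genes <- replicate(7, sp, simplify = FALSE)
  res <- node_concordance(sp, genes)
  expect_true(all(res$nodes$n_concordant == 7))
  expect_true(all(res$nodes$n_main_alternative == 0))
  expect_true(all(res$nodes$n_other_alternative == 0))
  expect_true(all(res$nodes$ica == 1))
  expect_true(all(res$per_gene$n_conflicting_nodes == 0))
  # counts always sum to the number of gene trees
  s <- res$nodes$n_concordant + res$nodes$n_main_alternative +
    res$nodes$n_other_alternative + res$nodes$n_uninformative
  expect_true(all(s == 7))
})

test_that("a one-NNI gene tree conflicts exactly where the oracle says", {
  sp <- ape::read.tree(text =
    "(((((A:1,B:1)100:1,C:2)100:1,D:3)100:1,E:4)100:1,O:5)100;")
  # NNI at the (A,B) node: swap B and C
  gt <- ape::read.tree(text =
    "(((((A:1,C:1)100:1,B:2)100:1,D:3)100:1,E:4)100:1,O:5)100;")
  res <- node_concordance(sp, list(gt))

  # oracle: exhaustive comparison of every species clade against every
  # supported gene clade under the subset/incompatibility definitions
  sp_clades <- Filter(function(x)
    length(x) >= 2 && length(sp$tip.label) - length(x) >= 2,
    oracle_clades(sp))
  gt_clades <- Filter(function(x)
    length(x) >= 2 && length(x) < length(gt$tip.label),
    oracle_clades(gt))
  verdicts <- vapply(sp_clades, function(I) {
    if (any(vapply(gt_clades, function(h) setequal(h, I), logical(1))))
      return("concordant")
    inc <- any(vapply(gt_clades, function(h) {
      ov <- length(intersect(h, I))
      ov > 0 && ov < length(h) && ov < length(I)
    }, logical(1)))
    if (inc) "conflicting" else "uninformative"
  }, character(1))
  names(verdicts) <- sapply(sp_clades, paste, collapse = ",")

  got <- ifelse(res$nodes$n_concordant == 1, "concordant",
                ifelse(res$nodes$n_main_alternative +
                         res$nodes$n_other_alternative == 1,
                       "conflicting", "uninformative"))
  # match rows by ingroup via node ids
  clades <- scotags:::.node_clades(sp)
  keys <- sapply(res$nodes$node, function(n)
    paste(sort(clades[[n]]), collapse = ","))
  expect_setequal(paste(keys, got), paste(names(verdicts), verdicts))
  # the swapped node {A,B} conflicts; {A,B,C} itself is preserved by the
  # rearrangement and stays concordant
  expect_equal(keys[got == "conflicting"], "A,B")
  expect_equal(res$nodes$main_alternative[keys == "A,B"], "A,C")
  expect_equal(res$per_gene$n_conflicting_nodes, 1L)
})

test_that("bootstrap filter and missing taxa make genes uninformative", {
  sp <- ape::read.tree(text =
    "((((A:1,B:1)100:1,C:2)100:1,D:3)100:1,O:4)100;")
  # same topology but weakly supported at (A,B)
  gt_weak <- ape::read.tree(text =
    "((((A:1,B:1)50:1,C:2)100:1,D:3)100:1,O:4)100;")
  res <- node_concordance(sp, list(gt_weak), bs_filter = 70)
  clades <- scotags:::.node_clades(sp)
  keys <- sapply(res$nodes$node, function(n)
    paste(sort(clades[[n]]), collapse = ","))
  expect_equal(res$nodes$n_uninformative[keys == "A,B"], 1L)
  expect_equal(res$nodes$n_concordant[keys == "A,B,C"], 1L)

  # gene tree missing all but one ingroup taxon of a node: uninformative
  gt_miss <- ape::read.tree(text = "(((A:1,C:2)100:1,D:3)100:1,O:4)100;")
  res2 <- node_concordance(sp, list(gt_miss))
  keys2 <- sapply(res2$nodes$node, function(n)
    paste(sort(clades[[n]]), collapse = ","))
  expect_equal(res2$nodes$n_uninformative[keys2 == "A,B"], 1L)

  # taxa absent from the species tree are an error
  gt_bad <- ape::read.tree(text = "(((A:1,Z:2)100:1,D:3)100:1,O:4)100;")
  expect_error(node_concordance(sp, list(gt_bad)), "not in the species")
})

test_that("internode certainty matches the entropy formula", {
  expect_equal(internode_certainty_all(c(s = 10)), 1)
  expect_equal(internode_certainty_all(c(s = 50, h = 50)), 0)
  # direct-arithmetic oracle for a 0.7/0.2/0.1 split
  want <- 1 + (0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1)) / log(3)
  expect_equal(internode_certainty_all(c(s = 70, h1 = 20, h2 = 10)),
               want, tolerance = 1e-9)
  # clusters below min_frac are dropped (keeps the focal cluster)
  expect_equal(internode_certainty_all(c(s = 97, h = 3), min_frac = 0.05),
               1)
  # decreasing in evenness on 2-cluster splits
  vals <- sapply(seq(50, 95, by = 5), function(p)
    internode_certainty_all(c(s = p, h = 100 - p)))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(internode_certainty_all(numeric(0)), "empty")
})

test_that("quartet score is exact on identity and one-NNI trees", {
  sp <- ape::read.tree(text = "((((A,B),C),D),E);")
  expect_equal(normalized_quartet_score(sp, list(sp, sp)), 1)

  gt <- ape::read.tree(text = "((((A,C),B),D),E);")  # NNI at (A,B)
  got <- normalized_quartet_score(sp, list(gt))
  # oracle: enumerate all C(5,4) = 5 quartets by hand via induced trees
  quartets <- combn(sp$tip.label, 4)
  agree <- 0
  for (k in seq_len(ncol(quartets))) {
    q <- quartets[, k]
    is <- ape::keep.tip(sp, q); ig <- ape::keep.tip(gt, q)
    agree <- agree +
      (ape::dist.topo(ape::unroot(is), ape::unroot(ig)) == 0)
  }
  expect_equal(got, agree / 5)
  expect_equal(got, 3 / 5)   # quartets lacking B or C are unaffected
})

test_that("quartet score of random resolved trees approaches 1/3", {
  set.seed(302)
  sp <- ape::rtree(8, tip.label = LETTERS[1:8])
  genes <- replicate(1000, ape::rtree(8, tip.label = sample(LETTERS[1:8])),
                     simplify = FALSE)
  s <- normalized_quartet_score(sp, genes)
  expect_equal(s, 1 / 3, tolerance = 0.06)
  # invariant to gene order
  expect_equal(normalized_quartet_score(sp, rev(genes)), s)
})

test_that("quartet score degrades with increasing coalescent theta", {
  chron <- simulate_species_chronogram(8, seed = 41)
  scores <- sapply(c(0.01, 2, 20), function(th) {
    gts <- simulate_gene_trees_msc(chron, theta = th, n_trees = 60,
                                   seed = 42)
    normalized_quartet_score(chron, gts)
  })
  expect_equal(scores[1], 1, tolerance = 0.01)
  expect_true(all(diff(scores) < 0))
})
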