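# Shared fixture builders and independent oracles used across test files.

# minimal hit-table row
hit_row <- function(q, s, evalue = 1e-20, identity = 95, coverage = 100,
                    score = 100) {
  data.frame(query_id = q, subject_id = s, identity_pct = identity,
             aln_len = 100, mismatches = 0, gap_opens = 0,
             q_start = 1, q_end = 100, s_start = 1, s_end = 100,
             evalue = evalue, score = score,
             query_coverage_pct = coverage, stringsAsFactors = FALSE)
}

hit_table <- function(...) do.call(rbind, list(...))

random_hit_table <- function(n, n_q = 10, n_s = 10) {
  data.frame(
    query_id = sample(sprintf("q%02d", seq_len(n_q)), n, replace = TRUE),
    subject_id = sample(sprintf("s%02d", seq_len(n_s)), n, replace = TRUE),
    identity_pct = runif(n, 0, 100), aln_len = 100, mismatches = 0,
    gap_opens = 0, q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    evalue = 10^runif(n, -40, 1), score = runif(n, 10, 500),
    query_coverage_pct = runif(n, 0, 100), stringsAsFactors = FALSE)
}

random_aln <- function(n_taxa, n_cols, gap_frac = 0.1,
                       states = c("A", "C", "G", "T", "-")) {
  p <- c(rep((1 - gap_frac) / 4, 4), gap_frac)
  m <- matrix(sample(states, n_taxa * n_cols, replace = TRUE, prob = p),
              nrow = n_taxa,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)), NULL))
  multi_aln(m)
}

# independent brute-force PIS/variable counter (per-column table scan)
oracle_count_sites <- function(aln) {
  m <- unclass(aln)
  states <- c("A", "C", "G", "T", "-")
  nv <- 0L; np <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(factor(m[, j], levels = states))
    tab <- tab[tab > 0]
    if (length(tab) >= 2L) nv <- nv + 1L
    if (sum(tab >= 2L) >= 2L) np <- np + 1L
  }
  list(n_variable = nv, n_pis = np)
}

# independent smith-waterman with affine gaps (slow reference DP)
oracle_sw <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                      gap_ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (deletion from b's view)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext,
                   E[i, j - 1] - gap_ext)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext,
                   F[i - 1, j] - gap_ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# independent MCL reference: literal matrix iteration
oracle_mcl <- function(A, inflation = 3, iters = 60, prune = 1e-5) {
  loop <- apply(A, 2, max); loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M[M < prune] <- 0
    M <- sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  }
  adj <- (M > 0) | t(M > 0)
  n <- nrow(A)
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (v in seq_len(n)) new[v] <- min(comp[adj[v, ] | seq_len(n) == v])
    if (identical(new, comp)) break
    comp <- new
  }
  unname(split(rownames(A), comp))
}

# independent rooted-clade lister via ape::prop.part
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(i) sort(labs[i]))
}

# random supported binary tree
random_support_tree <- function(taxa, supports = NULL) {
  tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
  if (is.null(supports))
    supports <- sample(0:100, tr$Nnode, replace = TRUE)
  tr$node.label <- as.character(supports)
  tr
}
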