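#' Call single-copy genes from a filtered self-search
#'
#' A gene is single-copy when its filtered genome-vs-itself hit set consists
#' of exactly one hit, to itself.  Genes with additional hits (members of
#' multi-copy families) are excluded; genes with no hit at all (typically
#' lost to the similarity filter) are excluded and recorded in the
#' \code{"no_hit"} attribute of the result.
#'
#' @param self_hits filtered hit table of a proteome searched against itself
#'   (see [filter_hits()]).
#' @param genes character vector of all gene ids in the proteome.
#' @return character vector of single-copy gene ids, with attribute
#'   \code{no_hit} listing genes that had no filtered hit.
#' @export
call_single_copy <- function(self_hits, genes) {
  subj_by_query <- split(self_hits$subject_id, self_hits$query_id)
  single <- character(0)
  no_hit <- character(0)
  for (g in genes) {
    hs <- unique(subj_by_query[[g]])
    if (is.null(hs) || length(hs) == 0L) {
      no_hit <- c(no_hit, g)
    } else if (length(hs) == 1L && hs == g) {
      single <- c(single, g)
    }
  }
  structure(single, no_hit = no_hit)
}

# best subject per query under the ordering: highest score, then lowest
# e-value, then lexicographically smallest subject id
.best_hits <- function(hits) {
  if (nrow(hits) == 0L)
    return(stats::setNames(character(0), character(0)))
  o <- order(hits$query_id, -hits$score, hits$evalue, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  stats::setNames(h$subject_id[first], h$query_id[first])
}

#' Reciprocal best hits between two filtered searches
#'
#' A pair \code{(a, b)} is an ortholog candidate when \code{b} is \code{a}'s
#' best-scoring match in genome B and \code{a} is \code{b}'s best-scoring
#' match in genome A.  "Best" is the highest score; ties are broken by lower
#' e-value and then by lexicographic subject id, so the best match is always
#' uniquely determined.
#'
#' @param hits_ab filtered hit table, genome-A queries vs genome-B subjects.
#' @param hits_ba filtered hit table, genome-B queries vs genome-A subjects.
#' @return data.frame with columns \code{gene_a, gene_b, support}
#'   (\code{"rbb"}), one row per reciprocal pair, sorted by \code{gene_a}.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_ab <- .best_hits(hits_ab)
  best_ba <- .best_hits(hits_ba)
  a_ids <- names(best_ab)
  keep <- vapply(seq_along(a_ids), function(i) {
    b <- best_ab[[i]]
    !is.na(best_ba[b]) && !is.null(best_ba[[b]]) &&
      b %in% names(best_ba) && best_ba[[b]] == a_ids[i]
  }, logical(1))
  out <- data.frame(gene_a = a_ids[keep],
                    gene_b = unname(best_ab[keep]),
                    support = rep("rbb", sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a similarity graph from hit tables
#'
#' Nodes are sequence ids tagged with their genome of origin; undirected
#' edge weights are the maximum alignment score observed between the two
#' sequences in either direction.  Self-hits are dropped.
#'
#' @param hits one hit table or a list of hit tables to pool.
#' @param genome_of named character vector mapping every node id to its
#'   genome tag (e.g. \code{"A"} or \code{"B"}).
#' @return a \code{similarity_graph}: list with \code{nodes}, \code{genome}
#'   and an \code{edges} data.frame (\code{from, to, weight}).
#' @export
similarity_graph <- function(hits, genome_of) {
  if (is.data.frame(hits)) hits <- list(hits)
  h <- do.call(rbind, hits)
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  nodes <- sort(unique(names(genome_of)))
  if (nrow(h) > 0L) {
    miss <- setdiff(unique(c(h$query_id, h$subject_id)), nodes)
    if (length(miss) > 0L)
      stopf("genome_of lacks tags for: %s",
            paste(utils::head(miss, 5), collapse = ", "))
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    key <- paste(a, b, sep = "\r")
    w <- tapply(h$score, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stopf("edge weights must be finite and positive")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, genome = genome_of[nodes], edges = edges),
            class = "similarity_graph")
}

#' Markov clustering of a similarity graph
#'
#' Implements the MCL iteration on the column-stochastic transition matrix
#' of the graph: self-loops are added (weight = the node's maximum incident
#' edge weight, or 1 for isolated nodes), the matrix is column-normalized,
#' and expansion (matrix squaring), inflation (entrywise power followed by
#' column renormalization) and pruning of entries below \code{prune}
#' alternate until the largest entrywise change falls below \code{epsilon}
#' or \code{max_iter} is reached.  Clusters are the connected components of
#' the non-zero structure of the attractor matrix.
#'
#' @param graph a [similarity_graph()].
#' @param inflation inflation exponent (> 1); higher values give finer
#'   clusters.  Default 3.0, an intermediate stringency.
#' @param max_iter iteration cap (default 100).
#' @param epsilon convergence threshold on the max entry change.
#' @param prune entries below this are zeroed each iteration.
#' @return a \code{cluster_set}: list of character vectors (disjoint
#'   clusters) with attributes \code{inflation} and \code{converged}.
#' @export
markov_cluster <- function(graph, inflation = 3.0, max_iter = 100L,
                           epsilon = 1e-6, prune = 1e-5) {
  stopifnot(inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stopf("empty graph")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e) > 0L) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    A[cbind(i, j)] <- pmax(A[cbind(i, j)], e$weight)
    A[cbind(j, i)] <- pmax(A[cbind(j, i)], e$weight)
  }
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2[M2 < prune] <- 0                 # prune
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    if (max(abs(M2 - M)) < epsilon) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged)
    warning("Markov clustering did not converge within max_iter; ",
            "returning the current clustering")
  # connected components of the attractor's non-zero structure
  adj <- (M > 0) | (t(M) > 0)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  clusters <- unname(split(nodes, comp))
  structure(clusters, class = "cluster_set",
            inflation = inflation, converged = converged)
}

#' Intersect reciprocal-best-hit pairs with Markov clusters
#'
#' A pair \code{(a, b)} is cluster-supported when some cluster contains
#' exactly one genome-A gene and exactly one genome-B gene and those are
#' \code{a} and \code{b}.  The returned pairs are those supported by both
#' the reciprocal-best-hit test and the clustering.
#'
#' @param rbb data.frame from [reciprocal_best_hits()].
#' @param clusters a \code{cluster_set} from [markov_cluster()].
#' @param genome_of named character vector mapping gene ids to genome tags
#'   (\code{"A"}/\code{"B"}).
#' @return data.frame \code{gene_a, gene_b, support} with support
#'   \code{"rbb,mcl"}.
#' @export
shared_sco_set <- function(rbb, clusters, genome_of) {
  mcl_keys <- character(0)
  for (cl in clusters) {
    g <- genome_of[cl]
    if (length(cl) == 2L && sum(g == "A") == 1L && sum(g == "B") == 1L) {
      a <- cl[g == "A"]; b <- cl[g == "B"]
      mcl_keys <- c(mcl_keys, paste(a, b, sep = "\r"))
    }
  }
  keys <- paste(rbb$gene_a, rbb$gene_b, sep = "\r")
  out <- rbb[keys %in% mcl_keys, , drop = FALSE]
  if (nrow(out) > 0L) out$support <- "rbb,mcl"
  rownames(out) <- NULL
  out
}

#' End-to-end shared single-copy ortholog detection for two proteomes
#'
#' Runs the full ortholog-calling stage: all-vs-all self searches to call
#' single-copy genes in each proteome, cross searches restricted to the
#' single-copy sets, reciprocal best hits, Markov clustering of the pooled
#' cross-hit similarity graph, and the intersection of the two supports.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param max_evalue,min_identity,min_coverage similarity filter thresholds
#'   applied to every search (defaults \code{1e-10}, 30, 70).
#' @param inflation Markov clustering inflation (default 3.0).
#' @param seed_filter use the seeded-search speedup of
#'   [local_similarity_search()] (recommended for more than a few dozen
#'   sequences).
#' @return list with elements \code{pairs} (the shared SCO pairs), \code{rbb},
#'   \code{clusters}, \code{single_copy_a}, \code{single_copy_b}.
#' @export
find_shared_scos <- function(proteome_a, proteome_b,
                             max_evalue = 1e-10, min_identity = 30,
                             min_coverage = 70, inflation = 3.0,
                             seed_filter = TRUE) {
  flt <- function(h) filter_hits(h, max_evalue, min_identity, min_coverage)
  self_a <- flt(local_similarity_search(proteome_a, proteome_a,
                                        type = "protein",
                                        seed_filter = seed_filter))
  self_b <- flt(local_similarity_search(proteome_b, proteome_b,
                                        type = "protein",
                                        seed_filter = seed_filter))
  sc_a <- call_single_copy(self_a, names(proteome_a))
  sc_b <- call_single_copy(self_b, names(proteome_b))
  pa <- proteome_a[sc_a]; pb <- proteome_b[sc_b]
  hits_ab <- flt(local_similarity_search(pa, pb, type = "protein",
                                         seed_filter = seed_filter))
  hits_ba <- flt(local_similarity_search(pb, pa, type = "protein",
                                         seed_filter = seed_filter))
  rbb <- reciprocal_best_hits(hits_ab, hits_ba)
  genome_of <- stats::setNames(c(rep("A", length(sc_a)),
                                 rep("B", length(sc_b))),
                               c(as.character(sc_a), as.character(sc_b)))
  graph <- similarity_graph(list(hits_ab, hits_ba), genome_of)
  clusters <- markov_cluster(graph, inflation = inflation)
  pairs <- shared_sco_set(rbb, clusters, genome_of)
  list(pairs = pairs, rbb = rbb, clusters = clusters,
       single_copy_a = as.character(sc_a), single_copy_b = as.character(sc_b))
}

#' Write ortholog pairs as TSV
#' @param pairs data.frame \code{gene_a, gene_b, support}.
#' @param path output file.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
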