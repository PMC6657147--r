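# --- tree utilities ---------------------------------------------------------

# tip-label sets of the clade below each internal node (node number ->
# character vector), computed by postorder accumulation
.node_clades <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; chd <- tree$edge[k, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  sets
}

# numeric support of each internal node from node labels (NA when absent)
.node_supports <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  length(sup) <- tree$Nnode
  sup
}

# does the (possibly unrooted) tree contain a split separating `taxa` from
# the rest?  singletons and complements of singletons always do.
.has_split <- function(tree, taxa) {
  tips <- tree$tip.label
  if (length(taxa) <= 1L || length(setdiff(tips, taxa)) <= 1L) return(TRUE)
  key <- taxon_set_key(taxa)
  comp_key <- taxon_set_key(setdiff(tips, taxa))
  ntip <- ape::Ntip(tree)
  clades <- .node_clades(tree)
  for (n in (ntip + 1L):(ntip + tree$Nnode)) {
    k <- taxon_set_key(clades[[n]])
    if (k == key || k == comp_key) return(TRUE)
  }
  FALSE
}

#' Root a gene tree on its outgroup
#'
#' Roots the tree on the branch subtending the outgroup taxa present in the
#' tree.  If those taxa are not monophyletic in the unrooted tree a typed
#' error of class \code{scotags_outgroup_error} is raised so the caller can
#' discard the tree; a single outgroup taxon roots on its pendant edge.
#'
#' @param tree a \code{phylo} tree (support values in node labels are
#'   preserved).
#' @param outgroup_taxa character vector of outgroup taxon labels.
#' @return the rooted \code{phylo} tree.
#' @export
root_on_outgroup <- function(tree, outgroup_taxa) {
  present <- intersect(outgroup_taxa, tree$tip.label)
  if (length(present) == 0L)
    stop(structure(class = c("scotags_outgroup_error", "error",
                             "condition"),
                   list(message = "no outgroup taxon present in the tree",
                        call = NULL)))
  if (!.has_split(ape::unroot(tree), present))
    stop(structure(class = c("scotags_outgroup_error", "error",
                             "condition"),
                   list(message = paste0(
                     "outgroup taxa are not monophyletic: ",
                     paste(present, collapse = ", ")), call = NULL)))
  ingroup <- setdiff(tree$tip.label, present)
  # reroot at an ingroup tip first so the outgroup cannot straddle the
  # stored root trifurcation, then root on the outgroup clade
  t2 <- ape::root(ape::unroot(tree), outgroup = ingroup[1L],
                  resolve.root = TRUE)
  ape::root(t2, outgroup = present, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal branch whose support value is below
#' \code{threshold}; branches with no support value are kept.  Tips and
#' branch lengths of surviving edges are untouched.
#'
#' @param tree a \code{phylo} tree with support values in its node labels.
#' @param threshold numeric support threshold (default 70).
#' @return the collapsed \code{phylo} tree (may contain polytomies).
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  ntip <- ape::Ntip(tree)
  sup <- .node_supports(tree)
  root <- ntip + 1L
  drop_node <- function(n) {
    n > ntip && n != root && !is.na(sup[n - ntip]) &&
      sup[n - ntip] < threshold
  }
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- if (is.null(tree$edge.length)) NULL else
    stats::setNames(tree$edge.length, tree$edge[, 2L])
  lab <- tree$node.label
  build <- function(n) {
    if (n <= ntip) return(tree$tip.label[n])
    parts <- character(0)
    stack <- children[[as.character(n)]]
    while (length(stack) > 0L) {
      c1 <- stack[1L]; stack <- stack[-1L]
      if (drop_node(c1)) {
        stack <- c(children[[as.character(c1)]], stack)  # splice up
      } else {
        s <- build(c1)
        if (!is.null(elen))
          s <- paste0(s, ":", format(elen[[as.character(c1)]],
                                     digits = 15))
        parts <- c(parts, s)
      }
    }
    nl <- if (!is.null(lab) && n - ntip <= length(lab))
      lab[n - ntip] else ""
    paste0("(", paste(parts, collapse = ","), ")", nl)
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

# rooted bipartitions of a gene tree: ingroup clusters of size >= 2,
# excluding the root's trivial all-taxa cluster, with supports
.tree_bipartitions <- function(tree, missing_support = 100) {
  ntip <- ape::Ntip(tree)
  clades <- .node_clades(tree)
  sup <- .node_supports(tree)
  root <- ntip + 1L
  out <- list()
  for (n in (ntip + 1L):(ntip + tree$Nnode)) {
    if (n == root) next
    cl <- clades[[n]]
    if (length(cl) < 2L || length(cl) >= ntip) next
    s <- sup[n - ntip]
    if (is.na(s)) s <- missing_support
    out[[length(out) + 1L]] <- list(ingroup = cl, support = s)
  }
  out
}

#' Per-node concordance and conflict between gene trees and a species tree
#'
#' For every internal node of the rooted species tree with ingroup
#' \code{I}, each rooted gene tree is classified against the node after
#' restricting \code{I} to the gene tree's taxa: the gene is concordant
#' when one of its bipartitions with support at least \code{bs_filter} has
#' exactly that restricted ingroup; conflicting when no such match exists
#' but some filtered bipartition is incompatible with the restricted
#' ingroup (overlapping, neither containing the other); and uninformative
#' otherwise (including when fewer than two ingroup or two outgroup taxa
#' remain).  The main alternative at a node is the most frequent
#' conflicting ingroup set across genes (ties broken by the
#' lexicographically smallest taxon-set string); conflicting genes not
#' supporting it count as other alternatives.  Internode certainty (ICA)
#' is computed per node from the concordant count and the conflicting
#' cluster counts.
#'
#' @param species_tree rooted \code{phylo} species tree.
#' @param gene_trees list of rooted \code{phylo} gene trees with bootstrap
#'   supports in node labels; taxa must be subsets of the species-tree
#'   taxa.
#' @param bs_filter bootstrap threshold for gene-tree bipartitions
#'   (default 70).
#' @param missing_support support assumed for unlabeled gene-tree branches
#'   (default 100, appropriate when low-support branches were collapsed
#'   upstream).
#' @param ica_min_frac cluster inclusion threshold passed to
#'   [internode_certainty_all()].
#' @return list with \code{nodes} (data.frame: \code{node, ingroup_size,
#'   n_concordant, n_main_alternative, n_other_alternative,
#'   n_uninformative, ica, main_alternative}) and \code{per_gene}
#'   (data.frame: \code{gene, n_concordant_nodes, n_conflicting_nodes}).
#' @export
node_concordance <- function(species_tree, gene_trees, bs_filter = 70,
                             missing_support = 100, ica_min_frac = 0.05) {
  sp_taxa <- species_tree$tip.label
  ntip <- ape::Ntip(species_tree)
  clades <- .node_clades(species_tree)
  root <- ntip + 1L
  # evaluable nodes: at least two ingroup and two outgroup taxa in the
  # species tree (smaller complements can never be informative)
  node_ids <- setdiff((ntip + 1L):(ntip + species_tree$Nnode), root)
  node_ids <- node_ids[vapply(node_ids, function(n)
    length(clades[[n]]) >= 2L && ntip - length(clades[[n]]) >= 2L,
    logical(1))]

  gt_bips <- vector("list", length(gene_trees))
  gt_taxa <- vector("list", length(gene_trees))
  for (g in seq_along(gene_trees)) {
    gt <- gene_trees[[g]]
    extra <- setdiff(gt$tip.label, sp_taxa)
    if (length(extra) > 0L)
      stopf("gene tree %d has taxa not in the species tree: %s",
            g, paste(extra, collapse = ", "))
    gt_taxa[[g]] <- gt$tip.label
    bips <- .tree_bipartitions(gt, missing_support)
    gt_bips[[g]] <- Filter(function(b) b$support >= bs_filter, bips)
  }

  n_conc_gene <- integer(length(gene_trees))
  n_conf_gene <- integer(length(gene_trees))
  node_rows <- list()
  for (n in node_ids) {
    I <- clades[[n]]
    n_conc <- 0L; n_uninf <- 0L
    conflict_counts <- list()     # taxon_set_key -> count over genes
    n_conf <- 0L
    for (g in seq_along(gene_trees)) {
      Tg <- gt_taxa[[g]]
      Ip <- intersect(I, Tg)
      if (length(Ip) < 2L || length(setdiff(Tg, Ip)) < 2L) {
        n_uninf <- n_uninf + 1L
        next
      }
      key_I <- taxon_set_key(Ip)
      concordant <- FALSE
      incompat <- character(0)
      for (b in gt_bips[[g]]) {
        h <- b$ingroup
        if (taxon_set_key(h) == key_I) {
          concordant <- TRUE
          break
        }
        ov <- length(intersect(h, Ip))
        if (ov > 0L && ov < length(h) && ov < length(Ip))
          incompat <- c(incompat, taxon_set_key(h))
      }
      if (concordant) {
        n_conc <- n_conc + 1L
        n_conc_gene[g] <- n_conc_gene[g] + 1L
      } else if (length(incompat) > 0L) {
        n_conf <- n_conf + 1L
        n_conf_gene[g] <- n_conf_gene[g] + 1L
        for (k in unique(incompat))
          conflict_counts[[k]] <- (conflict_counts[[k]] %||% 0L) + 1L
      } else {
        n_uninf <- n_uninf + 1L
      }
    }
    if (length(conflict_counts) > 0L) {
      cc <- unlist(conflict_counts)
      main_key <- names(cc)[order(-cc, names(cc))][1L]
      n_main <- 0L
      # count genes whose incompatible set includes the main alternative
      for (g in seq_along(gene_trees)) {
        Tg <- gt_taxa[[g]]
        Ip <- intersect(I, Tg)
        if (length(Ip) < 2L || length(setdiff(Tg, Ip)) < 2L) next
        key_I <- taxon_set_key(Ip)
        conc <- any(vapply(gt_bips[[g]], function(b)
          taxon_set_key(b$ingroup) == key_I, logical(1)))
        if (conc) next
        if (any(vapply(gt_bips[[g]], function(b) {
          h <- b$ingroup
          ov <- length(intersect(h, Ip))
          ov > 0L && ov < length(h) && ov < length(Ip) &&
            taxon_set_key(h) == main_key
        }, logical(1)))) n_main <- n_main + 1L
      }
      n_other <- n_conf - n_main
    } else {
      main_key <- NA_character_
      n_main <- 0L; n_other <- 0L
    }
    counts <- c(stats::setNames(n_conc, taxon_set_key(I)),
                unlist(conflict_counts))
    ica <- internode_certainty_all(counts, focal = taxon_set_key(I),
                                   min_frac = ica_min_frac)
    node_rows[[length(node_rows) + 1L]] <- data.frame(
      node = n, ingroup_size = length(I), n_concordant = n_conc,
      n_main_alternative = n_main, n_other_alternative = n_other,
      n_uninformative = n_uninf, ica = ica,
      main_alternative = main_key, stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, node_rows)
  rownames(nodes) <- NULL
  list(nodes = nodes,
       per_gene = data.frame(gene = seq_along(gene_trees),
                             n_concordant_nodes = n_conc_gene,
                             n_conflicting_nodes = n_conf_gene))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internode Certainty All
#'
#' Entropy-based certainty of a species-tree node given the frequencies of
#' its cluster and of the conflicting clusters observed across gene trees.
#' The focal (species-tree) cluster is always retained; conflicting
#' clusters are retained when their relative frequency is at least
#' \code{min_frac}.  Retained counts are normalized to probabilities
#' \code{p_i} over \code{n} clusters and
#' \code{ICA = 1 + sum(p_i log_n(p_i))}; a single retained cluster gives
#' 1, an even two-way split gives 0.
#'
#' @param counts named numeric vector: cluster key -> count; must include
#'   the focal cluster (its count may be 0).
#' @param focal name of the species-tree cluster (default: first element).
#' @param min_frac inclusion threshold on relative frequency (default
#'   0.05).
#' @return ICA value in \code{(-1, 1]}.
#' @export
internode_certainty_all <- function(counts, focal = names(counts)[1L],
                                    min_frac = 0.05) {
  if (length(counts) == 0L) stopf("empty frequency map")
  if (!(focal %in% names(counts)))
    stopf("focal cluster '%s' not present in the frequency map", focal)
  total <- sum(counts)
  keep <- names(counts) == focal |
    (if (total > 0) counts / total >= min_frac else FALSE)
  kept <- counts[keep]
  n <- length(kept)
  if (n == 1L) return(1)
  s <- sum(kept)
  if (s == 0) return(1)
  p <- kept / s
  p <- p[p > 0]
  1 + sum(p * log(p, base = n))
}

# topological (unit-branch-length) cophenetic distances
.topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  ape::cophenetic.phylo(t2)
}

# resolved quartet pairing for all 4-subsets at once; returns integer code
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved; quartets given as a
# 4 x K matrix of tip labels
.quartet_codes <- function(D, q) {
  s1 <- D[cbind(q[1L, ], q[2L, ])] + D[cbind(q[3L, ], q[4L, ])]
  s2 <- D[cbind(q[1L, ], q[3L, ])] + D[cbind(q[2L, ], q[4L, ])]
  s3 <- D[cbind(q[1L, ], q[4L, ])] + D[cbind(q[2L, ], q[3L, ])]
  m <- pmin(s1, s2, s3)
  code <- integer(ncol(q))
  uniq1 <- (s1 == m) + (s2 == m) + (s3 == m) == 1L
  code[uniq1 & s1 == m] <- 1L
  code[uniq1 & s2 == m] <- 2L
  code[uniq1 & s3 == m] <- 3L
  code
}

#' Normalized quartet score of gene trees against a species tree
#'
#' Over all gene trees and all four-taxon subsets of the taxa a gene tree
#' shares with the species tree: a quartet enters the denominator when both
#' induced quartet topologies are resolved, and the numerator when they
#' agree.  The score is the fraction of agreeing resolved quartets.
#'
#' @param species_tree a \code{phylo} tree.
#' @param gene_trees list of \code{phylo} trees (taxa subsets of the
#'   species tree; trees sharing fewer than 4 taxa contribute nothing).
#' @return score in \code{[0, 1]}.
#' @export
normalized_quartet_score <- function(species_tree, gene_trees) {
  Dsp <- .topo_dist(species_tree)
  num <- 0; den <- 0
  for (gt in gene_trees) {
    shared <- intersect(gt$tip.label, species_tree$tip.label)
    if (length(shared) < 4L) next
    q <- utils::combn(shared, 4L)
    Dg <- .topo_dist(gt)
    cs <- .quartet_codes(Dsp, q)
    cg <- .quartet_codes(Dg, q)
    both <- cs > 0L & cg > 0L
    den <- den + sum(both)
    num <- num + sum(both & cs == cg)
  }
  if (den == 0) stopf("no scorable quartet among the gene trees")
  num / den
}

#' Write a per-node conflict summary as TSV
#' @param conc result of [node_concordance()].
#' @param path output file for the per-node table.
#' @param per_gene_path optional output file for the per-gene table.
#' @export
write_conflict_report <- function(conc, path, per_gene_path = NULL) {
  utils::write.table(conc$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(per_gene_path))
    utils::write.table(conc$per_gene, per_gene_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
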