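# Synthetic-data generators.  Every generator is a pure function of its
# arguments and an explicit seed: the caller's global RNG state is never
# consulted or modified.

#' Simulate a species chronogram
#'
#' A pure-birth (Yule) tree conditioned on the number of tips, rescaled so
#' the crown height equals \code{crown_age}; ultrametric by construction.
#'
#' @param n_taxa number of species (>= 3).
#' @param crown_age crown height in My (default 30).
#' @param birth_rate speciation rate (per lineage per My; only the shape
#'   of the tree depends on it once rescaled).
#' @param seed integer seed.
#' @return an ultrametric \code{phylo} tree with tips \code{sp01, sp02,
#'   ...}.
#' @export
simulate_species_chronogram <- function(n_taxa, crown_age = 30,
                                        birth_rate = 0.2, seed = 1L) {
  stopifnot(n_taxa >= 3L)
  with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
    tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    calibrate_chronogram(tr, crown_age = crown_age)
  })
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Samples one haploid lineage per species and coalesces lineages within
#' the branches of the chronogram: within a population of scaled size
#' \code{theta}, \code{k} lineages coalesce with exponential waiting times
#' of rate \code{choose(k, 2) / theta}.  Small \code{theta} forces every
#' coalescence into its species branch, so gene trees match the species
#' topology; large \code{theta} produces deep coalescence (incomplete
#' lineage sorting).  All branch supports are set to 100.
#'
#' @param chron ultrametric \code{phylo} chronogram.
#' @param theta coalescent population-size parameter, in the chronogram's
#'   time units.
#' @param n_trees number of gene trees.
#' @param seed integer seed.
#' @return list of rooted \code{phylo} gene trees.
#' @export
simulate_gene_trees_msc <- function(chron, theta, n_trees, seed = 1L) {
  stopifnot(theta >= 0)
  ntip <- ape::Ntip(chron)
  depths <- ape::node.depth.edgelength(chron)
  h <- max(depths[seq_len(ntip)])
  age <- h - depths                      # node ages before present
  tree_po <- ape::reorder.phylo(chron, "postorder")
  children <- split(tree_po$edge[, 2L], tree_po$edge[, 1L])
  root <- ntip + 1L
  # species-tree nodes in increasing age order (tips first)
  internal_by_age <- order(age[(ntip + 1L):(ntip + chron$Nnode)]) + ntip

  sim_one <- function() {
    # lineages per species-tree node: list of (newick, height)
    lin <- vector("list", ntip + chron$Nnode)
    for (i in seq_len(ntip))
      lin[[i]] <- list(list(nwk = chron$tip.label[i], h = 0))
    coalesce_in <- function(lins, t_start, t_end) {
      t <- t_start
      while (length(lins) > 1L) {
        k <- length(lins)
        rate <- k * (k - 1) / 2 / theta
        w <- if (theta == 0) 0 else stats::rexp(1L, rate)
        if (t + w > t_end) break
        t <- t + w
        pick <- sample.int(k, 2L)
        a <- lins[[pick[1L]]]; b <- lins[[pick[2L]]]
        merged <- list(
          nwk = sprintf("(%s:%.10g,%s:%.10g)100",
                        a$nwk, t - a$h, b$nwk, t - b$h),
          h = t)
        lins <- c(lins[-pick], list(merged))
      }
      lins
    }
    for (n in internal_by_age) {
      ch <- children[[as.character(n)]]
      incoming <- list()
      for (cd in ch) {
        l <- lin[[cd]]
        l <- coalesce_in(l, age[cd], age[n])
        incoming <- c(incoming, l)
      }
      lin[[n]] <- incoming
    }
    final <- coalesce_in(lin[[root]], age[root], Inf)
    ape::read.tree(text = paste0(final[[1L]]$nwk, ";"))
  }
  with_seed(seed, lapply(seq_len(n_trees), function(i) sim_one()))
}

#' Evolve a nucleotide alignment on a tree with per-site rates
#'
#' Sites evolve independently under JC69 along the tree's branches (branch
#' lengths in My, rates in substitutions/site/My).  Per-site rates are
#' either supplied directly or drawn from a gamma distribution.  Optional
#' indels gap a random taxon subset at randomly chosen columns, to
#' exercise gap-aware column statistics.
#'
#' @param tree \code{phylo} tree with branch lengths.
#' @param n_sites number of alignment columns.
#' @param rate_distribution list with \code{shape} and \code{mean} of the
#'   gamma rate distribution (subst/site/My); ignored when \code{rates} is
#'   given.
#' @param rates optional explicit per-site rate vector (length
#'   \code{n_sites}).
#' @param root_seq optional root sequence (length \code{n_sites}); random
#'   when \code{NULL}.
#' @param indel_rate expected fraction of columns receiving a gap block.
#' @param seed integer seed.
#' @return list with \code{aln} (a [multi_aln()]) and \code{rates} (the
#'   true per-site rates).
#' @export
evolve_alignment <- function(tree, n_sites,
                             rate_distribution = list(shape = 0.5,
                                                      mean = 0.01),
                             rates = NULL, root_seq = NULL,
                             indel_rate = 0, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    if (is.null(rates))
      rates <- stats::rgamma(n_sites, shape = rate_distribution$shape,
                             rate = rate_distribution$shape /
                               rate_distribution$mean)
    stopifnot(length(rates) == n_sites, all(rates >= 0))
    tree_pre <- ape::reorder.phylo(tree, "cladewise")
    ntip <- ape::Ntip(tree)
    root <- ntip + 1L
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_sites)
    states[root, ] <- if (is.null(root_seq))
      sample.int(4L, n_sites, replace = TRUE)
    else match(strsplit(toupper(root_seq), "", fixed = TRUE)[[1]], bases)
    for (k in seq_len(nrow(tree_pre$edge))) {
      par <- tree_pre$edge[k, 1L]; chd <- tree_pre$edge[k, 2L]
      t <- tree_pre$edge.length[k]
      p_same <- .jc69_psame(rates, t)
      u <- stats::runif(n_sites)
      same <- u < p_same
      cur <- states[par, ]
      nxt <- cur
      chg <- which(!same)
      if (length(chg) > 0L) {
        # uniform choice among the three other bases
        shift <- sample.int(3L, length(chg), replace = TRUE)
        nxt[chg] <- ((cur[chg] - 1L + shift) %% 4L) + 1L
      }
      states[chd, ] <- nxt
    }
    m <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
    rownames(m) <- tree$tip.label
    if (indel_rate > 0) {
      gap_cols <- which(stats::runif(n_sites) < indel_rate)
      for (j in gap_cols) {
        k <- sample.int(ntip - 1L, 1L)
        rows <- sample.int(ntip, k)
        m[rows, j] <- "-"
      }
    }
    list(aln = multi_aln(m), rates = rates)
  })
}

# random CDS of `n_codons` sense codons (no stop), returned as DNA string
.random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1L, paste,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-mutate a DNA/protein string at per-position rate `rate`
.mutate_seq <- function(seq, rate, alphabet) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Build a synthetic proteome pair with planted orthologs and paralogs
#'
#' Emits two proteomes, a reference genome with gene models, and the
#' ground truth.  Each planted single-copy ortholog is present exactly
#' once per genome (the genome-B copy diverged from the genome-A copy at
#' the given rate); each paralog family contributes \code{family_size}
#' diverged copies to both genomes, so family members fail the unique
#' self-hit test.  Every SCO gene carries a 3-exon gene model with UTRs on
#' its genome contig, so coding, non-coding and mixed tag classes are all
#' realizable.
#'
#' @param n_sco number of planted single-copy orthologs.
#' @param n_paralog_families number of planted multi-copy families.
#' @param family_size copies per paralog family per genome (>= 2).
#' @param divergence per-residue substitution rate between genome-A and
#'   genome-B orthologs (default 0.1).
#' @param seed integer seed.
#' @return list with \code{proteome_a}, \code{proteome_b} (named character
#'   vectors), \code{genome_a} (named contig sequences),
#'   \code{gene_models} (data.frame: \code{contig, type, start, end} in
#'   1-based closed GFF-style coordinates), and \code{truth} (list with
#'   \code{sco_pairs} and \code{paralog_genes}).
#' @export
build_proteome_pair <- function(n_sco, n_paralog_families = 0L,
                                family_size = 2L, divergence = 0.1,
                                seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    prot_a <- character(0); prot_b <- character(0)
    contigs <- character(0)
    gm <- list()
    sco_pairs <- data.frame(gene_a = character(), gene_b = character(),
                            stringsAsFactors = FALSE)
    for (i in seq_len(n_sco)) {
      ga <- sprintf("A_sco%04d", i); gb <- sprintf("B_sco%04d", i)
      n_cod <- sample(60:120, 1L)
      ex_cod <- c(ceiling(n_cod / 3), ceiling(n_cod / 3))
      ex_cod <- c(ex_cod, n_cod - sum(ex_cod))
      exons <- vapply(ex_cod, function(k) .random_cds(k), character(1))
      utr5 <- .random_dna(30L); utr3 <- .random_dna(30L)
      intr1 <- .random_dna(sample(60:120, 1L))
      intr2 <- .random_dna(sample(60:120, 1L))
      contig <- paste0(utr5, exons[1L], intr1, exons[2L], intr2,
                       exons[3L], utr3)
      ct <- sprintf("chrA_%s", ga)
      contigs[ct] <- contig
      # gene model, 1-based closed coordinates
      p <- cumsum(c(30L, nchar(exons[1L]), nchar(intr1),
                    nchar(exons[2L]), nchar(intr2), nchar(exons[3L]),
                    30L))
      gm[[length(gm) + 1L]] <- data.frame(
        contig = ct,
        type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
                 "intron", "CDS", "three_prime_UTR"),
        start = c(1L, 1L, 31L, p[2L] + 1L, p[3L] + 1L, p[4L] + 1L,
                  p[5L] + 1L, p[6L] + 1L),
        end = c(nchar(contig), 30L, p[2L], p[3L], p[4L], p[5L], p[6L],
                p[7L]),
        gene = ga, stringsAsFactors = FALSE)
      cds <- paste(exons, collapse = "")
      prot_a[ga] <- .translate(cds)
      cds_b <- .mutate_seq(cds, divergence, c("A", "C", "G", "T"))
      pb <- .translate(cds_b)
      pb <- gsub("*", sample(aa, 1L), pb, fixed = TRUE)  # no stops
      prot_b[gb] <- pb
      sco_pairs <- rbind(sco_pairs,
                         data.frame(gene_a = ga, gene_b = gb,
                                    stringsAsFactors = FALSE))
    }
    paralog_genes <- character(0)
    for (f in seq_len(n_paralog_families)) {
      base <- .translate(.random_cds(sample(60:120, 1L)))
      for (k in seq_len(family_size)) {
        ga <- sprintf("A_par%03d_%d", f, k)
        gb <- sprintf("B_par%03d_%d", f, k)
        prot_a[ga] <- .mutate_seq(base, 0.05, aa)
        prot_b[gb] <- .mutate_seq(base, 0.05, aa)
        paralog_genes <- c(paralog_genes, ga, gb)
      }
    }
    gene_models <- do.call(rbind, gm)
    list(proteome_a = prot_a, proteome_b = prot_b, genome_a = contigs,
         gene_models = gene_models,
         truth = list(sco_pairs = sco_pairs,
                      paralog_genes = paralog_genes))
  })
}

#' Generate allelic contigs for one locus
#'
#' Produces \code{ploidy} allele sequences by mutating the locus at the
#' heterozygosity rate, plus optional contaminant paralog contigs diverged
#' at a much higher rate (15 percent).
#'
#' @param locus_seq locus DNA sequence.
#' @param ploidy number of alleles to emit (>= 1).
#' @param heterozygosity per-site allele mutation rate.
#' @param n_extra_contaminants number of contaminant contigs.
#' @param seed integer seed.
#' @return named character vector of contigs with attribute
#'   \code{true_allele_count} (distinct alleles among the non-contaminant
#'   sequences).
#' @export
make_allelic_contigs <- function(locus_seq, ploidy,
                                 heterozygosity = 0.002,
                                 n_extra_contaminants = 0L, seed = 1L) {
  stopifnot(ploidy >= 1L)
  dna <- c("A", "C", "G", "T")
  with_seed(seed, {
    alleles <- vapply(seq_len(ploidy), function(k)
      .mutate_seq(locus_seq, heterozygosity, dna), character(1))
    names(alleles) <- sprintf("allele%d", seq_len(ploidy))
    contam <- if (n_extra_contaminants > 0L)
      stats::setNames(vapply(seq_len(n_extra_contaminants), function(k)
        .mutate_seq(locus_seq, 0.15, dna), character(1)),
        sprintf("contam%d", seq_len(n_extra_contaminants)))
    else character(0)
    out <- c(alleles, contam)
    attr(out, "true_allele_count") <- length(unique(alleles))
    out
  })
}

# sample a conserved flank that admits at least one valid primer of the
# given side; bounded resampling keeps the generator deterministic
.sample_primer_flank <- function(len, side, cons, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    fl <- .random_dna(len)
    if (length(.primer_candidates(fl, cons, side)) > 0L) return(fl)
  }
  stopf("could not sample a %s primer flank in %d tries", side, max_tries)
}

#' Simulate a complete tag-mining study with known ground truth
#'
#' Builds everything the pipeline consumes: a species chronogram, a
#' proteome pair with planted orthologs (and optional paralog decoys), one
#' locus per SCO with a conserved-flank / variable-core tag architecture,
#' per-locus true multi-species alignments evolved on the chronogram,
#' per-species assembled contigs (with optional extra alleles or
#' contaminants), multispecies-coalescent gene trees per locus, and the
#' ground truth of every planted feature.
#'
#' Locus architecture (columns, 0-based): \code{[pre | left flank | core |
#' right flank | post]} where the flanks evolve at rate 0 (perfectly
#' conserved, so conserved primers exist by construction) and the core and
#' padding evolve at the locus rate.
#'
#' @param n_sco number of planted SCO loci.
#' @param n_taxa number of ingroup species in the chronogram.
#' @param n_paralog_families paralog decoy families for the orthology
#'   stage.
#' @param crown_age chronogram crown age in My (default 30).
#' @param core_rate mean substitution rate of the variable core
#'   (subst/site/My).
#' @param theta coalescent parameter for the per-locus gene trees.
#' @param flank_len,core_len,pad_len architecture segment lengths.
#' @param heterozygosity per-site allele divergence within a species.
#' @param ploidy ploidy assigned to every simulated species assembly.
#' @param duplicate_locus indices of SCO loci whose reference genome
#'   receives an exact duplicated copy of the locus (a segmental-
#'   duplication decoy: the tag fails primer specificity and the
#'   reciprocal-best test).
#' @param extra_allele_locus indices of SCO loci for which one non-
#'   reference species receives a contaminant contig, so the allele count
#'   exceeds the ploidy.
#' @param seed integer seed.
#' @return list with components \code{chronogram}, \code{proteomes} (the
#'   [build_proteome_pair()] output), \code{alignments} (per-SCO
#'   [multi_aln()]), \code{gene_trees}, \code{ref_genome} (named contig
#'   per locus, reference-species sequences), \code{gene_models}
#'   (per-locus feature data.frame in reference coordinates),
#'   \code{assemblies} (per species: named contig vectors), \code{ploidy}
#'   (named integer vector), \code{ref_species}, \code{anchors} (the
#'   reference species plus the most divergent species), and \code{truth}
#'   (planted tag intervals, site rates, SCO pairs, decoy loci).
#' @export
simulate_study <- function(n_sco = 5L, n_taxa = 8L,
                           n_paralog_families = 0L, crown_age = 30,
                           core_rate = 0.004, theta = 0.5,
                           flank_len = 60L, core_len = 350L,
                           pad_len = 40L, heterozygosity = 0,
                           ploidy = 2L, duplicate_locus = integer(0),
                           extra_allele_locus = integer(0),
                           seed = 1L) {
  cons <- primer_constraints()
  chron <- simulate_species_chronogram(n_taxa, crown_age = crown_age,
                                       seed = seed + 1L)
  prot <- build_proteome_pair(n_sco, n_paralog_families, seed = seed + 2L)
  gene_trees <- simulate_gene_trees_msc(chron, theta = theta,
                                        n_trees = n_sco, seed = seed + 3L)
  alignments <- list()
  assemblies <- stats::setNames(
    replicate(n_taxa, character(0), simplify = FALSE), chron$tip.label)
  ref_genome <- character(0)
  gene_models <- list()
  tag_truth <- list()
  rates_truth <- list()
  ref_species <- chron$tip.label[1L]
  decoy_species <- chron$tip.label[2L]
  D <- ape::cophenetic.phylo(chron)
  anchors <- c(ref_species, names(which.max(D[ref_species, ])))
  n_sites <- 2L * pad_len + 2L * flank_len + core_len
  for (i in seq_len(n_sco)) {
    sco_id <- prot$truth$sco_pairs$gene_a[i]
    fl_l <- with_seed(seed + 10L + i,
                      .sample_primer_flank(flank_len, "left", cons))
    fl_r <- with_seed(seed + 400L + i,
                      .sample_primer_flank(flank_len, "right", cons))
    root_seq <- paste0(.dna_or_empty(seed + 800L + i, pad_len), fl_l,
                       .dna_or_empty(seed + 1200L + i, core_len), fl_r,
                       .dna_or_empty(seed + 1600L + i, pad_len))
    rates <- rep(core_rate, n_sites)
    fl1 <- (pad_len + 1L):(pad_len + flank_len)
    fl2 <- (pad_len + flank_len + core_len + 1L):
      (pad_len + 2L * flank_len + core_len)
    rates[c(fl1, fl2)] <- 0
    ev <- evolve_alignment(chron, n_sites, rates = rates,
                           root_seq = root_seq, seed = seed + 2000L + i)
    aln <- ev$aln
    attr(aln, "locus_id") <- sco_id
    alignments[[sco_id]] <- aln
    rates_truth[[sco_id]] <- ev$rates
    tag_truth[[sco_id]] <- list(core_start = pad_len + flank_len,
                                core_end = pad_len + flank_len + core_len,
                                flank_left = c(pad_len, pad_len + flank_len),
                                flank_right = c(pad_len + flank_len +
                                                  core_len,
                                                pad_len + 2L * flank_len +
                                                  core_len))
    ref_locus <- paste(unclass(aln)[ref_species, ], collapse = "")
    ref_genome[sco_id] <- ref_locus
    if (i %in% duplicate_locus)
      ref_genome[paste0(sco_id, "_dup")] <- ref_locus
    # a simple two-CDS gene model over the locus so tags can fall in
    # coding, non-coding or mixed regions (coordinates 1-based closed)
    b1 <- max(2L, round(n_sites * 0.10)); b2 <- round(n_sites * 0.45)
    b3 <- round(n_sites * 0.60); b4 <- round(n_sites * 0.87)
    gene_models[[sco_id]] <- data.frame(
      contig = sco_id,
      type = c("gene", "five_prime_UTR", "CDS", "intron", "CDS",
               "three_prime_UTR"),
      start = c(1L, 1L, b1 + 1L, b2 + 1L, b3 + 1L, b4 + 1L),
      end = c(n_sites, b1, b2, b3, b4, n_sites),
      gene = sco_id, stringsAsFactors = FALSE)
    for (sp in chron$tip.label) {
      locus <- gsub("-", "", paste(unclass(aln)[sp, ], collapse = ""),
                    fixed = TRUE)
      ctg <- make_allelic_contigs(
        locus, ploidy = if (sp == ref_species) 1L else ploidy,
        heterozygosity = if (sp == ref_species) 0 else heterozygosity,
        n_extra_contaminants =
          if (sp == decoy_species && i %in% extra_allele_locus) 1L else 0L,
        seed = seed + 3000L + i * 100L + match(sp, chron$tip.label))
      names(ctg) <- sprintf("%s_%s_%s", sp, sco_id, names(ctg))
      assemblies[[sp]] <- c(assemblies[[sp]], ctg)
    }
  }
  list(chronogram = chron, proteomes = prot, alignments = alignments,
       gene_trees = stats::setNames(gene_trees,
                                    prot$truth$sco_pairs$gene_a),
       ref_genome = ref_genome, gene_models = gene_models,
       assemblies = assemblies,
       ploidy = stats::setNames(rep(as.integer(ploidy), n_taxa),
                                chron$tip.label),
       ref_species = ref_species, anchors = anchors,
       truth = list(sco_pairs = prot$truth$sco_pairs,
                    paralog_genes = prot$truth$paralog_genes,
                    tag_architecture = tag_truth,
                    site_rates = rates_truth,
                    duplicate_locus = duplicate_locus,
                    extra_allele_locus = extra_allele_locus))
}

.dna_or_empty <- function(seed, n) {
  if (n <= 0L) return("")
  with_seed(seed, .random_dna(n))
}
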