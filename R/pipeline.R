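#' Pipeline configuration with the standard thresholds
#'
#' All stage thresholds surfaced as named keys: similarity filter (e-value
#' 1e-10, identity 30, coverage 70), window screening (300 bp, 4 taxa),
#' primer constraints (59-61 C, homopolymer 3, GC clamp, product 300-550,
#' at most 100 pairs), retrieval thresholds (1e-10, 65, 100 percent,
#' +/- 20 percent), bootstrap filter 70, crown age 30 My, inflation 3.0.
#'
#' @param anchors taxa that must cover every tag window.
#' @param outgroup_species species retrieved in relaxed (outgroup) mode.
#' @param ... overrides for any of the defaults listed above
#'   (\code{max_evalue, min_identity, min_coverage, inflation, min_len,
#'   min_taxa, constraints, thresholds, bs_filter, crown_age}).
#' @return named list of configuration values.
#' @export
pipeline_config <- function(anchors = character(0),
                            outgroup_species = character(0), ...) {
  cfg <- list(
    max_evalue = 1e-10, min_identity = 30, min_coverage = 70,
    inflation = 3.0,
    min_len = 300L, min_taxa = 4L, anchors = anchors,
    constraints = primer_constraints(),
    thresholds = retrieval_thresholds(),
    bs_filter = 70, crown_age = 30,
    outgroup_species = outgroup_species,
    seed_filter = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.stage_report <- function(stage, n_in, n_out, removed = list()) {
  removed <- lapply(removed, as.integer)
  stopifnot(n_in == n_out + sum(unlist(removed)))
  list(stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
       n_removed_by_reason = removed)
}

#' Run the full tag-mining pipeline on a simulated or loaded study
#'
#' Executes the stages in order: ortholog calling (single-copy calling,
#' reciprocal best hits, Markov clustering, intersection), tag design
#' (windows, strict consensus, primer pairs, most-variable non-overlapping
#' selection), the post-design filters (primer specificity on the
#' reference genome; allele count vs ploidy; tag-level reciprocal-best
#' test; retrieval from per-species assemblies with edge checks and
#' relaxed outgroup mode), and marker assessment (site statistics,
#' per-site rates on the chronogram, PI profiles with phantom-spike
#' removal, per-node gene-tree conflict).  Deterministic given its inputs;
#' per-stage removal counts are logged in stage reports.
#'
#' @param study a study bundle from [simulate_study()] or [read_study()].
#' @param out_dir optional output directory; when given, writes
#'   \code{scos.tsv}, \code{tags.tsv}, \code{tag_seqs.fasta},
#'   \code{metrics.tsv}, \code{node_conflict.tsv} and
#'   \code{stage_reports.json}.
#' @param config a [pipeline_config()].
#' @return list with \code{scos}, \code{tags} (selected and surviving tag
#'   table), \code{tag_seqs} (per-tag named list of per-species
#'   sequences), \code{metrics} (per-tag metrics table), \code{conflict}
#'   (per-node summary), \code{reports} (list of stage reports).
#' @export
run_pipeline <- function(study, out_dir = NULL,
                         config = pipeline_config(anchors =
                                                    study$anchors)) {
  reports <- list()
  ## stage 1-2: orthology
  orth <- find_shared_scos(study$proteomes$proteome_a,
                           study$proteomes$proteome_b,
                           max_evalue = config$max_evalue,
                           min_identity = config$min_identity,
                           min_coverage = config$min_coverage,
                           inflation = config$inflation,
                           seed_filter = config$seed_filter)
  scos <- orth$pairs
  n_genes <- length(study$proteomes$proteome_a)
  reports$orthology <- .stage_report(
    "orthology", n_genes, nrow(scos),
    list(not_shared_single_copy = n_genes - nrow(scos)))

  ## stage 4: tag design on the per-SCO alignments
  sco_ids <- intersect(scos$gene_a, names(study$alignments))
  cands <- list()
  for (id in sco_ids) {
    cands[[id]] <- build_candidate_tags(
      study$alignments[[id]], id, min_len = config$min_len,
      min_taxa = config$min_taxa, required = config$anchors,
      constraints = config$constraints)
  }
  cands <- if (length(cands) > 0L) do.call(rbind, cands)
  else data.frame()
  tags <- if (!is.null(cands) && nrow(cands) > 0L)
    rank_and_select_tags(cands)
  else cands
  n_cand <- if (is.null(cands)) 0L else nrow(cands)
  n_sel <- if (is.null(tags)) 0L else nrow(tags)
  reports$tag_design <- .stage_report(
    "tag_design", n_cand, n_sel,
    list(overlapping_or_lower_rank = n_cand - n_sel))
  if (n_sel == 0L) {
    res <- .finish_pipeline(study, scos, tags, list(), reports, config,
                            out_dir)
    return(res)
  }
  tags$consensus <- vapply(seq_len(nrow(tags)), function(i) {
    aln <- study$alignments[[tags$sco_id[i]]]
    win <- list(start = tags$start[i], end = tags$end[i],
                covering_taxa = .window_cover(aln, tags$start[i],
                                              tags$end[i]))
    strict_consensus(aln, win)
  }, character(1))

  ## stage 5a: primer specificity on the reference genome
  pass <- vapply(seq_len(nrow(tags)), function(i)
    check_primer_specificity(tags[i, ], study$ref_genome,
                             product_range = c(config$constraints$product_min,
                                               config$constraints$product_max)
    )$pass, logical(1))
  reports$primer_specificity <- .stage_report(
    "primer_specificity", nrow(tags), sum(pass),
    list(unspecific_primers = sum(!pass)))
  tags <- tags[pass, , drop = FALSE]

  ## stage 5b: allele count vs ploidy in per-species contigs
  ingroup <- setdiff(names(study$assemblies), config$outgroup_species)
  pass <- vapply(seq_len(nrow(tags)), function(i) {
    id <- tags$sco_id[i]
    for (sp in ingroup) {
      ctg <- study$assemblies[[sp]]
      ctg <- ctg[grepl(id, names(ctg), fixed = TRUE)]
      if (length(ctg) == 0L) next
      pieces <- substr(ctg, tags$start[i] + 1L, tags$end[i])
      chk <- allele_count_check(pieces, study$ploidy[[sp]])
      if (!chk$pass) return(FALSE)
    }
    TRUE
  }, logical(1))
  reports$allele_count <- .stage_report(
    "allele_count", length(pass), sum(pass),
    list(allele_count_exceeds_ploidy = sum(!pass)))
  tags <- tags[pass, , drop = FALSE]

  ## stage 5c: reciprocal-best test of each tag on the reference genome
  pass <- vapply(seq_len(nrow(tags)), function(i) {
    tag_rbb_test(tags$consensus[i], study$ref_genome,
                 list(contig = tags$sco_id[i],
                      start = tags$start[i] + 1L,
                      end = tags$end[i]))$pass
  }, logical(1))
  reports$tag_rbb <- .stage_report(
    "tag_rbb", length(pass), sum(pass), list(rbb_fail = sum(!pass)))
  tags <- tags[pass, , drop = FALSE]

  ## stage 5d: retrieval from assemblies
  tag_seqs <- list()
  drop_tag <- logical(nrow(tags))
  n_species_rejects <- 0L
  for (i in seq_len(nrow(tags))) {
    seqs <- character(0)
    for (sp in names(study$assemblies)) {
      ctg <- study$assemblies[[sp]]
      ctg <- ctg[grepl(tags$sco_id[i], names(ctg), fixed = TRUE)]
      if (length(ctg) == 0L) next
      og <- sp %in% config$outgroup_species
      r <- retrieve_tag_from_assembly(
        tags$consensus[i], ctg, study$ploidy[[sp]],
        thresholds = config$thresholds,
        check_edges = !og, enforce_ploidy = !og,
        primer_pair = tags[i, ])
      if (r$status == "ok") {
        seqs[sp] <- r$sequence
      } else if (identical(r$level, "tag")) {
        drop_tag[i] <- TRUE
        break
      } else {
        n_species_rejects <- n_species_rejects + 1L
      }
    }
    if (!drop_tag[i]) tag_seqs[[tags$tag_id[i]]] <- seqs
  }
  reports$retrieval <- .stage_report(
    "retrieval", length(drop_tag), sum(!drop_tag),
    list(best_hits_exceed_ploidy = sum(drop_tag)))
  reports$retrieval$n_species_level_rejects <- n_species_rejects
  tags <- tags[!drop_tag, , drop = FALSE]

  .finish_pipeline(study, scos, tags, tag_seqs, reports, config, out_dir)
}

.window_cover <- function(aln, start, end) {
  cov <- aln_coverage(aln)
  rownames(aln)[rowSums(cov[, (start + 1L):end, drop = FALSE]) ==
                  (end - start)]
}

# assessment + output writing
.finish_pipeline <- function(study, scos, tags, tag_seqs, reports, config,
                             out_dir) {
  metrics <- NULL
  conflict <- NULL
  if (!is.null(tags) && nrow(tags) > 0L) {
    chron <- calibrate_chronogram(study$chronogram,
                                  crown_age = config$crown_age)
    rows <- list()
    for (i in seq_len(nrow(tags))) {
      aln <- study$alignments[[tags$sco_id[i]]]
      sub <- aln_slice(aln, tags$start[i], tags$end[i])
      st <- count_sites(sub)
      rates <- estimate_site_rates(sub, chron)
      prof <- pi_profile(rates,
                         t_grid = seq(config$crown_age / 400,
                                      config$crown_age,
                                      length.out = 400))
      sp <- remove_phantom_spikes(prof)
      area <- area_under_profile(sp$profile, 0, config$crown_age)
      cls <- if (!is.null(study$gene_models[[tags$sco_id[i]]]))
        annotate_tag(tags$start[i], tags$end[i],
                     study$gene_models[[tags$sco_id[i]]])
      else NA_character_
      rows[[i]] <- data.frame(
        tag_id = tags$tag_id[i], sco_id = tags$sco_id[i],
        n_taxa = nrow(sub), n_sites = st$n_sites,
        n_variable = st$n_variable, n_pis = st$n_pis,
        pis_fraction = st$pis_fraction,
        structure_class = cls,
        area_under_pi = area,
        pi_peak_time = sp$profile$t[which.max(sp$profile$net_pi)],
        n_removed_spike_sites = length(sp$removed_sites),
        stringsAsFactors = FALSE)
    }
    metrics <- do.call(rbind, rows)
    gts <- study$gene_trees[unique(tags$sco_id)]
    gts <- gts[!vapply(gts, is.null, logical(1))]
    if (length(gts) > 0L) {
      conflict <- node_concordance(chron, unname(gts),
                                   bs_filter = config$bs_filter)
      pg <- conflict$per_gene
      pg$sco_id <- names(gts)
      metrics$n_concordant_nodes <-
        pg$n_concordant_nodes[match(metrics$sco_id, pg$sco_id)]
      metrics$n_conflicting_nodes <-
        pg$n_conflicting_nodes[match(metrics$sco_id, pg$sco_id)]
    }
  }
  res <- list(scos = scos, tags = tags, tag_seqs = tag_seqs,
              metrics = metrics, conflict = conflict, reports = reports)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs to a directory
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ortholog_pairs(res$scos, file.path(out_dir, "scos.tsv"))
  tg <- res$tags
  if (is.null(tg) || nrow(tg) == 0L) {
    tg <- data.frame(tag_id = character(0))
  }
  utils::write.table(tg, file.path(out_dir, "tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fa <- character(0)
  for (tid in names(res$tag_seqs)) {
    s <- res$tag_seqs[[tid]]
    if (length(s) > 0L)
      fa[paste0(tid, "|", names(s))] <- unname(s)
  }
  write_fasta(fa, file.path(out_dir, "tag_seqs.fasta"))
  if (!is.null(res$metrics))
    utils::write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$conflict))
    write_conflict_report(res$conflict,
                          file.path(out_dir, "node_conflict.tsv"))
  jsonlite::write_json(res$reports,
                       file.path(out_dir, "stage_reports.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Join tag, informativeness and conflict outputs into one metrics table
#'
#' @param tags tag table (must carry \code{tag_id}, \code{sco_id}).
#' @param site_stats data.frame keyed by \code{tag_id} with site
#'   statistics columns.
#' @param informativeness data.frame keyed by \code{tag_id} with
#'   \code{area_under_pi} and \code{pi_peak_time}.
#' @param conflict optional data.frame keyed by \code{sco_id} with
#'   \code{n_concordant_nodes}, \code{n_conflicting_nodes}; tags without
#'   conflict metrics keep \code{NA} in those columns.
#' @return one row per tag, deterministically ordered by \code{tag_id}.
#' @export
write_metrics_report <- function(tags, site_stats, informativeness,
                                 conflict = NULL) {
  orphan <- setdiff(tags$tag_id, site_stats$tag_id)
  orphan2 <- setdiff(tags$tag_id, informativeness$tag_id)
  if (length(c(orphan, orphan2)) > 0L)
    stopf("tags lacking metrics: %s",
          paste(unique(c(orphan, orphan2)), collapse = ", "))
  out <- merge(tags[, c("tag_id", "sco_id")], site_stats, by = "tag_id")
  out <- merge(out, informativeness, by = "tag_id")
  if (!is.null(conflict)) {
    out$n_concordant_nodes <-
      conflict$n_concordant_nodes[match(out$sco_id, conflict$sco_id)]
    out$n_conflicting_nodes <-
      conflict$n_conflicting_nodes[match(out$sco_id, conflict$sco_id)]
  } else {
    out$n_concordant_nodes <- NA_integer_
    out$n_conflicting_nodes <- NA_integer_
  }
  out <- out[order(out$tag_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a study bundle to plain-text files
#'
#' FASTA for sequences, newick for trees, TSV for the ploidy table and
#' GFF3-style feature tables, and a JSON ground-truth sidecar.
#'
#' @param study a [simulate_study()] bundle.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "assemblies"), showWarnings = FALSE)
  dir.create(file.path(dir, "genetrees"), showWarnings = FALSE)
  write_fasta(study$proteomes$proteome_a,
              file.path(dir, "proteome_A.faa"))
  write_fasta(study$proteomes$proteome_b,
              file.path(dir, "proteome_B.faa"))
  write_fasta(study$ref_genome, file.path(dir, "ref_genome.fna"))
  ape::write.tree(study$chronogram, file.path(dir, "chronogram.nwk"))
  for (id in names(study$alignments))
    write_alignment(study$alignments[[id]],
                    file.path(dir, "alignments", paste0(id, ".fasta")))
  for (sp in names(study$assemblies))
    write_fasta(study$assemblies[[sp]],
                file.path(dir, "assemblies", paste0(sp, ".fna")))
  for (id in names(study$gene_trees))
    ape::write.tree(study$gene_trees[[id]],
                    file.path(dir, "genetrees", paste0(id, ".nwk")))
  gm <- do.call(rbind, study$gene_models)
  utils::write.table(gm, file.path(dir, "gene_models.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(species = names(study$ploidy), ploidy = study$ploidy,
               row.names = NULL),
    file.path(dir, "ploidy.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(ref_species = study$ref_species, anchors = study$anchors,
         truth = list(sco_pairs = study$truth$sco_pairs,
                      paralog_genes = study$truth$paralog_genes)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#' @param dir directory written by [write_study()].
#' @return a study bundle as produced by [simulate_study()] (without the
#'   simulation-only ground-truth internals).
#' @export
read_study <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  aln_files <- sort(list.files(file.path(dir, "alignments"),
                               full.names = TRUE))
  alignments <- stats::setNames(
    lapply(aln_files, read_alignment),
    sub("\\.fasta$", "", basename(aln_files)))
  asm_files <- sort(list.files(file.path(dir, "assemblies"),
                               full.names = TRUE))
  assemblies <- stats::setNames(
    lapply(asm_files, read_fasta),
    sub("\\.fna$", "", basename(asm_files)))
  gt_files <- sort(list.files(file.path(dir, "genetrees"),
                              full.names = TRUE))
  gene_trees <- stats::setNames(
    lapply(gt_files, ape::read.tree),
    sub("\\.nwk$", "", basename(gt_files)))
  gm <- utils::read.delim(file.path(dir, "gene_models.tsv"),
                          stringsAsFactors = FALSE)
  pl <- utils::read.delim(file.path(dir, "ploidy.tsv"),
                          stringsAsFactors = FALSE)
  list(
    chronogram = ape::read.tree(file.path(dir, "chronogram.nwk")),
    proteomes = list(
      proteome_a = read_fasta(file.path(dir, "proteome_A.faa")),
      proteome_b = read_fasta(file.path(dir, "proteome_B.faa"))),
    alignments = alignments,
    gene_trees = gene_trees,
    ref_genome = read_fasta(file.path(dir, "ref_genome.fna")),
    gene_models = split(gm, gm$contig),
    assemblies = assemblies,
    ploidy = stats::setNames(as.integer(pl$ploidy), pl$species),
    ref_species = gt$ref_species,
    anchors = gt$anchors,
    truth = gt$truth)
}
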