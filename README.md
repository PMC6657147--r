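# scotags

Mining genome pairs for variable single-copy orthologous sequence tags
(SCO tags) for species-level phylogenomics, with a marker-assessment
toolkit.

## The problem

Resolving relationships among closely related species needs many
independent nuclear loci that are (i) single-copy — so that cross-species
comparisons compare orthologs, not paralogs — (ii) PCR-amplifiable across
the whole group with one conserved primer pair, and (iii) variable enough
inside the amplicon to carry phylogenetic signal. `scotags` implements an
end-to-end workflow that mines such markers from a pair of annotated
genomes and a panel of per-species assemblies, and then quantifies each
marker's utility.

The workflow:

1. **Ortholog calling.** All-vs-all protein similarity searches are
   filtered (e-value ≤ 1e-10, identity ≥ 30%, query coverage > 70%);
   single-copy genes are those whose only filtered self-search hit is
   themselves. Shared single-copy orthologs (SCOs) between the two
   genomes are the intersection of reciprocal best hits with Markov
   clustering (MCL, inflation 3.0) of the cross-genome similarity graph:
   a pair is cluster-supported only when its cluster contains exactly one
   gene per genome.
2. **Tag design.** Per-SCO multi-species alignments are screened for
   windows ≥ 300 bp covered by ≥ 4 taxa including required anchor
   species. A strict consensus (IUPAC codes for substitutions, `N` for
   gapped columns) is built per window, and primer pairs are designed in
   its ambiguity-free stretches under Primer3-style constraints: Tm
   59–61 °C (nearest-neighbor thermodynamics), homopolymers ≤ 3, a
   3′-G/C clamp, product 300–550 bp, ≤ 100 pairs per consensus. The most
   variable non-overlapping amplicons are selected greedily.
3. **Tag filters.** (a) primer specificity: exactly one convergent
   perfect-match primer site pair on the reference genome; (b) allele
   counts in per-species contigs must not exceed the declared ploidy;
   (c) a reciprocal-best test of each tag against the reference genome;
   (d) retrieval from per-species assemblies (e-value ≤ 1e-10, identity
   ≥ 65%, 100% query coverage, length difference ≤ ±20%) with exact
   primer edges required — relaxed for outgroup species. Every stage
   logs its removals.
4. **Assessment.** Variable and parsimony-informative sites (gap treated
   as a fifth character state), per-site substitution rates by maximum
   likelihood (JC69) on a time-calibrated chronogram, Townsend
   phylogenetic-informativeness profiles
   ρ(t; λ) = 16 λ² t e^(−4λt) summed over sites, area under the profile,
   and removal of "phantom spikes" (profiles with more than one maximum
   are cleaned by an elbow threshold on the sorted site rates, applied
   twice); gene-tree/species-tree conflict per node (concordance /
   conflict counts with a 70% bootstrap filter, Internode Certainty All)
   and the normalized quartet score.

A simulation module (`simulate_study()` and friends) generates every
input with known ground truth — planted orthologs and paralog decoys,
conserved-flank/variable-core tag architectures, coalescent gene trees
with tunable incomplete lineage sorting, ploidy-aware allelic contigs —
so the whole pipeline is testable without any external data or tools.

## Worked example

```r
library(scotags)
study <- simulate_study(n_sco = 3, n_taxa = 6, seed = 7)
res   <- run_pipeline(study)
res$scos
#>      gene_a    gene_b support
#> 1 A_sco0001 B_sco0001 rbb,mcl
#> 2 A_sco0002 B_sco0002 rbb,mcl
#> 3 A_sco0003 B_sco0003 rbb,mcl
res$metrics[, c("tag_id", "n_pis", "structure_class", "area_under_pi",
                "n_concordant_nodes", "n_conflicting_nodes")]
#>              tag_id n_pis structure_class area_under_pi n_concordant_nodes n_conflicting_nodes
#> 1 A_sco0003_w1_p009    45           mixed      62.83842                  3                   0
#> 2 A_sco0001_w1_p042    36           mixed      53.57639                  3                   0
#> 3 A_sco0002_w1_p007    30           mixed      48.94286                  3                   0
```

All three planted SCOs are recovered with both reciprocal-best-hit and
clustering support, each yields one selected tag, and the per-tag metrics
report parsimony-informative sites, the gene-model class of the amplicon
(here spanning coding and non-coding sequence), the area under the
informativeness profile over 0–30 My, and per-node agreement of the
locus tree with the species tree (all three evaluable nodes concordant —
the simulation used moderate coalescent ILS).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/scotag.R", package="scotags"))')" \
    simulate --seed 42 --n-sco 5 --n-taxa 8 -o fixtures/
Rscript .../scotag.R run --study fixtures/ -o results/
```

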