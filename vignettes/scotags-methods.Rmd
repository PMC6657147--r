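---
title: "Methods: mining and assessing single-copy orthologous sequence tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and assessing single-copy orthologous sequence tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotags)
```

This vignette documents the models, parameter choices and numerical
decisions behind `scotags`, in the spirit of a methods section: what each
stage assumes, where the design was genuinely open and which choice was
made, and what the synthetic-data tests do and do not demonstrate.

## Ortholog calling

**Similarity filter.** Hits are kept when e-value ≤ 1e-10 (inclusive),
percent identity ≥ 30 (inclusive, "at least"), and query coverage
strictly > 70% ("above"). Coverage is of the query only; subject coverage
is never tested. These edge semantics follow the usual phrasing of such
filters literally, and the filter is idempotent and order-preserving.

**Single-copy calling.** A gene is single-copy when its filtered
genome-vs-itself hit set is exactly one hit, to itself. Genes with no
filtered hit at all are treated as unclassifiable rather than single-copy
and are reported separately.

**Reciprocal best hits.** "Best" is the highest alignment score; ties are
broken by lower e-value, then lexicographically smaller subject id. The
last tie-break always resolves, so every query has a unique best match
and the procedure is deterministic. A gene can consequently appear in at
most one retained pair.

**Markov clustering.** The classic MCL iteration on the column-stochastic
matrix of the similarity graph: expansion (matrix squaring), inflation
(entrywise power, default 3.0, then column renormalization), and pruning
of entries < 1e-5, iterated until the maximum entrywise change is below
1e-6 or 100 iterations. Self-loops are set to each node's maximum
incident edge weight (1 for isolated nodes), a standard regularization
that prevents period-two oscillation. Clusters are connected components
of the attractor's non-zero structure. Non-convergence returns the
current clustering with a warning rather than failing. Cluster support
for an ortholog pair is deliberately strict: the pair's cluster must
contain *exactly* one gene from each genome, so any residual family
structure vetoes the pair.

**Internal search engine.** All-pairs affine-gap Smith–Waterman (BLOSUM62
11/1 for protein; +2/−3 with gap 5/2 for DNA, using an IUPAC-aware fuzzy
scoring matrix so ambiguous consensus bases remain alignable). Raw scores
are converted to bits with fixed Karlin–Altschul-style constants and
e-values use E = m·n·2^−bits. The e-value scale is a surrogate for a
database search engine's: all decisive thresholds downstream act on
identity and coverage, which are exact properties of the reported
alignment. An optional shared-k-mer seed filter (k = 4 for protein, 11
for DNA, ≥ 2 shared words) skips hopeless pairs; correctness tests run
the exhaustive scan.

## Tag design

**Coverage and windows.** A taxon covers an alignment column when the
column lies within its first-to-last non-gap extent: internal gaps do not
interrupt coverage, terminal gaps (missing sequence) do. Windows are
maximal runs of columns with ≥ `min_taxa` (default 4) covering taxa
including every anchor taxon, kept at ≥ `min_len` (default 300) columns.
All alignment coordinates are 0-based half-open; GFF-style feature tables
(1-based closed) are converted at the boundary.

**Strict consensus.** Unanimous columns emit the base; substitution-only
columns emit the IUPAC code of the observed base set; any gap among
covering taxa emits `N`. Primers are restricted to ambiguity-free
(A/C/G/T-only) consensus stretches, which makes them conserved across
the covering taxa *by construction*.

**Melting temperature.** Unified nearest-neighbor thermodynamics
(10-parameter ΔH/ΔS dinucleotide table with terminal-base-pair initiation
terms), entropic salt correction 0.368·(L−1)·ln[Na⁺], and
Tm = 1000·ΔH / (ΔS + R·ln(C/4)) − 273.15, with defaults 50 mM monovalent
salt and 0.5 µM oligo. The calculation is deterministic and symmetric
under reverse complement (the duplex is the same molecule).

**Primer pairs.** Candidates are 18–25-mers (a conventional range) with
Tm in 59–61 °C, homopolymer runs ≤ 3, and a 3′-terminal G or C (the
single-base reading of a "GC clamp"). Pairs must give products of
300–550 bp and may not overlap. Pairs are scored by |ΔTm| then by
distance of the product from 425 bp (the midpoint of the allowed range);
when more than 100 pairs exist, up to 100 are chosen greedily in score
order preferring pairs whose product covers yet-uncovered consensus,
so the retained pairs span the region rather than piling on one locus.

**Tag variability and selection.** A tag's variability is its count of
variable amplicon columns (≥ 2 states among covering taxa, gap as a
fifth state, ambiguity codes treated as missing). Variable-site count is
used rather than parsimony-informative sites because selection happens
before the final species panel is known; it maximizes retained
polymorphism. Selection is greedy by variability with deterministic
tie-breaks (longer amplicon, leftmost start, tag id), accepting only
candidates that overlap no already-accepted tag of the same locus.

## Tag filters

Specificity uses perfect-match primer binding on both strands and counts
convergently oriented site pairs with an in-range product; exactly one
site pair genome-wide passes. A mismatch-tolerant binding model would be
less conservative but non-deterministic in its cutoffs; perfect matching
is the strictest reading of "unspecific binding".

Allele counting uppercases and gap-strips contig sequences and compares
the number of distinct strings with the declared ploidy; "compatible
with ploidy" is read as ≤ ploidy (for polyploids any stricter rule would
need phasing information the pipeline does not have). A tag failing in
any ingroup species is rejected for all species.

Retrieval keeps hits with e-value ≤ 1e-10, identity ≥ 65%, alignment
spanning 100% of the query columns, and ungapped subject span within
±20% of the query length. Equal-top-score hits form the best-hit set;
when it exceeds the ploidy the whole tag is discarded. Otherwise the
choice among tied best hits — "arbitrary" in spirit — is made
deterministic: lexicographically smallest contig id, then smallest start
coordinate. With edge checking, the retrieved sequence must begin with
the left primer and end with the reverse complement of the right primer.
Outgroup species disable both the edge check and the ploidy-based
tag-wide discard, reflecting that outgroup assemblies are used only to
root trees, not to validate the marker.

## Informativeness

**Site statistics.** Variable and parsimony-informative columns are
counted over the five states A, C, G, T and gap; `N` and IUPAC codes are
missing data. A parsimony-informative site has ≥ 2 states each in ≥ 2
sequences.

**Column cleaning.** A light two-threshold filter (gap fraction ≤ 0.5,
modal unambiguous base frequency ≥ 0.5 by default) stands in for heavier
alignment-trimming tools. It is intentionally simple and is not
byte-compatible with any external trimmer; a column provenance map makes
the trimming auditable.

**Chronogram.** Calibration scales all branch lengths linearly so the
crown height equals the calibration age (default 30 My); ultrametricity
is checked to a relative tolerance of 1e-6 and violations are an error,
not silently repaired.

**Site rates.** Rates are estimated by maximum likelihood under JC69 on
the fixed chronogram with Felsenstein pruning, one bounded 1-D search
per site (or per site *class* when a class assignment is supplied — the
two-taxon closed form λ = −3/(8T)·ln(1 − 4p/3) applies to a class of
sites with p-distance p, and the class machinery is what makes rate
recovery statistically well-posed). The search is on [0, 10]
substitutions/site/My; because the log-likelihood is numerically flat
over most of that interval, the maximum is first bracketed on a 40-point
logarithmic grid and then refined by golden-section search, with an
explicit preference for the λ = 0 boundary when it is as good (invariant
columns get exactly 0). JC69 replaces a heavier GTR machinery
deliberately: it is deterministic, dependency-free and testable against
a closed form; single-site data rarely support richer models anyway.
Raw per-site estimates on few taxa are noisy and saturated columns hit
the search bound — that is precisely the spike artifact the profile
cleaning below addresses.

**Informativeness profiles.** Each site of rate λ contributes the
four-taxon asymptotic informativeness ρ(t; λ) = 16 λ² t e^(−4λt); the
net profile is the sum over sites, evaluated on a grid of 1000 points
over (0, 30] My by default. The profile peaks at t = 1/(4λ) for a single
rate, is additive over sites, and vanishes at both time extremes. The
absolute scale of net informativeness depends on normalization
conventions that differ between implementations, so all checks in this
package are on shape properties (peak position, additivity, integrals),
never on absolute profile heights. The area under the profile uses the
trapezoidal rule; t = 0 is supplied analytically (ρ(0) = 0) so grids
starting above zero still integrate from the origin.

**Phantom-spike removal.** A profile is flagged when it has more than
one *strict interior* local maximum on its evaluation grid. For flagged
profiles the sorted (descending) site rates are examined for an elbow:
the index maximizing perpendicular distance to the chord between the
first and last points, with both axes normalized to [0, 1] so the
criterion is scale-free. Sites with rates strictly above the elbow rate
are discarded and the profile recomputed; the elbow-trim is applied
exactly twice, after which even secondary spikes are gone. Degenerate
flagged inputs (all rates equal) remove nothing, and unflagged profiles
are exact fixed points. Removal can only shrink the site set.

## Conflict accounting

Gene trees are rooted on their outgroup taxa; non-monophyly of the
present outgroup raises a typed error so callers can discard the tree
(the count of discarded trees is itself a reported quantity in real
analyses). Rooting is implemented via a split-existence check computed
directly from edge clades, so outgroups straddling the stored
trifurcation of an unrooted tree are handled. Branches with bootstrap
support below 70 are contracted into polytomies before comparison;
branches without a recorded support are kept (the convention appropriate
when weak branches were already collapsed upstream; the assumed support
for unlabeled branches is configurable).

For a species-tree node with ingroup I and a gene tree on taxa T, the
comparison restricts I to I′ = I ∩ T. The gene is concordant when some
supported gene clade equals I′; conflicting when none does but some
supported clade overlaps I′ without nesting either way; uninformative
otherwise — including whenever fewer than two ingroup or two outgroup
taxa remain, and for species nodes whose own complement has fewer than
two taxa (such nodes are excluded from the report entirely since no gene
tree could ever be informative about them). The "main alternative" at a
node is the most frequent conflicting ingroup set across genes, ties
broken by the lexicographically smallest taxon-set string; each
conflicting gene counts toward the main alternative when its
incompatible clades include it, otherwise toward "other alternatives",
so per-node counts always sum to the number of gene trees.

Internode Certainty All retains the species cluster plus every
conflicting cluster at relative frequency ≥ 0.05 (a pragmatic floor to
keep rare noise out of the entropy), normalizes the retained counts and
returns 1 + Σ pᵢ·log_n(pᵢ): 1 for an uncontested node, 0 for an even
two-way split, approaching −1 as many equally frequent alternatives
swamp the species cluster.

The normalized quartet score enumerates all four-taxon subsets shared
between each gene tree and the species tree, determines each induced
quartet topology from the four-point condition on unit-branch-length
path distances, and reports the fraction of doubly resolved quartets
that agree. Quartets unresolved in a collapsed gene tree are excluded
from numerator and denominator both.

## The synthetic-data generator

All generators are pure functions of their arguments and an explicit
seed; the caller's RNG state is never touched. The simulated regime
follows the data regime the pipeline targets: a crown age of 30 My,
ingroup panels of 6–17 species, ploidies 1x–8x, and per-locus tag
architectures of roughly 550 bp.

* Species chronograms are pure-birth trees conditioned on the tip count
  and rescaled to the crown age.
* Gene trees come from a multispecies coalescent with one sampled
  lineage per species; θ (in My) controls incomplete lineage sorting,
  from none (θ → 0, gene trees equal the species tree) to saturation.
* Alignments evolve under JC69 with per-site rates, either gamma-drawn
  (default shape 0.5, mean 0.01 substitutions/site/My — a plausible
  nuclear regime where an average site accumulates of order one change
  across a 30-My radiation) or explicitly supplied.
* Tag loci use a conserved-flank / variable-core architecture: 60-bp
  flanks at rate 0 (each resampled until it provably admits a valid
  primer, so designability holds by construction), a 350-bp core and
  40-bp padding at the locus rate (default 0.004/site/My). The planted
  core is the ground-truth tag.
* Proteome pairs plant single-copy orthologs (one copy per genome,
  genome-B copies diverged at 10% per site at the nucleotide level) and
  paralog families (diverged copies in both genomes) on random
  stop-free coding sequences; each SCO carries a consistent three-exon
  gene model whose CDS translates exactly to the emitted protein.
* Allelic contigs mutate a locus at the heterozygosity rate per allele;
  contaminant contigs (15% divergence) model paralogous assembly
  products. Decoy knobs plant an exact duplicated reference locus
  (caught by primer specificity / the tag reciprocal-best test) or an
  extra allele (caught by the ploidy check).

What the simulations do *not* emulate: alignment error (the simulator
emits true alignments, as multiple alignment is outside the pipeline's
scope), indel evolution beyond simple gap-block injection, rate
variation across lineages, base-composition bias, sequencing or assembly
error inside contigs, and hybridization or gene flow (gene-tree discord
comes only from the coalescent). Passing tests therefore demonstrate
correctness of the algorithms under the stated models, not robustness to
real-data pathologies such as misalignment or chimeric contigs.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
at deliberately modest sizes — proteome pairs up to 200 orthologs plus
50 paralog families, alignments of ~500 columns on up to 10 taxa, 1000
random gene trees for the quartet baseline, 80 coalescent trees per θ
level — sizes at which every brute-force oracle is still exact and the
whole suite completes in a couple of minutes on one core. The pipeline
itself contains no randomness: given identical inputs and configuration
it produces byte-identical outputs, which the tests verify literally.

## Known limitations

* The e-value scale of the internal search engine is a surrogate;
  analyses that must rank marginal hits by e-value should use a
  dedicated search engine and feed the tabular output in via
  `parse_hit_table()`.
* Per-site rate estimates on small taxon panels are intrinsically
  noisy; downstream consumers should either supply site classes or rely
  on the spike-removal step, and should treat absolute net-PI values as
  relative measures only.
* The column-cleaning filter is a simple surrogate for dedicated
  alignment trimmers and is not byte-compatible with any of them.
* `collapse_low_support()` rebuilds the tree through a newick round
  trip; branch lengths of surviving edges are preserved to 15
  significant digits, which is ample for topological downstream use but
  not bit-exact.
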