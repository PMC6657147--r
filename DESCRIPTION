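Package: scotags
Title: Mining Genomes for Variable Single-Copy Orthologous Sequence Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to mine pairs of annotated genomes for single-copy
    orthologous loci and to design, filter and assess short PCR-amplifiable
    sequence tags (SCO tags) inside them for species-level phylogenomics.
    Orthologs are called by intersecting reciprocal best hits with Markov
    clustering of a protein similarity graph.  Tag design screens
    multi-species alignments for well-covered windows, builds strict
    consensus sequences and designs conserved primer pairs under melting
    temperature, homopolymer, GC-clamp and product-size constraints.
    Post-design filters test primer specificity, tag-level reciprocal-best
    orthology, allele-count consistency with ploidy, and threshold-based
    retrieval from assembled genomes.  Marker utility is quantified by
    variable and parsimony-informative site counts (gaps as a fifth state),
    per-site substitution rates on an ultrametric chronogram, Townsend
    phylogenetic-informativeness profiles with phantom-spike removal, and
    gene-tree/species-tree conflict accounting (per-node concordance,
    internode certainty, normalized quartet score).  A simulation module
    generates all required inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
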