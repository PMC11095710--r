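Package: mitofrag
Title: Comparative Analysis of Mitochondrial Genome Fragmentation on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of fragmented (minicircular)
    mitochondrial genomes on a dated phylogeny. Fits two-state Mk models
    (equal-rates, all-rates-different, irreversible) of the
    single-chromosome/fragmented trait by maximum likelihood with AICc model
    selection, reconstructs ancestral states by marginal likelihood,
    stochastic character mapping and Fitch parsimony, and measures
    phylogenetic signal with the Fritz-Purvis D statistic. Selects
    phylogenetically independent matched pairs of fragmented and
    non-fragmented lineages and contrasts substitution rates (branch lengths)
    and gene-order rearrangement scores with two-tailed sign tests. Gene
    orders are compared through gene-boundary (adjacency) sets with
    parsimony reconstruction of ancestral adjacencies. Assembly diagnostics
    assess contig circularity from end k-mer matches and read connectivity
    across a spliced junction, and scan for mononucleotide repeats and
    inter-contig shared sequence. Base-composition statistics cover
    partitioned AT content (including fourfold degenerate sites under the
    invertebrate mitochondrial code), phylogenetic ANOVA and PGLS.
    A synthetic-data generator produces birth-death trees, Markov-evolved
    binary traits, painted branch lengths, rearranged gene orders and
    sequencing reads with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    seqinr,
    jsonlite
Config/testthat/edition: 3
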