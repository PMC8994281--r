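Package: minikaryo
Title: Comparative Analysis of Fragmented Mitochondrial Genomes in Sucking Lice
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the fragmented mitochondrial (mt) genomes of
    sucking lice (Anoplura), whose mt genes are distributed over many small
    circular minichromosomes. Provides a text format and data model for mt
    karyotypes (ordered, oriented gene lists per minichromosome plus declared
    missing genes), extraction of minichromosomal characters (co-membership
    blocks and oriented adjacencies), parsimony inference of ancestral
    karyotypes by a two-clause rule, detection and phylogenetic tallying of
    minichromosome split, merger, translocation and loss events, affine-gap
    pairwise alignment identity for paralog classification and degenerate-gene
    scanning, conserved AT-rich/GC-rich motif discovery in non-coding regions,
    and a karyotype/sequence simulator with ground-truth event logs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
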