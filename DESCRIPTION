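Package: pksminer
Title: Mining Polyketide Synthase Gene Clusters in Annotated Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("pksminer", "maintainers", email = "pksminer@example.org",
           role = c("aut", "cre"))
Description: Detects trans-AT polyketide synthase (PKS) biosynthetic gene
    clusters in bacterial genome annotation records. Parses GenBank flat
    files into an annotated-genome model, matches CDS features against a
    curated catalogue of PKS cluster components (bacillaene, macrolactin
    and difficidin templates), chains hits into candidate clusters, scores
    completeness and classifies genomes as harbouring complete, partial or
    absent PKS macroclusters, with gene-neighbourhood reporting. Includes
    an annotation-independent Smith-Waterman homology fallback, a 16S
    phylogenetics workflow (Kimura 2-parameter distances, neighbor-joining,
    bootstrap supports) and a synthetic annotated-genome generator with
    ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
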