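Package: binsage
Title: Assembly-Graph-Aware Metagenomic Contig Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bins metagenomic contigs into putative genomes by combining
    contig-specific signals (canonical tetranucleotide composition and
    multi-sample read depth) with the topology of the assembly graph.
    Contig features are compressed with a variational auto-encoder, refined
    with a GraphSAGE-style graph neural network trained on coverage-weighted
    positive and negative edge samples, and the concatenated embeddings are
    clustered with iterative medoid clustering. Includes readers for GFA,
    FASTA and MetaBAT2/VAMB-style depth tables, single-copy marker-gene and
    gold-label bin evaluation, and a synthetic community generator for
    testing the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
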