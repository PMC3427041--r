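Package: homeopipe
Title: Homoeolog-Specific SNP Calling, Homoeologous Recombination
    Detection and Molecular Evolution in Allopolyploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for allopolyploid transcriptome
    assemblies built from mixed diploid and allotetraploid read sets, as
    in cotton (Gossypium). Calls genome-diagnostic SNPs that separate the
    A- and D-subgenome homoeologs by majority-rule consensus building and
    a binomial pileup quality model, reconciles calls across long-read
    and short-read platforms, detects nonreciprocal homoeologous
    recombination (gene conversion between subgenomes) from chimeric
    diagnostic-allele haplotypes and places events on the two-species
    phylogeny, and estimates pairwise Nei-Gojobori dN/dS with
    Jukes-Cantor correction plus lineage-polarized substitution counts.
    A fully parameterised synthetic-data generator with complete truth
    records makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    withr,
    stats,
    utils,
    Biostrings,
    ShortRead,
    Rsamtools,
    GenomicAlignments,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
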