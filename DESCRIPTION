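Package: sorfscan
Title: Discovery of Conserved Small Open Reading Frames in Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow for finding small open reading frames
    (sORFs, at most 80 codons) that standard genome annotation misses.
    Annotated genomes are partitioned into exonic, intronic and intergenic
    space; both strands are scanned for ORFs with a start and a stop codon;
    a trainable hexamer log-odds classifier supplies a coding probability
    and the two predictions are intersected into a consensus set; candidates
    are screened against annotated proteins by local alignment, deduplicated,
    greedily clustered at 70% identity, and clusters spanning at least two
    species are called conserved. Per-cluster neighbor-joining trees with
    Jones-Taylor-Thornton distances and bootstrap support complete the
    analysis. A synthetic multi-species genome generator with planted
    homologous sORF families provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
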