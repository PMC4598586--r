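Package: rrbsim
Title: Simulation and Analysis of Reduced-Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for double-digest reduced-representation
    bisulfite sequencing (RRBS) of plant genomes, exercised on synthetic data.
    Generates multi-chromosome genomes with gene, transposon and repeat
    annotations carrying polyploid subgenome and copy-number labels, a
    ground-truth methylome with context-dependent levels (CG/CHG/CHH),
    sample-versus-reference SNPs, and non-directional paired-end bisulfite and
    ddRAD read sets from SacI/MseI size-selected fragments. Implements in-silico
    double digestion and size selection with capture statistics, read trimming
    and quality filtering, three-letter non-directional bisulfite alignment
    with unique-mapping rules, per-cytosine methylation calling with
    mate-overlap and base-quality filters, permissive SNP calling and masking
    of disrupted sites, sliding-window and metagene methylation profiles, and
    subgenome/copy-number stratification of methylation and expression with
    pairwise chi-square comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
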