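Package: branchmapr
Title: Bulked Segregant Analysis and Fine Mapping of a Branching QTL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for mapping a partially dominant
    inflorescence-branching quantitative trait locus from an F2 cross of two
    tomato recombinant inbred lines. Implements QTL-seq style bulked segregant
    analysis (per-site SNP index and delta SNP index with 1,000 kb / 10 kb
    sliding-window smoothing and a simulation-based significance threshold),
    interval narrowing from recombinant marker genotypes and progeny tests,
    differential-expression calling on FPKM matrices (two-library proportion
    test, Benjamini-Hochberg adjustment, fold-change and abundance filters,
    cross-mutant intersection), and CArG-box promoter motif scanning with
    position weight matrices in JASPAR format. A seeded synthetic-data
    generator emulates the genetic design (960 F2 plants, extreme bulks of 24
    and 31, pooled short-read allele depths) so every stage is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
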