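Package: cytopop
Title: Population Genomics of Co-Inherited Cytoplasmic Genomes in Inbred Host Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint population-genomic analysis of a maternally inherited
    endosymbiont (such as Wolbachia) and mitochondrial DNA in a panel of
    inbred host lines. Provides infection-status calling from sequencing
    depth and breadth of coverage, relative titre (copy-number) estimation
    from organelle-to-nuclear depth ratios, nucleotide diversity and
    Tajima's D with a fixed-S neutral coalescent null, cross-genome
    linkage disequilibrium, distance-based genealogy summaries for
    star-phylogeny detection, single-trait and multivariate (canonical
    correlation) association of nuclear SNPs with titre phenotypes, and a
    synthetic-panel generator so the whole pipeline can be exercised and
    validated without external data.
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
    readr,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    vcfR,
    ape,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
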