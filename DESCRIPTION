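Package: splitkmer
Title: Positional Localization of Split 8-mers in TSS-Aligned Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A DNA-centric toolkit for discovering composite transcription
    factor binding sites from the positional distribution of split 8-mers
    (two 4-mers separated by a fixed-length insert) in promoters aligned on
    the transcription start site. Enumerates reverse-complement canonical
    pattern classes, counts occurrences into a binned promoter grid, scores
    positional concentration with a localization factor and a binomial
    non-uniformity test, and profiles localization across insert lengths to
    find patterns that localize at a unique spacing (such as the overlapping
    ETS and CRE motifs). Downstream genome-context stages scan genomes for
    literal motifs, measure enrichment in region sets (promoters, CpG
    islands, DNase hypersensitive sites), extend motifs base by base,
    enumerate 1-bp variants, scan CG dinucleotide pairs, average per-base
    conservation scores around occurrences, and classify the CpG methylation
    status of occurrences across cell types. A synthetic-data generator
    reproduces the statistical structure of each input so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
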