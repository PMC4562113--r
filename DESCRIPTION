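Package: hotspotUsage
Title: In Vitro Binding-Site Catalogs Versus In Vivo Recombination Hotspot Usage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit relating a genome-wide in vitro protein-DNA
    binding-site catalog (with quantitative affinities in reads per million) to
    in vivo recombination-hotspot usage. Classifies binding sites as used in
    vivo, in vitro only, or ambiguous from overlap with H3K4me3 and DMC1 peak
    sets; detects hotspot-deficient genomic regions with r-scan span statistics
    under an empirical permutation null with Benjamini-Hochberg control;
    quantifies usage by chromatin category with Poisson errors and by affinity
    quintile in closed versus open chromatin; and computes positional profiles
    (composite coverage, nucleotide frequencies, SNP-density ratios, binned
    log2 enrichment) around binding sites. Includes a synthetic-data generator
    emulating the statistical structure of such studies, so the whole pipeline
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
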