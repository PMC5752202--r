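Package: telodomains
Title: Simulation and Analysis of Telomere-Proximal Facultative Heterochromatin
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study position effects on facultative heterochromatin
    (H3K27me2/3) domains around chromosome ends. Simulates multi-chromosome
    genomes with telomere repeat arrays, methylation domains and genes;
    applies chromosomal rearrangements (insertional, reciprocal and
    quasiterminal translocations, deletions, telomere-repeat insertions and
    chromosome circularization) with exact coordinate liftover; generates
    ChIP-style and RNA-style read data; and provides the analysis stages of
    a ChIP-seq domain pipeline: sliding-window coverage, scaling
    normalization, thresholding domain calls, gained/lost/invariant
    differential classification across rearrangements, allele-specific
    (SNP-parsed) profiles, discordant-pair/split-read breakpoint calling,
    telomere repeat array detection and expression-by-domain-class
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    IRanges,
    S4Vectors,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
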