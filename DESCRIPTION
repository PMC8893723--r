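Package: fruitstrat
Title: Developmental Transcriptomics of Mushroom-Forming Fungi: Gene Ages,
    Allele-Specific Expression and Conserved Orthogroups
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative developmental transcriptomics of
    fruiting-body-forming fungi. Classifies developmentally expressed genes
    from stage-structured FPKM tables, assigns phylostratigraphic gene ages
    on a rooted species tree and computes transcriptome age indices (TAI),
    deconvolves allele-specific expression between the two parental nuclei
    of a dikaryon by Hamming-distance read assignment, partitions read-base
    mismatches into allele markers and RNA-editing candidates, builds
    filtered reciprocal-best-hit orthogroups with Markov clustering, and
    separates complex-multicellularity-specific from shared sexual
    development orthogroups. A synthetic-data module with planted ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
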