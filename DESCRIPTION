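Package: dgescreen
Title: RNAi Target Screening from Digital Gene Expression Tag Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate RNAi target genes from 3' digital gene
    expression (DGE) tag profiles of the kind produced by NlaIII tag
    sequencing across insect developmental stages. Builds a virtual
    CATG-anchored tag database from a de novo transcriptome (unigene FASTA),
    filters raw tag libraries into clean tags with a fully auditable
    accounting (ambiguous bases, adaptors, copy number below two), maps
    clean tags back to unigenes, partitions expression across stages
    (copy-number distributions, four-set Venn membership) and calls
    stage-specific tags as ranked RNAi candidates. Companion bioassay
    analytics cover Abbott control-corrected mortality, probit
    dose-response with LC50 and Fieller fiducial limits, hatch ratios,
    and comparative-Ct (2^-ddCt) relative expression for knockdown
    confirmation. A seeded synthetic-data generator emulates the full
    input set (unigenes, stage tag libraries with sequencing noise,
    dose-response and Ct tables) so the whole pipeline is testable
    without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
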