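Package: eracr
Title: Integration of ERa ChIP-Seq and ATAC-Seq Peak Landscapes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to integrate chromatin accessibility (ATAC-seq) and
    estrogen receptor alpha (ERa) binding (ChIP-seq) peak landscapes across
    inducible cell clones. Classifies condition-specific accessible regions
    over a doxycycline x estradiol treatment grid, defines ERa-bound active
    chromatin regions (ERa-ACR) as ChIP peaks overlapping open chromatin,
    scores transcription-factor binding-motif enrichment with exact
    hypergeometric tests, detects estrogen response element half and full
    sites, and computes pioneer-factor (FoxA1) co-occurrence, sharing and
    chromatin-opening statistics. Ships a fully seeded synthetic-data
    generator that plants known motif and accessibility ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
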