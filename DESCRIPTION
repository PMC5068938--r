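Package: minicrdesign
Title: Design and In Silico Verification of Type III CRISPR miniCRISPR Loci
    for Post-Transcriptional Gene Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for programming type III (CMR/CSM) CRISPR systems to
    silence mRNAs in hyperthermophilic archaea. Selects protospacers on a
    target transcript whose protospacer-adjacent sequence (PAS) base-pairs
    the crRNA 5' repeat handle (suppressing DNA interference while
    permitting RNA cleavage, including G:U wobble and the minimal -3/-4/-5
    motif), surveys genomes for PAS-motif availability per CDS, assembles
    single, multiplex and dosage miniCRISPR loci with simulated crRNA
    maturation, designs and verifies the modular overlap-extension PCR
    construction route in silico, and provides qPCR standard-curve,
    delta-delta-Ct and substrate-consumption quantification helpers.
    Includes a seeded synthetic-sequence fixture generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
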