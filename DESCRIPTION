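Package: fragmap
Title: Interaction Domain Mapping from Yeast Two-Hybrid Fragment Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps protein-protein interaction motifs at amino-acid resolution
    from randomly sheared ORF fragment libraries selected in a yeast two-hybrid
    reporter. Provides a simulator of the full experiment (circular prey plasmid,
    acoustic-shear fragmentation, six reading-frame cloning, reporter selection,
    paired-end sequencing), an internal seed-and-verify read mapper for circular
    plasmid references with SAM interchange, reading-frame classification and
    stratified coverage tracks (All/UniquePE/InFrame), a coverage-plateau domain
    caller with flank-slope diagnostics, and a nine-residue transactivation-domain
    scanner for flagging self-activating (false positive) peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
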