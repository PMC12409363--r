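Package: trnanick
Title: Anticodon Nuclease Cleavage-Site Analysis for tRNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize the tRNA targets of
    anticodon-stem nucleases such as the AriB Toprim effector of the PARIS
    anti-phage defence system. Provides canonical (Sprinzl-style) tRNA
    numbering and region maps, a ground-truthed small-RNA read simulator for
    two library protocols (reverse-transcriptase-stall-limited cDNA libraries
    and RNA-end-ligated libraries), read mapping with a uniqueness filter,
    full-length versus anticodon-fragment classification, log-log depletion
    regression, 5'-end pileups and nick-site calling, consensus-site scanning
    and phage escape-mutation annotation, in-silico RNase T1 digestion with
    average-mass MH+ prediction and MALDI peak matching, and ribosome
    toeprint stall prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
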