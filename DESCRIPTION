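Package: cblscreen
Title: Structural Screening of CBL-Type Calcium Sensors and CIPK-Type Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multilevel screening pipeline for calcineurin B-like (CBL)
    calcium sensor proteins and their interacting CIPK-type protein kinases
    in predicted proteomes. Detects EF-hand calcium-binding loops including
    the extended 14-, 15- and 19-residue first-EF-hand variants that
    distinguish CBL proteins from calmodulin and CNB/NCS-type sensors,
    classifies sensors by coordinating-residue identity, inter-EF-hand
    spacing and N-terminal lipid-modification motifs, detects the
    21-residue NAF regulatory domain of CIPKs with a position-specific
    scoring matrix, groups candidate paralogs with neighbor joining to flag
    intraspecific gene amplification, and emits a per-species inventory.
    Includes a synthetic proteome generator with machine-readable ground
    truth so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
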