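Package: metseg
Title: Sequence-Based Identification of Metal Ion Binding Residues
Version: 0.1.0
Authors@R:
    person("metseg", "developers", email = "metseg@example.org", role = c("aut", "cre"))
Description: Identifies metal-ion binding residues in proteins from sequence
    alone.  Sliding-window segments centered on each residue are scored by
    conservation-weighted position weight scoring matrices (PWSM) built from
    binding and non-binding training segments; composition is compressed to a
    two-dimensional Increment of Diversity statistic; physicochemical
    recodings (six-class hydropathy, three-class polarization charge),
    three-state secondary structure and binned relative solvent accessibility
    supply further PWSM channels.  Channels are fused by a C-SVC support
    vector machine with an RBF kernel (an in-package SMO solver), evaluated
    with balanced negative subsampling repeated five-fold cross-validation,
    and reported as Sn/Sp/Acc/MCC.  Includes a synthetic-data generator with
    planted binding microenvironments so the whole pipeline is testable
    without external databases, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
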