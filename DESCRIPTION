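Package: methylassign
Title: Structure-Based Automatic Assignment of Methyl NMR Resonances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic assignment of methyl 1H/13C resonances in selectively
    methyl-labeled proteins from a known 3D structure and unassigned 2D HMQC
    and methyl-methyl NOESY peak lists. Expected peak networks are generated
    from the structure using an r^-6 effective inter-methyl distance; the
    mapping of expected to measured peaks is optimized by an evolutionary
    algorithm coupled to greedy local search; many independent runs over a
    triplet of distance cutoffs are consolidated into consensus chemical
    shifts with a calibrated strong/weak confidence classification. Includes
    XEASY and Sparky peak-list readers and writers, reciprocity and
    signal-to-noise NOESY filtering, residue-type attribution of NOESY peaks,
    a synthetic benchmark simulator with ground truth, and a parameter-sweep
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp,
    bio3d
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
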