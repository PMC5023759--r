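Package: dimerscan
Title: Membrane-Compatible GPCR Dimer Interface Enumeration and Consensus Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models class-A GPCR homodimers by exhaustive enumeration of
    membrane-compatible dimer poses (rotations of each protomer about the
    membrane normal), local rigid-body Monte Carlo refinement against a
    self-contained surrogate interaction energy, four-parameter interface
    scoring (cross-protomer interface score, buried solvent-accessible
    surface area, binding-energy surrogate, hydrogen-bond energy), and
    consensus ranking of transmembrane-helix interface classes by value
    averaging and by top-population frequency. Includes a synthetic
    generator of idealized seven-transmembrane helical bundles with
    plantable interface decorations and trajectories, Ballesteros-Weinstein
    generic numbering, binding-site distance geometry, Kabsch
    superposition, and inactive-state trajectory diagnostics (ionic-lock
    distances, hydrogen-bond persistence, water bridges, RMSD stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
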