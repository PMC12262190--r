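Package: ppiiens
Title: Conformational Ensemble Analysis of Polyproline II Content in Mucin-Domain Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the backbone conformational ensembles of
    heavily O-glycosylated mucin-domain peptides such as the lubricin
    (PRG4) tandem-repeat region. Builds ideal-geometry peptide backbones
    from dihedral assignments, samples synthetic (phi, psi) ensembles from
    configurable secondary-structure basin mixtures, runs a toy
    replica-exchange Monte Carlo sampler on the implied energy landscape,
    constructs Ramachandran-like free-energy surfaces by Boltzmann
    inversion, classifies conformations into named secondary-structure
    regions (polyproline II, beta, alpha-R, alpha-L, coil), estimates
    per-residue region populations with block-bootstrap confidence
    intervals, and checks sampling convergence through radius-of-gyration
    histogram overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
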