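Package: phydnds
Title: Codon-Model Selection Scans and Phylogenetic Regression of Brain Size
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a two-stage molecular-evolution analysis of candidate
    genes across a species phylogeny. Stage one fits codon substitution site
    models (M0, M1a, M2a) by maximum likelihood and tests for positive
    selection with likelihood-ratio tests and false-discovery-rate control.
    Stage two fits the free-ratio branch model, aggregates per-branch dN and
    dS into root-to-tip dN/dS per species, and regresses log brain size on
    log selection measures with phylogenetic generalized least squares under
    Pagel's lambda (maximum likelihood, likelihood-weighted average, or
    fixed), including phyletic-dwarf exclusion and leave-one-out sensitivity
    analyses. A seeded simulator generates codon alignments under site-class
    mixtures or per-branch dN/dS variation, and phylogenetically correlated
    traits, so the whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    nlme,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
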