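Package: xlinkr
Title: Validation and Assembly of Multi-Domain Protein Models Against
    Cross-Link Distance Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating multi-domain protein structural models
    against MS-cleavable cross-linker (e.g. DSSO) Calpha-Calpha distance
    restraints and disulfide geometry, for the "divide and conquer"
    modelling of very large proteins such as apolipoprotein B-100.
    Derives linker distance thresholds from spacer and side-chain
    geometry, measures and classifies restraint satisfaction, keeps the
    segmentation bookkeeping (subunits, domains, coils, secondary
    structure content, consensus domain boundaries, in-silico trypsin
    digestion), assembles rigid domain models by multi-start restraint
    fitting with explicit mirror-image (improper transform) handling,
    checks containment in simplified lipoprotein particle shells, and
    implements protein-painting surface-exposure logic with hydrolyzed
    mono-link concordance. A synthetic fixture generator produces
    idealized Calpha traces with planted restraints so every step is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
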