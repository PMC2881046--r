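Package: protstab
Title: Protein Metabolic Stability Classification from Sequence-Derived Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies proteins into four metabolic half-life classes (short,
    medium, long, extra-long) from a 376-component feature representation:
    composition/transition/distribution (CTD) descriptors over six
    physicochemical groupings, amino-acid composition, sequence length,
    subcellular-location flags, KEGG pathway enrichment scores and protein
    complex counts. Features are ranked by minimum-redundancy
    maximum-relevance (mRMR) mutual information, a subset is chosen by
    incremental feature selection (IFS) under jackknife cross-validation of a
    cosine-distance nearest-neighbor classifier, and half-life classes are
    predicted hierarchically (short/medium versus long/extra-long, then within
    each branch). Includes a self-contained synthetic benchmark generator so
    the whole pipeline runs without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
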