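Package: mdscout
Title: Mining Molecular Dynamics Datasets in Generalist Data Repositories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to find, index and characterise molecular dynamics (MD)
    simulation data scattered across generalist data repositories (Zenodo,
    Figshare, OSF). Implements the two-phase Explore-and-Expand indexing
    strategy (typed extension/keyword queries followed by full dataset
    cataloguing, including zip archive previews, and a false-positive
    cleaning step), native readers for the Gromacs .gro, .mdp, .log and
    binary .xtc formats, inference of per-file annotations (MD engine,
    molecular composition, simulation time, all-atom versus coarse-grain
    resolution, thermostat/barostat, temperature), summary analytics over
    the resulting index, and a keyword search engine with TSV export.
    A synthetic-corpus generator with a ground-truth manifest makes the
    whole pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    xml2,
    arrow,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
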