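Package: aromaprofiler
Title: Volatile Profiling and Aroma Networks for Fortified Wines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for GC-MS volatolomics of fortified (Madeira-style)
    wines: Kovats retention-index computation from an n-alkane ladder (van den
    Dool-Kratz), retention-index and spectral-resemblance based compound
    identification against a packaged 82-compound reference library,
    internal-standard semi-quantification of peak areas, odor-threshold based
    screening of potential impact odorants, and bipartite compound-to-aroma-note
    networks with shared-compound projections over grape varieties and wine age
    classes. Includes a ground-truthed synthetic chromatographic peak-table
    generator emulating a 22-wine study design so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
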