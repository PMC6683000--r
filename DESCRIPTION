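Package: msgroupr
Title: Consolidate Mass-Spectrometry Acquisition Metadata into Minimal
    Parameter Groups and Render Reporting Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reads per-run acquisition metadata of liquid
    chromatography / mass spectrometry experiments from an open per-file
    JSON dialect or from mzML headers, strips file-specific fields,
    and partitions large collections into the minimal set of parameter
    groups sharing all relevant instrument settings via content hashing
    of canonically serialized parameter trees.  Parses EASY-nLC style
    gradient method text, detects parameter drift by diffing groups,
    and renders guideline-specific (MIAPE, JPR, custom) publication
    tables exported as tab-delimited text, spreadsheet workbooks and
    JSON.  Includes a seeded synthetic-collection generator for testing
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stringi,
    utils,
    stats,
    xml2,
    yaml,
    zip
Suggests:
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
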