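Package: echosift
Title: Rule-Based Extraction of Structured Measurements from Echocardiography Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A targeted, rule-based text-mining pipeline that turns free-text
    echocardiography reports into an analysis-ready table. It ships a versioned
    registry of 80 cardiovascular data elements (59 quantitative, 21 qualitative)
    with synonyms, units and plausibility constraints; normalizes EHR-export
    noise (ellipsis runs, whitespace); segments and classifies sentences as
    structured, semi-structured or unstructured; extracts numeric, range and
    categorical values with windowed regular expressions and a deterministic
    two-sentence look-ahead for co-reference ("the mean gradient across this
    valve"); homogenizes measurement units; flags unit errors, physiologic
    inconsistencies and interquartile-range outliers; and summarizes surviving
    values per report and element. A seeded synthetic-report generator with
    exact gold annotations and a precision/recall/F1 evaluation harness make
    every stage testable without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
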