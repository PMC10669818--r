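Package: echoparse
Title: Rule-Based Extraction of Measurements from Echocardiogram Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts semi-structured trans-thoracic echocardiogram (TTE)
    report text into a structured table of continuous measurements (velocities,
    gradients, dimensions, velocity-time integrals) and discrete severity
    grades (regurgitation, stenosis, ventricular function). Extraction is
    driven by an editable outcome lexicon (gazetteer), a tokeniser and
    sentence splitter tuned to clinical measurement clauses, and a cascade of
    priority-ordered pattern rules that bind values, average ranges, convert
    units to canonical scales and map qualitative severity labels to ordinal
    codes. Includes a dual-track validation pipeline (intraclass correlation
    and R-squared for continuous outcomes; per-outcome confusion tallies,
    precision/recall/F1 and pooled accuracy for discrete outcomes) and a
    ground-truthed synthetic report generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
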