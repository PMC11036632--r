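Package: picostruct
Title: Structured PICO Template Extraction from Randomized Controlled Trial Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts nested PICO (Patient, Intervention, Comparison, Outcomes)
    template instances from the abstracts of randomized controlled trials. Two
    engines are provided: an extractive pipeline that tags slot-filler start and
    end tokens, scores pairwise filler compatibility with a learned symmetric
    function and groups fillers into template instances by clustering with an
    inferred instance count; and a generative pipeline that linearizes nested
    template forests into token sequences, derives a right-linear context-free
    grammar from the template schema and decodes with stack-guided vocabulary
    masking so that every generated sequence parses back into a valid template
    forest. Includes slot-level evaluation metrics (micro F1, per-template mean
    F1, template-cardinality mean absolute deviation) and a seeded synthetic
    corpus generator so the full pipeline can be exercised end-to-end without
    external data or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
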