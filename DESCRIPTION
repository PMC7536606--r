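Package: dietassist
Title: Knowledge-Based Conversational Diet Assistant for Dementia Caregivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A text-mode conversational decision-support system that helps
    informal caregivers of people with Alzheimer disease and related dementias
    (ADRD) manage daily diet. The package combines an ontology-style knowledge
    base (food, nutrition, and user-profile concepts with IS-A subsumption and
    TBox/ABox partitioning), a tabled backward-chaining inference engine over
    safe Horn rules with numeric built-ins, citable diet-guideline constraints
    (MIND encourage/limit lists, per-meal calorie targets, diabetic macro
    bounds), a finite-state dialogue manager with slot filling and context
    expiry, personalized recommendation services with rejection handling, a
    scripted-conversation evaluation harness reporting dialogue success and
    recommendation correctness rates, and a deterministic synthetic-fixture
    generator so everything runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
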