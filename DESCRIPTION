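Package: labelweaver
Title: Dynamic Enhancement of Drug Product Labels with Linked Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links drug claims from three kinds of drug-information sources
    -- clinical-trial registry records with published results, drug-drug
    interaction terminology entries carrying Critical/Significant severity,
    and pharmacokinetic (CYP enzyme) assertions with supporting or refuting
    evidence -- to the Clinical Studies, Drug Interactions, and Clinical
    Pharmacology sections of structured product labels (SPL-style XML).
    Flags interaction and pathway claims that are potentially novel to a
    label section by case-insensitive string matching against section text
    and a class-expandable reference interaction set, renders per-product
    enhanced-label HTML reports, and provides the evaluation toolkit
    (precision/recall/F, pipeline precision, Cohen's kappa, relevance
    bookkeeping, per-drug summary tables) together with a seedable
    synthetic-corpus generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
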