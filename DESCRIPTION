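Package: elderwell
Title: Lifelong Learning and the Subjective Wellbeing of Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the association between lifelong learning
    and the subjective wellbeing of older adults from item-level survey
    responses. Implements a Multidimensional Wellbeing Index (a bounded,
    monotone, unit-free, scale-invariant normalised-distance aggregate) over
    the CASP-19, Satisfaction with Life and WHO-5 instruments; categorical
    recoding of survey fields; multiple correspondence analysis of the
    cases-by-categories indicator matrix; pre-pruned CART regression trees;
    and ordinary least squares with heteroskedasticity-robust standard
    errors. A synthetic survey generator with known ground-truth effects
    makes every stage of the pipeline testable without access to survey
    microdata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
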