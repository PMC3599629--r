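Package: scalestep
Title: Stepwise Item Response Theory Evaluation of Ordinal Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating ordinal rating-scale instruments in small
    clinical samples with a three-step item response theory strategy:
    nonparametric Mokken scale analysis (Loevinger scalability coefficients,
    automatic item selection, restscore checks of monotonicity and invariant
    item ordering) with bootstrap and permutation inference, a Rasch rating
    scale model as an equal-discrimination gate, and a graded response model
    fitted by marginal maximum likelihood giving item locations,
    discriminations, information functions, coverage summaries, and person
    measures with rank intervals. Includes synthetic response generators
    emulating small-sample questionnaire data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
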