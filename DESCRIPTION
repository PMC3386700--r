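Package: reactomics
Title: Reactomics Analysis of Lipid/PDA Biosensor-Array Plate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostic pattern analysis for arrays of lipid/polydiacetylene
    (PDA) detector vesicles read out in 96-well fluorescence plates.
    Computes percentage fluorescent chromatic responses (%FCR) from raw
    emissions, aggregates replicate wells, standardizes plates via shared
    standardization sera, z-normalizes to the healthy-control group, and
    classifies clinical groups with exhaustive feature-subset selection
    over a linear support vector machine, repeated over random balanced
    train/test partitions. Includes exact binomial chance-accuracy tests,
    a full label-shuffle null experiment, and a synthetic plate-cohort
    generator with realistic plate gain/offset artifacts for end-to-end
    validation without clinical sera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
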