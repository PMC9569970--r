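Package: ppptrace
Title: Partitioning Glucose Catabolism Between Glycolysis and the
    Pentose Phosphate Pathway from [1,2-13C2]Glucose Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope tracing analysis with
    [1,2-13C2]glucose in cultured cells. Implements the atom-fate model
    that maps glucose catabolism through glycolysis and the oxidative
    pentose phosphate pathway (PPP) onto positional isotopomers of
    pyruvate and lactate, converts positional isotopomers to
    mass-isotopologue distributions (MIDs) for GC-MS fragment ions,
    corrects measured MIDs for 13C natural abundance and tracer impurity
    by non-negative least squares, and estimates the fraction of glucose
    catabolized via the PPP by closed-form ratio inversion or bounded
    least squares with bootstrap uncertainty. Supporting assay
    computations cover isotope-dilution calibration of extracellular
    glucose and lactate, consumption and production rates per microgram
    protein, glycolysis-stress-test metrics from extracellular
    acidification traces, baseline normalization and fold changes,
    balanced two-way ANOVA with Tukey HSD, median-split group labeling,
    Kaplan-Meier curves and the log-rank test. A synthetic-data module
    generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
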