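Package: StereoMaturity
Title: Stereological Maturity Staging of Fish Ovaries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative-histology (stereology) workflow for staging the
    sexual maturity of female fish from ovarian point-grid counts. Provides
    the Glagolev point-count area-fraction estimator over a 19-structure
    ovarian taxonomy, a rule-based classifier assigning maturity phases
    (immature A, developing B, spawning C, regressing/regenerating D,
    omitted spawning E), inter-rater calibration statistics (per-structure
    reading-error index, multi-rater percentage agreement, Fleiss' kappa),
    cross-tabulation of stereological phases against macroscopic maturity
    stages with agreement percentages, a from-scratch logistic maturity
    ogive with bootstrap confidence intervals for L50, and a synthetic
    cohort generator (Dirichlet-multinomial slide compositions, rater
    noise, macroscopic staging error) so the full pipeline is testable
    without raw slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Preprocessing, Classification, Epidemiology
RoxygenNote: 7.3.3
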