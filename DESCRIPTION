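Package: osteodens
Title: Opportunistic CT Densitometry of the Proximal Humerus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies cancellous bone quality of the humeral head from
    CT-like volumes by three complementary workflows: an ROI-averaged
    mean-attenuation index computed on maximum-intensity projections, a
    phantom-calibrated cancellous volumetric bone mineral density
    measurement, and a threshold-segmentation trabecular density workflow.
    Includes the repeated-measures statistics used to compare the methods
    across clinical CT and micro-CT (paired tests with effect sizes,
    regression diagnostics with the Durbin-Watson statistic, Mauchly's
    sphericity test and Greenhouse-Geisser corrected within-subject
    ANOVA), and a synthetic-cohort generator producing humeral-head
    phantoms with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
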