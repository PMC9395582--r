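Package: cctascore
Title: Coronary Plaque Burden Scoring and Risk-Stratified Comparison for
    Coronary CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-patient coronary plaque burden scores from
    segment-level coronary CT angiography (CCTA) lesion annotations on the
    18-segment SCCT coronary model: the segment involvement score (SIS),
    segment stenosis score (SSS), stenosis coefficient (SC), severe
    proximal plaque (SPP) flag, obstructive-stenosis flag, and the
    CCTA-adapted Leaman score (CT-LeSc) with dominance-dependent
    localization weights.  Includes eligibility screening and UKPDS-based
    10-year fatal coronary-heart-disease risk tiering for type 2 diabetes
    cohorts, a nonparametric group-comparison battery (Mann-Whitney,
    Kruskal-Wallis with Bonferroni post-hoc, chi-squared, binary logistic
    odds ratios), a seeded synthetic cohort generator for end-to-end
    pipeline testing, and delimited-text readers/writers with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
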