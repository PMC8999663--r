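Package: ctperf
Title: Quantitative Myocardial Perfusion Analysis for Static Cardiac CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying myocardial perfusion from static cardiac
    computed-tomography perfusion (CTP) images. Implements the myocardial
    perfusion ratio (MPR) -- subendocardial enhancement normalised by the
    aortic peak enhancement of a diluted timing-bolus scan -- alongside the
    conventional endocardial CT attenuation and transmural perfusion ratio
    (TPR), mapped onto the AHA 16-segment model of the left ventricle.
    Includes a seeded synthetic phantom cohort generator (contrast kinetics,
    dynamic series, short-axis image stacks, SPECT-like segment truth),
    time-attenuation-curve analysis, automatic segment and layer measurement,
    and a from-scratch diagnostic-accuracy toolkit (empirical ROC/AUC with
    DeLong variance and paired tests, Youden cutoffs, Wilson intervals,
    Mann-Whitney U, Cohen's kappa, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
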