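Package: lvadpet
Title: Quantitative FDG-PET Analysis of LVAD Device Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volume-of-interest based quantification of [18F]FDG-PET scans of
    left ventricular assist device (LVAD) recipients with suspected device
    infection. Provides SUV normalization of activity-concentration volumes,
    threshold-based metabolic-volume segmentation (fixed absolute SUV and
    fixed relative fraction-of-SUVmax rules) yielding metabolic tumor volume
    (MTV) and total lesion glycolysis (TLG) per device component,
    semiquantitative lesion metrics (SUVmax, SUVmean, SUVpeak,
    lesion-to-background ratio) and total metabolic burden over the five LVAD
    components, two-group cohort comparison, and diagnostic evaluation with
    empirical ROC curves, DeLong AUC variance and paired AUC comparison,
    Youden-optimal cutoffs, and prevalence-adjusted predictive values.
    Includes a digital-phantom and cohort simulator with analytic ground
    truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
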