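Package: naquant
Title: Quantitative Multi-Echo Sodium MRI Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative brain sodium (23Na) MRI from multi-echo
    acquisitions. Fits biexponential T2* decay with a Rician noise floor to
    ROI-mean signal curves, fits reference-tube curves monoexponentially,
    calibrates magnetization against known phantom concentrations, and derives
    short- and long-fraction sodium concentrations (Na_SF, Na_LF), total sodium
    concentration (TSC) and the extracellular fraction (EcF). Includes a seeded
    synthetic-cohort generator emulating a 24-echo acquisition over ten brain
    regions, factorial ANOVA and Steel-Dwass all-pairs nonparametric post-hoc
    statistics, and an end-to-end pipeline with CSV/NIfTI interfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
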