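Package: vffr1d
Title: One-Dimensional Virtual Fractional Flow Reserve with
    Side-Branch Leakage Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes virtual fractional flow reserve (vFFR) from a
    coronary centreline radius profile and boundary conditions using
    one-dimensional steady-flow models that differ in how side-branch
    "leakage" flow is represented: no leak, homogenous, localized
    (taper-proportional), pressure-conductance, and porous-wall
    (Darcy-Forchheimer) leakage. Includes Fourier-filtration estimation
    of the hypothetical healthy lumen, an empirically lumped stenosis
    pressure-drop sub-model, microvascular-resistance coupled inlet-flow
    optimisation, a seeded synthetic vessel and cohort generator, and a
    method-comparison statistics battery (quantile-regression
    Bland-Altman, Passing-Bablok regression, Clopper-Pearson exact
    diagnostic metrics, ROC/AUC, chi-square, and exact noncentral-t
    paired sample-size calculation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
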