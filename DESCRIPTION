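Package: burnmech
Title: Mechanical Characterization and Statistical Comparison of Burned Skin Tensile Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the tensile mechanics of two soft-tissue
    populations (full-thickness burned human and porcine skin) from uniaxial
    force-displacement records. Converts raw records to nominal stress-strain
    curves; extracts ultimate tensile stress, ultimate tensile strain and
    toughness; fits the two-parameter Veronda-Westmann hyperelastic model by
    profiled nonlinear least squares; applies a decision-tree univariate test
    procedure (Shapiro-Wilk, F, t, Kolmogorov-Smirnov, Wilcoxon), Cohen's d
    effect sizes and exact noncentral-t power and sample-size calculations;
    and classifies tissue type by leave-one-out cross-validated ridge-stabilized
    logistic regression with an eight-metric performance suite. Includes a
    seeded synthetic tensile-test generator so the whole pipeline is testable
    without access to specimen data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
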