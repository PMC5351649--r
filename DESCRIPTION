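Package: mirpanel
Title: Circulating miRNA Diagnostic Panel Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A four-phase workflow for discovering and validating circulating
    microRNA diagnostic panels from qRT-PCR data: pooled-sample screening
    filters (detection gate, pool fold-change gate), qRT-PCR verification,
    absolute quantification via standard curves and spike-in normalization,
    2^-ddCt relative expression, and construction of a dichotomized
    risk-score panel (per-miRNA ROC cutoffs weighted by univariate logistic
    regression coefficients) that transfers to new cohorts with frozen
    cutoffs. Includes a synthetic case/control cohort generator
    (moment-matched lognormal concentrations with a Gaussian copula) so the
    full pipeline is testable without patient data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
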