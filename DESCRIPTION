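Package: uhrisk
Title: Early Risk Modelling of Uncomplicated Hypertension in Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building early risk models of uncomplicated
    hypertension in pregnancy from ambulatory blood-pressure indices and
    first-trimester biomarkers. Provides a synthetic cohort simulator with
    configurable marginals and a nonlinear outcome mechanism, descriptive
    group comparisons (median/IQR, Mann-Whitney, chi-squared/Fisher),
    construction of a cross-validated polynomial-logit biomarker index from
    uric acid and the sFlt-1/PlGF ratio, multivariate logistic risk models
    with Wald odds ratios, omnibus and Hosmer-Lemeshow diagnostics,
    Nagelkerke R-squared and ROC/AUC with Hanley-McNeil standard errors,
    and Bayesian Beta-Binomial comparison of classifier accuracies.
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
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
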