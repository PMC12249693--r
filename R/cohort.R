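#' Default marginal distributions for the synthetic cohort
#'
#' One row per continuous variable: the target median and interquartile range
#' on measurement units, the distribution family used to reach them, and a
#' plausibility range the draws are clamped to. Medians/IQRs for office blood
#' pressure, biochemistry and demographics follow the study cohort's printed
#' summaries (n = 132 pregnancies at moderate cardiovascular risk); the
#' 24-h/daytime/nighttime ambulatory indices, for which no population table is
#' printed, default to clinically plausible values for such a cohort (about a
#' 12% nocturnal systolic dip).
#'
#' Angiogenic markers and uric acid use lognormal marginals (their IQRs are of
#' the order of their medians, i.e. heavy right skew); all other variables are
#' normal, truncated to `lower`/`upper`.
#'
#' @return A tibble with columns `variable`, `dist` (`"normal"` or
#'   `"lognormal"`), `median`, `iqr`, `lower`, `upper`.
#' @export
default_marginals <- function() {
  tibble::tribble(
    ~variable,    ~dist,       ~median, ~iqr,   ~lower, ~upper,
    "age",        "normal",     36,      8.0,    18,     52,
    "bmi",        "normal",     30.8,    11.3,   16,     60,
    "heart_rate", "normal",     90.0,    18.0,   45,     160,
    "office_sbp", "normal",     134.5,   12.8,   80,     220,
    "office_dbp", "normal",     81.0,    13.8,   40,     140,
    "sbp_24h",    "normal",     122,     12,     40,     260,
    "sbp_day",    "normal",     126,     12,     40,     260,
    "sbp_night",  "normal",     111,     13,     40,     260,
    "dbp_24h",    "normal",     76,      11,     40,     260,
    "dbp_day",    "normal",     79,      11,     40,     260,
    "dbp_night",  "normal",     66,      12,     40,     260,
    "uric_acid",  "lognormal",  4.1,     1.38,   NA,     NA,
    "sflt1",      "lognormal",  1908.0,  2683.3, NA,     NA,
    "plgf",       "lognormal",  215.5,   250.8,  NA,     NA
  )
}

#' Default latent correlation matrix for the synthetic cohort
#'
#' Correlations are imposed on the Gaussian copula scores underlying the
#' continuous marginals. The study reports no correlation structure, so these
#' are configurable package defaults: strong coherence among ambulatory
#' blood-pressure indices (24-h vs daytime r = 0.9), moderate office-ambulatory
#' agreement (r = 0.6), moderate systolic-diastolic coupling, weak
#' anthropometric and metabolic links, and a mild positive sFlt-1/PlGF
#' association.
#'
#' The stylized target values below are not jointly positive definite, so the
#' returned matrix is the nearest correlation matrix to the target
#' (`Matrix::nearPD`); entries move by only a few hundredths.
#'
#' @return A symmetric positive-definite correlation matrix whose dimnames are
#'   the continuous cohort variables.
#' @export
default_correlation <- function() {
  vars <- default_marginals()$variable
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  # systolic block
  set_r("office_sbp", "sbp_24h", 0.60)
  set_r("office_sbp", "sbp_day", 0.60)
  set_r("office_sbp", "sbp_night", 0.55)
  set_r("sbp_24h", "sbp_day", 0.90)
  set_r("sbp_24h", "sbp_night", 0.85)
  set_r("sbp_day", "sbp_night", 0.70)
  # diastolic block
  set_r("office_dbp", "dbp_24h", 0.60)
  set_r("office_dbp", "dbp_day", 0.60)
  set_r("office_dbp", "dbp_night", 0.55)
  set_r("dbp_24h", "dbp_day", 0.90)
  set_r("dbp_24h", "dbp_night", 0.85)
  set_r("dbp_day", "dbp_night", 0.70)
  # systolic-diastolic coupling, same period stronger than cross-period
  set_r("office_sbp", "office_dbp", 0.60)
  set_r("sbp_24h", "dbp_24h", 0.65)
  set_r("sbp_day", "dbp_day", 0.65)
  set_r("sbp_night", "dbp_night", 0.65)
  for (s in c("sbp_24h", "sbp_day", "sbp_night")) {
    for (d in c("dbp_24h", "dbp_day", "dbp_night")) {
      if (R[s, d] == 0) set_r(s, d, 0.45)
    }
  }
  for (d in c("dbp_24h", "dbp_day", "dbp_night")) set_r("office_sbp", d, 0.40)
  for (s in c("sbp_24h", "sbp_day", "sbp_night")) set_r("office_dbp", s, 0.40)
  # demographics / metabolism
  set_r("age", "bmi", 0.10)
  for (bp in c("office_sbp", "office_dbp")) set_r("bmi", bp, 0.20)
  for (bp in c("sbp_24h", "sbp_day", "sbp_night",
               "dbp_24h", "dbp_day", "dbp_night")) set_r("bmi", bp, 0.15)
  set_r("heart_rate", "office_sbp", 0.10)
  set_r("heart_rate", "office_dbp", 0.10)
  set_r("uric_acid", "bmi", 0.20)
  for (bp in c("office_sbp", "office_dbp", "sbp_24h", "sbp_day", "sbp_night",
               "dbp_24h", "dbp_day", "dbp_night")) set_r("uric_acid", bp, 0.10)
  set_r("sflt1", "plgf", 0.30)
  R <- as.matrix(Matrix::nearPD(R, corr = TRUE, posd.tol = 1e-4)$mat)
  dimnames(R) <- list(vars, vars)
  R
}

default_binary_prevalence <- function() {
  # Table-1-style prevalences on n = 132; antihypertensive drugs are
  # conditioned on essential hypertension (22 of the 55 hypertensive women).
  c(primipara = 49 / 132,
    former_smoker = 16 / 132,
    ckd = 6 / 132,
    dm = 9 / 132,
    essential_ht = 55 / 132,
    ht_drugs_given_ht = 22 / 55)
}

default_outcome_model <- function() {
  # True risk surface: logit P(UH) = intercept + beta_nsbp * (nSBP - center)
  # + a degree-2 polynomial in the standardized log biomarkers. The quadratic
  # coefficients are the three second-order terms of the reference index
  # equation; the linear terms default to zero so first-order marginal
  # associations of each biomarker with the outcome stay weak (as in the
  # study cohort) while a degree-2 model has real signal to find.
  list(
    intercept = NULL, # NULL = calibrated to `uh_prevalence` at generation time
    beta_nsbp = 0.098,
    nsbp_center = 111,
    surface = c(ua = 0, af = 0,
                ua2 = -0.9713, ua_af = 1.4606, af2 = -0.3904),
    night_shift_sbp = 0,
    night_shift_dbp = 0
  )
}

#' Configure the synthetic cohort generator
#'
#' @param n_subjects Number of pregnancies to simulate (>= 20).
#' @param uh_prevalence Target prevalence of uncomplicated hypertension,
#'   strictly between 0 and 1. Default 72/132.
#' @param seed Integer seed; the same configuration always yields an identical
#'   cohort.
#' @param marginals Tibble as produced by [default_marginals()]; rows may be
#'   edited but all fourteen variables must be present with positive `iqr`.
#' @param correlation Latent Gaussian-copula correlation matrix over the
#'   marginal variables; see [default_correlation()].
#' @param binary_prevalence Named vector of prevalences for the binary
#'   covariates (`primipara`, `former_smoker`, `ckd`, `dm`, `essential_ht`)
#'   plus `ht_drugs_given_ht`, the probability of antihypertensive treatment
#'   among women with essential hypertension (treatment implies hypertension).
#' @param outcome Outcome-mechanism parameters; see the list returned by the
#'   default. `intercept = NULL` requests calibration of the intercept so the
#'   realized event probability averages to `uh_prevalence`. `surface` holds
#'   the degree-2 coefficients on standardized log uric acid (`ua`) and log
#'   sFlt-1/PlGF ratio (`af`). `night_shift_*` add a fixed mmHg offset to the
#'   nighttime indices of cases after the outcome is drawn (default 0, which
#'   keeps the outcome model exactly as written).
#' @return A `uh_cohort_config` object (a list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 132,
                          uh_prevalence = 72 / 132,
                          seed = 1L,
                          marginals = default_marginals(),
                          correlation = default_correlation(),
                          binary_prevalence = default_binary_prevalence(),
                          outcome = list()) {
  check_number(n_subjects, "n_subjects", lower = 20)
  if (!is.numeric(uh_prevalence) || length(uh_prevalence) != 1 ||
      uh_prevalence <= 0 || uh_prevalence >= 1) {
    abort("`uh_prevalence` must lie strictly between 0 and 1.",
          class = "uhrisk_config_error")
  }
  check_number(seed, "seed")
  need <- default_marginals()$variable
  if (!all(need %in% marginals$variable)) {
    abort(paste0("`marginals` is missing: ",
                 paste(setdiff(need, marginals$variable), collapse = ", ")),
          class = "uhrisk_config_error")
  }
  if (any(!is.finite(marginals$median)) || any(marginals$median <= 0) ||
      any(!is.finite(marginals$iqr)) || any(marginals$iqr <= 0)) {
    abort("marginal medians and IQRs must be positive and finite.",
          class = "uhrisk_config_error")
  }
  if (!isTRUE(all.equal(rownames(correlation), need)) ||
      !isTRUE(all.equal(colnames(correlation), need))) {
    abort("`correlation` dimnames must match the marginal variables.",
          class = "uhrisk_config_error")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    abort("`correlation` must be positive definite.",
          class = "uhrisk_config_error")
  }
  prev <- modifyList(as.list(default_binary_prevalence()),
                     as.list(binary_prevalence))
  if (any(unlist(prev) < 0 | unlist(prev) > 1)) {
    abort("binary prevalences must lie in [0, 1].",
          class = "uhrisk_config_error")
  }
  out <- modifyList(default_outcome_model(), outcome)
  structure(
    list(n_subjects = as.integer(n_subjects),
         uh_prevalence = uh_prevalence,
         seed = as.integer(seed),
         marginals = marginals[match(need, marginals$variable), , drop = FALSE],
         correlation = correlation,
         binary_prevalence = prev,
         outcome = out),
    class = "uh_cohort_config"
  )
}

# Population-scale location/scale of log uric acid and the log sFlt-1/PlGF
# ratio implied by a config; used both by the outcome mechanism and by tests
# that need the generator's true standardization.
biomarker_log_moments <- function(config) {
  m <- config$marginals
  row <- function(v) m[m$variable == v, ]
  ua <- row("uric_acid"); s <- row("sflt1"); p <- row("plgf")
  sd_ua <- lognormal_sdlog_from_iqr(ua$median, ua$iqr)
  sd_s <- lognormal_sdlog_from_iqr(s$median, s$iqr)
  sd_p <- lognormal_sdlog_from_iqr(p$median, p$iqr)
  rho <- config$correlation["sflt1", "plgf"]
  list(
    ua = c(mean = log(ua$median), sd = sd_ua),
    af = c(mean = log(s$median) - log(p$median),
           sd = sqrt(sd_s^2 + sd_p^2 - 2 * rho * sd_s * sd_p))
  )
}

#' True standardized biomarker scores under a generator configuration
#'
#' Returns, for each subject, the generator's own standardized log uric acid
#' (`z_ua`) and standardized log sFlt-1/PlGF ratio (`z_af`) — the variables
#' the outcome surface is written in. Mainly useful for parameter-recovery
#' checks where the correctly specified model must be fitted.
#'
#' @param cohort A cohort tibble.
#' @param config The `uh_cohort_config` that generated it (or whose scaling
#'   should be applied).
#' @return The cohort with `z_ua` and `z_af` columns appended.
#' @export
biomarker_scores <- function(cohort, config) {
  mom <- biomarker_log_moments(config)
  dplyr::mutate(
    cohort,
    z_ua = (log(.data$uric_acid) - mom$ua[["mean"]]) / mom$ua[["sd"]],
    z_af = (log(.data$sflt1 / .data$plgf) - mom$af[["mean"]]) / mom$af[["sd"]]
  )
}

outcome_linear_predictor <- function(config, cohort) {
  sc <- biomarker_scores(cohort, config)
  o <- config$outcome
  s <- o$surface
  o$beta_nsbp * (cohort$sbp_night - o$nsbp_center) +
    s[["ua"]] * sc$z_ua + s[["af"]] * sc$z_af +
    s[["ua2"]] * sc$z_ua^2 + s[["ua_af"]] * sc$z_ua * sc$z_af +
    s[["af2"]] * sc$z_af^2
}

#' Generate a synthetic pregnancy cohort
#'
#' Draws `n_subjects` records with the configured marginals (Gaussian copula
#' over normal/lognormal marginals back-solved from median and IQR), binary
#' covariates at their configured prevalences (antihypertensive treatment only
#' among hypertensive women), and a binary uncomplicated-hypertension outcome
#' from a logistic mechanism that increases with nighttime systolic pressure
#' and depends on a degree-2 surface in the standardized log biomarkers.
#'
#' When `outcome$intercept` is `NULL` the intercept is calibrated by
#' root-finding so the mean event probability over the realized covariates
#' equals `uh_prevalence`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject and the documented cohort columns
#'   (see [cohort_columns()]).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 132, seed = 7))
#' mean(cohort$uh)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "uh_cohort_config")) {
    abort("`config` must be created by cohort_config().",
          class = "uhrisk_config_error")
  }
  n <- config$n_subjects
  m <- config$marginals
  withr::with_seed(config$seed, {
    z <- matrix(rnorm(n * nrow(m)), n, nrow(m)) %*% chol(config$correlation)
    colnames(z) <- m$variable
    cont <- purrr::pmap_dfc(m, function(variable, dist, median, iqr, lower, upper) {
      zi <- z[, variable]
      x <- if (dist == "lognormal") {
        exp(log(median) + lognormal_sdlog_from_iqr(median, iqr) * zi)
      } else {
        pmin(pmax(median + normal_sd_from_iqr(iqr) * zi, lower), upper)
      }
      tibble::tibble(!!variable := x)
    })
    prev <- config$binary_prevalence
    essential_ht <- rbinom(n, 1, prev$essential_ht) == 1
    ht_drugs <- essential_ht & rbinom(n, 1, prev$ht_drugs_given_ht) == 1
    cohort <- tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      primipara = rbinom(n, 1, prev$primipara) == 1,
      former_smoker = rbinom(n, 1, prev$former_smoker) == 1,
      essential_ht = essential_ht,
      ht_drugs = ht_drugs,
      ckd = rbinom(n, 1, prev$ckd) == 1,
      dm = rbinom(n, 1, prev$dm) == 1
    )
    cohort <- dplyr::bind_cols(cohort, cont)
    lp <- outcome_linear_predictor(config, cohort)
    b0 <- config$outcome$intercept
    if (is.null(b0)) {
      b0 <- uniroot(function(c) mean(plogis(c + lp)) - config$uh_prevalence,
                    c(-40, 40), tol = 1e-10)$root
    }
    cohort$uh <- rbinom(n, 1, plogis(b0 + lp)) == 1
    cohort$sbp_night <- pmin(pmax(
      cohort$sbp_night + config$outcome$night_shift_sbp * cohort$uh, 40), 260)
    cohort$dbp_night <- pmin(pmax(
      cohort$dbp_night + config$outcome$night_shift_dbp * cohort$uh, 40), 260)
    cohort[, cohort_columns()$column]
  })
}

#' Cohort file schema
#'
#' The fixed column set (and CSV header order) of a cohort table: an opaque
#' subject `id`, six logical covariates, eleven continuous measurements on
#' their clinical units, the two angiogenic markers and uric acid, and the
#' logical `uh` outcome.
#'
#' @return A tibble with columns `column` and `type` (`"character"`,
#'   `"logical"` or `"double"`).
#' @export
cohort_columns <- function() {
  tibble::tibble(
    column = c("id", "primipara", "former_smoker", "essential_ht", "ht_drugs",
               "ckd", "dm", "age", "bmi", "heart_rate", "office_sbp",
               "office_dbp", "sbp_24h", "sbp_day", "sbp_night", "dbp_24h",
               "dbp_day", "dbp_night", "uric_acid", "sflt1", "plgf", "uh"),
    type = c("character", rep("logical", 6), rep("double", 14), "logical")
  )
}

#' Validate a cohort table
#'
#' Checks the schema of [cohort_columns()] and the record invariants: all
#' blood pressures positive with daytime/nighttime indices inside
#' \[40, 260\] mmHg, positive BMI, uric acid, sFlt-1 and PlGF. Errors name
#' the offending column and row.
#'
#' @param cohort A data frame to validate.
#' @return The cohort, invisibly, as a tibble.
#' @export
validate_cohort <- function(cohort) {
  schema <- cohort_columns()
  missing <- setdiff(schema$column, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")),
          class = "uhrisk_parse_error")
  }
  cohort <- tibble::as_tibble(cohort)[, schema$column]
  fail <- function(column, rows, why) {
    abort(sprintf("cohort column `%s` %s (first bad row: %d).",
                  column, why, rows[1]),
          class = "uhrisk_validation_error")
  }
  for (col in schema$column[schema$type == "double"]) {
    x <- cohort[[col]]
    if (!is.numeric(x)) fail(col, 1L, "is not numeric")
    bad <- which(!is.finite(x))
    if (length(bad)) fail(col, bad, "has missing or non-finite values")
  }
  for (col in c("bmi", "uric_acid", "sflt1", "plgf", "office_sbp", "office_dbp",
                "sbp_24h", "dbp_24h", "heart_rate")) {
    bad <- which(cohort[[col]] <= 0)
    if (length(bad)) fail(col, bad, "must be strictly positive")
  }
  for (col in c("sbp_day", "sbp_night", "dbp_day", "dbp_night")) {
    bad <- which(cohort[[col]] < 40 | cohort[[col]] > 260)
    if (length(bad)) fail(col, bad, "must lie within [40, 260] mmHg")
  }
  for (col in schema$column[schema$type == "logical"]) {
    if (!is.logical(cohort[[col]])) fail(col, 1L, "is not logical")
    bad <- which(is.na(cohort[[col]]))
    if (length(bad)) fail(col, bad, "has missing values")
  }
  if (anyDuplicated(cohort$id)) {
    fail("id", which(duplicated(cohort$id)), "has duplicated subject ids")
  }
  invisible(cohort)
}

#' Write / read a cohort CSV
#'
#' The on-disk format is a plain CSV with exactly the header of
#' [cohort_columns()]; logicals are written as `TRUE`/`FALSE`. Reading
#' validates the schema and record invariants, so a round trip through disk
#' is lossless.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  schema <- cohort_columns()
  spec <- do.call(readr::cols_only, c(
    setNames(lapply(schema$type, function(t) switch(t,
      character = readr::col_character(),
      logical = readr::col_logical(),
      double = readr::col_double())), schema$column)
  ))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(schema$column, header)
  if (length(missing) > 0) {
    abort(paste0("cohort file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "uhrisk_parse_error")
  }
  # parsing issues surface as structured errors below, not readr warnings
  cohort <- suppressWarnings(
    readr::read_csv(path, col_types = spec, show_col_types = FALSE))
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    abort(sprintf("could not parse cohort file: row %d, column `%s` (%s).",
                  probs$row[1], header[probs$col[1]], probs$expected[1]),
          class = "uhrisk_parse_error")
  }
  validate_cohort(cohort)
  cohort
}
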