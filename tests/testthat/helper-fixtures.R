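# Shared fixtures, built in code at test time.

# one default cohort per size, cached across test files
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n = 132, seed = 7) {
  key <- paste0("n", n, "_s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      cohort_config(n_subjects = n, seed = seed))
  }
  .cohort_cache[[key]]
}

# attach the out-of-fold index value as a predictor column
with_index_column <- function(cohort, index) {
  out <- dplyr::left_join(cohort, index$oof[, c("id", "oof_logit")], by = "id")
  dplyr::rename(out, uaaf_index = "oof_logit")
}

# printed coefficient rows of the published risk-model tables
# (B, SE, Exp(B), CI as printed; used to check Wald odds-ratio arithmetic)
table3_fixture <- function() {
  tibble::tribble(
    ~model,        ~term,           ~b,     ~se,    ~exp_b, ~ci_lo, ~ci_hi,
    "office_sbp",  "former_smoker", 1.678,  0.685,  5.354,  1.398,  20.507,
    "office_sbp",  "ht_drugs",      1.790,  0.607,  5.987,  1.821,  19.686,
    "office_sbp",  "office_sbp",    0.043,  0.017,  1.044,  1.010,  1.079,
    "osbp_uaaf",   "former_smoker", 1.964,  0.759,  7.128,  1.610,  31.561,
    "osbp_uaaf",   "ht_drugs",      1.989,  0.676,  7.311,  1.944,  27.488,
    "osbp_uaaf",   "office_sbp",    0.046,  0.018,  1.047,  1.010,  1.086,
    "osbp_uaaf",   "uaaf_index",    1.029,  0.293,  2.799,  1.575,  4.973,
    "nsbp",        "ht_drugs",      1.555,  0.661,  4.736,  1.297,  17.292,
    "nsbp",        "nsbp",          0.087,  0.018,  1.091,  1.054,  1.130,
    "nsbp_uaaf",   "ht_drugs",      1.264,  0.662,  3.540,  0.968,  12.952,
    "nsbp_uaaf",   "nsbp",          0.098,  0.020,  1.103,  1.060,  1.149,
    "nsbp_uaaf",   "uaaf_index",    1.039,  0.327,  2.826,  1.490,  5.361,
    "office_dbp",  "former_smoker", 1.811,  0.705,  6.115,  1.537,  24.335,
    "office_dbp",  "ht_drugs",      1.764,  0.608,  5.838,  1.773,  19.22,
    "office_dbp",  "office_dbp",    0.063,  0.019,  1.065,  1.026,  1.106,
    "ndbp",        "ndbp",          0.117,  0.026,  1.124,  1.069,  1.181,
    "ndbp_uaaf",   "ndbp",          0.120,  0.028,  1.128,  1.068,  1.191,
    "ndbp_uaaf",   "uaaf_index",    1.004,  0.327,  2.729,  1.437,  5.182
  )
}

# reference full-data index equation (degree 2, inputs on the model scale)
reference_index_coefficients <- function() {
  c(intercept = 0.3855, ua = 0.4989, af = -0.2740,
    ua2 = -0.9713, ua_af = 1.4606, af2 = -0.3904)
}

# a clearly degree-2 generator config (the quadratic-only default surface)
degree2_config <- function(n, seed) {
  cohort_config(n_subjects = n, seed = seed)
}

# ten-subject toy cohort for boundary cases (leave-one-out CV)
tiny_cohort <- function() {
  tibble::tibble(
    id = sprintf("T%02d", 1:10),
    uric_acid = c(3.1, 3.5, 4.0, 4.4, 4.9, 5.3, 5.8, 6.1, 6.6, 7.0),
    sflt1 = c(900, 1200, 1500, 1700, 2100, 2500, 2900, 3300, 3800, 4200),
    plgf = c(300, 280, 250, 240, 200, 180, 150, 140, 120, 100),
    uh = rep(c(FALSE, TRUE), each = 5)
  )
}
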