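#' Nocturnal blood-pressure dipping
#'
#' The percentage fall of the nighttime index relative to the daytime index,
#' `100 * (day - night) / day`. Negative values indicate a riser pattern.
#' Vectorized; both arguments recycle.
#'
#' @param day_value Daytime average (mmHg); must be positive.
#' @param night_value Nighttime average (mmHg).
#' @return Dipping in percent.
#' @examples
#' dipping(120, 108) # 10
#' @export
dipping <- function(day_value, night_value) {
  if (any(!is.finite(day_value)) || any(day_value <= 0)) {
    abort("`day_value` must be positive.", class = "uhrisk_domain_error")
  }
  100 * (day_value - night_value) / day_value
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), the convention fixed package-wide so reported
#' IQRs are reproducible.
#'
#' @param values Non-empty numeric vector without missing values.
#' @return A tibble with columns `median` and `iqr`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("`values` must be a non-empty numeric vector without missing values.",
          class = "uhrisk_domain_error")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], iqr = q[3] - q[1])
}

# exact two-sided Mann-Whitney p by full enumeration of group labelings;
# handles ties, feasible for combined n <= 10 (<= 252 labelings)
mann_whitney_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  centre <- n1 * length(b) / 2
  labelings <- utils::combn(length(pooled), n1, simplify = FALSE)
  us <- vapply(labelings, u_stat, numeric(1))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two independent samples. For combined sample sizes
#' of 10 or fewer the p-value is computed by exact enumeration of all group
#' labelings (valid under ties); otherwise the tie-corrected normal
#' approximation with continuity correction is used, which tracks the exact
#' enumeration closely even at small sample sizes.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact `"auto"` (enumerate when combined n <= 10), `TRUE` or `FALSE`.
#' @return A tibble with `u` (the U statistic of `group_a`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(group_a, group_b, exact = "auto") {
  if (length(group_a) == 0 || length(group_b) == 0 ||
      any(!is.finite(c(group_a, group_b)))) {
    abort("both groups must be non-empty and finite.",
          class = "uhrisk_domain_error")
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  u <- sum(outer(group_a, group_b, ">")) +
    0.5 * sum(outer(group_a, group_b, "=="))
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n1 + n2 <= 10)
  if (use_exact) {
    p <- mann_whitney_exact_p(group_a, group_b)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(c(group_a, group_b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1 # all observations identical
    } else {
      z <- max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2)
      p <- 2 * pnorm(-z)
    }
    method <- "normal"
  }
  tibble::tibble(u = u, p_value = min(p, 1), method = method)
}

#' Chi-squared or Fisher's exact test for a 2x2 table
#'
#' Pearson's chi-squared test without continuity correction when every
#' expected count is at least 5, otherwise Fisher's exact test (two-sided).
#' The returned `test` column reports which ran.
#'
#' @param table_2x2 A 2x2 matrix of nonnegative integer counts with positive
#'   row and column margins.
#' @return A tibble with `statistic` (NA for Fisher), `p_value` and `test`.
#' @examples
#' chi_squared_or_fisher(matrix(c(4, 18, 56, 54), 2))
#' @export
chi_squared_or_fisher <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round_half_up(tab))) {
    abort("`table_2x2` must be a 2x2 matrix of nonnegative integer counts.",
          class = "uhrisk_domain_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all row and column margins must be positive.",
          class = "uhrisk_domain_error")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(ct$statistic),
                   p_value = unname(ct$p.value),
                   test = "pearson")
  } else {
    ft <- fisher.test(tab)
    tibble::tibble(statistic = NA_real_,
                   p_value = unname(ft$p.value),
                   test = "fisher")
  }
}

#' Baseline group comparisons for a cohort
#'
#' Builds a baseline-characteristics table comparing subjects with and without
#' the outcome: continuous variables as median (IQR) per group with a
#' Mann-Whitney p-value, binary variables as count (percent) per group with a
#' chi-squared or Fisher p-value (see [chi_squared_or_fisher()]). Derived
#' sFlt-1/PlGF ratio and nocturnal dipping columns are added before
#' summarizing.
#'
#' @param cohort A cohort tibble (see [cohort_columns()]).
#' @param outcome Name of the logical outcome column. Default `"uh"`.
#' @return A tibble with one row per variable: `variable`, `kind`
#'   (`"continuous"`/`"binary"`), group summaries (`*_no`, `*_yes` columns),
#'   `test`, `statistic` and `p_value`.
#' @export
describe_cohort <- function(cohort, outcome = "uh") {
  cohort <- dplyr::mutate(
    cohort,
    af_ratio = .data$sflt1 / .data$plgf,
    sbp_dipping = dipping(.data$sbp_day, .data$sbp_night),
    dbp_dipping = dipping(.data$dbp_day, .data$dbp_night)
  )
  y <- cohort[[outcome]]
  if (!is.logical(y) || any(is.na(y))) {
    abort("`outcome` must name a complete logical column.",
          class = "uhrisk_domain_error")
  }
  cont_vars <- c("age", "bmi", "heart_rate", "office_sbp", "office_dbp",
                 "sbp_24h", "sbp_day", "sbp_night", "dbp_24h", "dbp_day",
                 "dbp_night", "uric_acid", "sflt1", "plgf", "af_ratio",
                 "sbp_dipping", "dbp_dipping")
  bin_vars <- c("primipara", "former_smoker", "essential_ht", "ht_drugs",
                "ckd", "dm")
  cont <- purrr::map_dfr(intersect(cont_vars, names(cohort)), function(v) {
    x <- cohort[[v]]
    s0 <- median_iqr(x[!y]); s1 <- median_iqr(x[y])
    mw <- mann_whitney(x[y], x[!y])
    tibble::tibble(variable = v, kind = "continuous",
                   median_no = s0$median, iqr_no = s0$iqr,
                   median_yes = s1$median, iqr_yes = s1$iqr,
                   count_no = NA_real_, percent_no = NA_real_,
                   count_yes = NA_real_, percent_yes = NA_real_,
                   test = paste0("mann_whitney_", mw$method),
                   statistic = mw$u, p_value = mw$p_value)
  })
  bin <- purrr::map_dfr(intersect(bin_vars, names(cohort)), function(v) {
    x <- cohort[[v]]
    tab <- matrix(c(sum(!y & x), sum(!y & !x), sum(y & x), sum(y & !x)),
                  nrow = 2, byrow = TRUE)
    res <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                     test = "degenerate")
    } else {
      chi_squared_or_fisher(tab)
    }
    tibble::tibble(variable = v, kind = "binary",
                   median_no = NA_real_, iqr_no = NA_real_,
                   median_yes = NA_real_, iqr_yes = NA_real_,
                   count_no = sum(!y & x), percent_no = 100 * mean(x[!y]),
                   count_yes = sum(y & x), percent_yes = 100 * mean(x[y]),
                   test = res$test, statistic = res$statistic,
                   p_value = res$p_value)
  })
  dplyr::bind_rows(cont, bin)
}
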