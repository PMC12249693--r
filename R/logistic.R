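#' Fit a binary logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a set of
#' predictor columns, with the reporting conventions of a clinical risk-model
#' table: coefficient `B`, standard error from the inverse observed
#' information, Wald statistic `(B/SE)^2` with a chi-squared p-value, odds
#' ratio `exp(B)` and its 95% Wald interval `exp(B +/- 1.96 SE)`.
#'
#' The fit refuses incomplete data, names collinear columns on rank
#' deficiency, and flags perfect separation as a distinct error instead of
#' returning silently diverged coefficients.
#'
#' @param data A data frame with complete rows for all used columns.
#' @param outcome Name of the logical (or 0/1) outcome column.
#' @param predictors Character vector of predictor column names; empty fits
#'   the intercept-only model.
#' @return A `uh_logit` object. Use [tidy()] for the coefficient table,
#'   [glance()] for model-level summaries, [omnibus_lrt()],
#'   [hosmer_lemeshow()] and [roc_auc()] for diagnostics.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit <- fit_logistic(cohort, "uh", c("sbp_night", "ht_drugs"))
#' tidy(fit)
#' @export
fit_logistic <- function(data, outcome, predictors = character()) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
          class = "uhrisk_domain_error")
  }
  df <- as.data.frame(data[, cols, drop = FALSE])
  if (!all(complete.cases(df))) {
    abort("missing values in the model frame; risk models require complete data.",
          class = "uhrisk_domain_error")
  }
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("`outcome` must be binary with both classes present.",
          class = "uhrisk_domain_error")
  }
  df[[outcome]] <- y
  # code logical predictors 0/1 so reported term names equal column names
  df[predictors] <- lapply(df[predictors], function(col) {
    if (is.logical(col)) as.numeric(col) else col
  })
  form <- stats::reformulate(if (length(predictors) == 0) "1" else predictors,
                             response = outcome)
  mm <- stats::model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "uhrisk_rank_error")
  }
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  # under (quasi-)complete separation every fitted probability collapses to
  # numerically 0 or 1 and the likelihood has no interior maximum
  mu <- fit$fitted.values
  if (!fit$converged || mean(mu * (1 - mu)) < 1e-8) {
    abort("logistic fit did not converge (perfect or quasi-perfect separation).",
          class = "uhrisk_separation_error")
  }
  n <- nrow(df)
  ll <- as.numeric(logLik(fit))
  ll_null <- if (length(predictors) == 0) ll else {
    as.numeric(logLik(glm(stats::reformulate("1", response = outcome),
                          data = df, family = binomial())))
  }
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  wald <- (b / se)^2
  table <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    wald = unname(wald),
    p_value = pchisq(unname(wald), df = 1, lower.tail = FALSE),
    odds_ratio = exp(unname(b)),
    ci_lower = exp(unname(b) - 1.96 * unname(se)),
    ci_upper = exp(unname(b) + 1.96 * unname(se))
  )
  structure(
    list(fit = fit, outcome = outcome, predictors = predictors,
         table = table, n = n, log_lik = ll, null_log_lik = ll_null,
         fitted = unname(fit$fitted.values), y = y),
    class = "uh_logit"
  )
}

#' @export
print.uh_logit <- function(x, ...) {
  cat(sprintf("Logistic risk model: %s ~ %s  (n = %d)\n", x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n))
  print(x$table)
  cat(sprintf("Nagelkerke R2 %.3f; accuracy %.3f at threshold 0.5\n",
              nagelkerke_r2(x), classification_accuracy(x$fitted, x$y)))
  invisible(x)
}

#' @export
tidy.uh_logit <- function(x, ...) x$table

#' @export
glance.uh_logit <- function(x, ...) {
  om <- omnibus_lrt(x)
  tibble::tibble(
    n = x$n, log_lik = x$log_lik, null_log_lik = x$null_log_lik,
    nagelkerke_r2 = nagelkerke_r2(x),
    accuracy = classification_accuracy(x$fitted, x$y),
    omnibus_statistic = om$statistic, omnibus_df = om$df,
    omnibus_p = om$p_value
  )
}

#' @export
predict.uh_logit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) {
    if (type == "response") object$fitted else predict(object$fit, type = type)
  } else {
    as.numeric(predict(object$fit, newdata = as.data.frame(newdata),
                       type = type))
  }
}

#' Omnibus likelihood-ratio test of model coefficients
#'
#' Tests the fitted model against the intercept-only model:
#' `statistic = 2 (LL_model - LL_null)` on as many degrees of freedom as
#' non-intercept terms, with an upper-tail chi-squared p-value.
#'
#' @param fit A `uh_logit` object.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
omnibus_lrt <- function(fit) {
  stopifnot(inherits(fit, "uh_logit"))
  stat <- max(0, 2 * (fit$log_lik - fit$null_log_lik))
  df <- length(coef(fit$fit)) - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE))
}

#' Nagelkerke pseudo R-squared
#'
#' Max-rescaled Cox-Snell R²:
#' `R2_CS = 1 - exp(2 (LL_null - LL_model) / n)` divided by its attainable
#' maximum `1 - exp(2 LL_null / n)`. Zero for the null model, approaching one
#' under perfect separation, and invariant to predictor rescaling.
#'
#' @param fit A `uh_logit` object.
#' @return A value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "uh_logit"))
  r2_cs <- 1 - exp(2 * (fit$null_log_lik - fit$log_lik) / fit$n)
  r2_max <- 1 - exp(2 * fit$null_log_lik / fit$n)
  min(1, max(0, r2_cs / r2_max))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by fitted probability into `g` groups of (near) equal
#' size — tied probabilities are kept in the same group, and when `n` is not a
#' multiple of `g` the remainder is spread one extra subject per group from
#' the first groups of the ranking. The statistic sums
#' `(observed - expected)^2 / expected` over groups and both outcome classes;
#' degrees of freedom are `groups - 2`. Groups whose expected count in either
#' class is zero are merged with their neighbour, with a warning.
#'
#' @param probabilities Fitted probabilities, strictly inside (0, 1).
#' @param outcomes Logical (or 0/1) outcomes.
#' @param g Number of groups (default 10); `n` must be at least `2 g`.
#' @return A tibble with `statistic`, `df`, `p_value` and `groups` (the
#'   number of groups actually used).
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, g = 10) {
  y <- as.integer(as.logical(outcomes))
  n <- length(y)
  if (n < 2 * g) {
    abort("need at least 2 subjects per group.", class = "uhrisk_domain_error")
  }
  if (any(probabilities <= 0 | probabilities >= 1)) {
    abort("`probabilities` must lie strictly inside (0, 1).",
          class = "uhrisk_domain_error")
  }
  ord <- order(probabilities)
  p <- probabilities[ord]
  yo <- y[ord]
  sizes <- rep(n %/% g, g) + (seq_len(g) <= n %% g)
  grp <- rep(seq_len(g), times = sizes)
  # keep ties together: every occurrence of a probability value takes the
  # group of its first occurrence in the ranking
  first_grp <- tapply(grp, p, function(x) x[1])
  grp <- as.integer(first_grp[as.character(p)])
  groups <- tibble::tibble(grp = grp, p = p, y = yo) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(n = dplyr::n(), obs1 = sum(.data$y),
                     exp1 = sum(.data$p), .groups = "drop")
  # merge any group with a zero expected count into its neighbour
  merged <- FALSE
  repeat {
    exp0 <- groups$n - groups$exp1
    bad <- which(groups$exp1 == 0 | exp0 == 0)
    if (length(bad) == 0 || nrow(groups) == 1) break
    i <- bad[1]
    j <- if (i == 1) 2 else i - 1
    groups$n[j] <- groups$n[j] + groups$n[i]
    groups$obs1[j] <- groups$obs1[j] + groups$obs1[i]
    groups$exp1[j] <- groups$exp1[j] + groups$exp1[i]
    groups <- groups[-i, ]
    merged <- TRUE
  }
  if (merged) {
    warn("Hosmer-Lemeshow: groups with zero expected counts were merged.")
  }
  g_eff <- nrow(groups)
  stat <- sum((groups$obs1 - groups$exp1)^2 / groups$exp1 +
                ((groups$n - groups$obs1) - (groups$n - groups$exp1))^2 /
                (groups$n - groups$exp1))
  df <- g_eff - 2L
  tibble::tibble(statistic = stat, df = df,
                 p_value = if (df < 1) NA_real_
                           else pchisq(stat, df, lower.tail = FALSE),
                 groups = g_eff)
}

#' Screen candidate confounders by the 10% odds-ratio-change rule
#'
#' Refits the exposure model once per candidate covariate and retains a
#' candidate when adding it changes the exposure's odds ratio by at least
#' `threshold` (relative change on the odds-ratio scale,
#' `|OR_adj - OR_crude| / OR_crude`). A candidate whose adjusted fit fails
#' (separation, collinearity) is reported with status `"undetermined"`, never
#' silently dropped.
#'
#' @param data Cohort data frame.
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the designated exposure (e.g. a BP index).
#' @param candidates Character vector of candidate covariate names.
#' @param covariates Covariates always kept in the base model.
#' @param threshold Relative odds-ratio change for retention (default 0.10).
#' @return A tibble with one row per candidate: `candidate`, `or_crude`,
#'   `or_adjusted`, `rel_change`, `retained`, `status`.
#' @export
screen_confounders <- function(data, outcome, exposure, candidates,
                               covariates = character(), threshold = 0.10) {
  base <- fit_logistic(data, outcome, c(exposure, covariates))
  or_crude <- base$table$odds_ratio[base$table$term == exposure]
  purrr::map_dfr(candidates, function(cand) {
    res <- tryCatch({
      adj <- fit_logistic(data, outcome, c(exposure, covariates, cand))
      or_adj <- adj$table$odds_ratio[adj$table$term == exposure]
      change <- abs(or_adj - or_crude) / or_crude
      tibble::tibble(candidate = cand, or_crude = or_crude,
                     or_adjusted = or_adj, rel_change = change,
                     retained = change >= threshold, status = "ok")
    }, error = function(e) {
      tibble::tibble(candidate = cand, or_crude = or_crude,
                     or_adjusted = NA_real_, rel_change = NA_real_,
                     retained = NA, status = "undetermined")
    })
    res
  })
}

#' Screen candidate interaction terms by Wald significance
#'
#' For each candidate pair, adds the product of the two (numeric-coded)
#' columns to the base predictor set and tests the product term's Wald
#' p-value against `alpha`.
#'
#' @param data Cohort data frame.
#' @param outcome Name of the binary outcome column.
#' @param predictors Base predictors kept in every model.
#' @param pairs List of length-2 character vectors naming candidate pairs.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per pair: `term_a`, `term_b`, `estimate`,
#'   `p_value`, `relevant`, `status`.
#' @export
screen_interactions <- function(data, outcome, predictors, pairs,
                                alpha = 0.05) {
  if (length(pairs) == 0) {
    return(tibble::tibble(term_a = character(), term_b = character(),
                          estimate = numeric(), p_value = numeric(),
                          relevant = logical(), status = character()))
  }
  purrr::map_dfr(pairs, function(pair) {
    a <- pair[[1]]; b <- pair[[2]]
    int_name <- paste0(a, "_x_", b)
    df <- data
    df[[int_name]] <- as.numeric(df[[a]]) * as.numeric(df[[b]])
    tryCatch({
      fit <- fit_logistic(df, outcome, unique(c(predictors, a, b, int_name)))
      row <- fit$table[fit$table$term == int_name, ]
      tibble::tibble(term_a = a, term_b = b, estimate = row$estimate,
                     p_value = row$p_value, relevant = row$p_value < alpha,
                     status = "ok")
    }, error = function(e) {
      tibble::tibble(term_a = a, term_b = b, estimate = NA_real_,
                     p_value = NA_real_, relevant = NA,
                     status = "undetermined")
    })
  })
}
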