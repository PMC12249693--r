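test_that("intercept-only fit returns the log-odds of the prevalence", {
  y <- rep(c(TRUE, FALSE), c(72, 60))
  df <- tibble::tibble(uh = y)
  fit <- fit_logistic(df, "uh")
  expect_equal(tidy(fit)$estimate[1], log(72 / 60), tolerance = 1e-6)
  expect_equal(nagelkerke_r2(fit), 0)
  om <- omnibus_lrt(fit)
  expect_equal(om$statistic, 0)
  expect_equal(om$p_value, 1)
})

test_that("published coefficient tables reconstruct their odds-ratio columns", {
  tab <- table3_fixture()
  # printed B and SE carry 3-decimal rounding, so reconstruction error grows
  # with the odds ratio itself: +/- 0.0005 on B is +/- 0.0005 * OR on exp(B)
  expect_true(all(abs(exp(tab$b) - tab$exp_b) <=
                    pmax(0.002, 0.00055 * tab$exp_b)))
  expect_true(all(abs(exp(tab$b - 1.96 * tab$se) - tab$ci_lo) <=
                    pmax(0.01, 0.0016 * tab$ci_lo)))
  expect_true(all(abs(exp(tab$b + 1.96 * tab$se) - tab$ci_hi) <=
                    pmax(0.01, 0.0016 * tab$ci_hi)))
  # and the package computes its odds-ratio columns the same way
  co <- cached_cohort()
  fit <- fit_logistic(co, "uh", c("sbp_night", "ht_drugs"))
  t <- tidy(fit)
  expect_equal(t$odds_ratio, exp(t$estimate))
  expect_equal(t$ci_lower, exp(t$estimate - 1.96 * t$std_error))
  expect_equal(t$ci_upper, exp(t$estimate + 1.96 * t$std_error))
  expect_equal(t$wald, (t$estimate / t$std_error)^2)
})

test_that("degenerate designs fail loudly", {
  co <- cached_cohort()
  dup <- dplyr::mutate(co, sbp_night2 = sbp_night)
  expect_error(fit_logistic(dup, "uh", c("sbp_night", "sbp_night2")),
               "sbp_night2", class = "uhrisk_rank_error")
  sep <- dplyr::mutate(co, perfect = as.numeric(uh) + 0)
  expect_error(fit_logistic(sep, "uh", "perfect"),
               class = "uhrisk_separation_error")
  na_co <- co
  na_co$sbp_night[3] <- NA
  expect_error(fit_logistic(na_co, "uh", "sbp_night"),
               class = "uhrisk_domain_error")
  expect_error(fit_logistic(co, "uh", "not_a_column"),
               class = "uhrisk_domain_error")
})

test_that("the omnibus statistic is additive over nested model steps", {
  co <- cached_cohort()
  f1 <- fit_logistic(co, "uh", "sbp_night")
  f2 <- fit_logistic(co, "uh", c("sbp_night", "ht_drugs"))
  f3 <- fit_logistic(co, "uh", c("sbp_night", "ht_drugs", "age"))
  steps <- 2 * (f1$log_lik - f1$null_log_lik) +
    2 * (f2$log_lik - f1$log_lik) + 2 * (f3$log_lik - f2$log_lik)
  expect_equal(omnibus_lrt(f3)$statistic, steps, tolerance = 1e-8)
  expect_equal(omnibus_lrt(f3)$df, 3)
  # a strong predictor (classes separable up to noise) is detected decisively
  strong <- withr::with_seed(14, tibble::tibble(
    y = rep(c(FALSE, TRUE), each = 60),
    x = c(rnorm(60, 0), rnorm(60, 2.5))))
  expect_lt(omnibus_lrt(fit_logistic(strong, "y", "x"))$p_value, 0.001)
})

test_that("Nagelkerke R2 matches a hand likelihood computation and is scale-free", {
  df <- tibble::tibble(y = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
                       x = c(1, 2, 3, 4, 5, 6))
  fit <- fit_logistic(df, "y", "x")
  # independent oracle: Bernoulli log likelihoods evaluated directly
  p_hat <- fit$fitted
  ll <- sum(log(ifelse(df$y, p_hat, 1 - p_hat)))
  p0 <- mean(df$y)
  ll0 <- sum(log(ifelse(df$y, p0, 1 - p0)))
  r2_cs <- 1 - exp(2 * (ll0 - ll) / 6)
  expect_equal(nagelkerke_r2(fit), r2_cs / (1 - exp(2 * ll0 / 6)),
               tolerance = 1e-10)

  co <- cached_cohort()
  f_mm <- fit_logistic(co, "uh", "sbp_night")
  f_cm <- fit_logistic(dplyr::mutate(co, sbp_night = sbp_night / 10),
                       "uh", "sbp_night")
  expect_equal(nagelkerke_r2(f_mm), nagelkerke_r2(f_cm), tolerance = 1e-6)

  # R2 climbs toward 1 as separation sharpens
  r2s <- purrr::map_dbl(c(1, 2, 4), function(shift) {
    d <- withr::with_seed(8, tibble::tibble(
      y = rep(c(FALSE, TRUE), each = 50),
      x = c(rnorm(50, 0), rnorm(50, shift))))
    nagelkerke_r2(fit_logistic(d, "y", "x"))
  })
  expect_true(all(diff(r2s) > 0))
  expect_gt(r2s[3], 0.8)
})

test_that("Hosmer-Lemeshow behaves at its degenerate and miscalibrated poles", {
  y <- rep(c(TRUE, FALSE), c(40, 60))
  hl_flat <- suppressWarnings(hosmer_lemeshow(rep(0.4, 100), y, g = 10))
  expect_equal(hl_flat$statistic, 0, tolerance = 1e-10)

  # systematic miscalibration (logit shift +1) is caught at n = 2000
  hits <- purrr::map_lgl(1:30, function(s) {
    withr::with_seed(100 + s, {
      x <- rnorm(2000)
      p_true <- plogis(-0.5 + x)
      yy <- runif(2000) < p_true
      p_shift <- plogis(qlogis(p_true) + 1)
      hosmer_lemeshow(p_shift, yy, g = 10)$p_value < 0.05
    })
  })
  expect_gt(mean(hits), 0.8)
  expect_error(hosmer_lemeshow(rep(0.5, 10), rep(c(TRUE, FALSE), 5), g = 10),
               class = "uhrisk_domain_error")
})

test_that("ROC agrees with the pairwise concordance oracle and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)

  oracle_auc <- function(s, y) {
    pos <- s[y]
    neg <- s[!y]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  }
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    s <- sample(round(rnorm(n), 1)) # rounding forces ties
    y <- runif(n) < 0.5
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_true(r$ci_lower <= r$auc && r$auc <= r$ci_upper)
  }
  # independent library cross-check
  s <- withr::with_seed(2, rnorm(150))
  y <- withr::with_seed(3, runif(150) < plogis(s))
  ref <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                   direction = "<")
  expect_equal(roc_auc(s, y)$auc, as.numeric(pROC::auc(ref)),
               tolerance = 1e-10)
  # Hanley-McNeil SE magnitude at the published operating point
  strong <- roc_auc(c(rnorm(60, 0), rnorm(72, 1.9)),
                    rep(c(FALSE, TRUE), c(60, 72)))
  expect_gt(strong$se, 0.02)
  expect_lt(strong$se, 0.05)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "uhrisk_domain_error")
})

test_that("classification accuracy counts threshold agreements", {
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(classification_accuracy(as.numeric(y), y), 1)
  expect_equal(classification_accuracy(1 - as.numeric(y), y), 0)
  expect_equal(110 / 132, 0.8333, tolerance = 1e-4)
  p <- c(0.9, 0.2, 0.4, 0.1)
  expect_equal(classification_accuracy(p, y), 0.75)
  expect_error(classification_accuracy(c(0.5, 1.2), c(TRUE, FALSE)),
               class = "uhrisk_domain_error")
})

test_that("confounder screening applies the 10% odds-ratio-change rule", {
  # a strong common cause of exposure and outcome must be retained;
  # an independent covariate must not
  sim <- withr::with_seed(77, {
    n <- 2000
    z <- rbinom(n, 1, 0.4)
    x <- rnorm(n, mean = 1.5 * z)
    noise <- rnorm(n)
    y <- runif(n) < plogis(-0.5 + 0.6 * x + 1.2 * z)
    tibble::tibble(y = y, x = x, z = z, noise = noise)
  })
  scr <- screen_confounders(sim, "y", "x", c("z", "noise"))
  expect_true(scr$retained[scr$candidate == "z"])
  expect_false(scr$retained[scr$candidate == "noise"])
  expect_true(all(scr$status == "ok"))
  # the change is measured on the odds-ratio scale
  expect_equal(scr$rel_change,
               abs(scr$or_adjusted - scr$or_crude) / scr$or_crude)
  # near-identical crude/adjusted ORs (e.g. 1.044 vs 1.047) stay out
  expect_lt(abs(1.047 - 1.044) / 1.044, 0.10)
})

test_that("interaction screening is calibrated and finds real product effects", {
  # type-I behaviour under no interaction
  hits <- purrr::map_lgl(1:30, function(s) {
    d <- withr::with_seed(200 + s, tibble::tibble(
      a = rnorm(400), b = rnorm(400),
      y = runif(400) < plogis(0.5 * a + 0.5 * b)))
    screen_interactions(d, "y", c("a", "b"), list(c("a", "b")))$relevant
  })
  expect_lt(mean(hits), 0.17)
  # a strong product effect is found most of the time
  found <- purrr::map_lgl(1:20, function(s) {
    d <- withr::with_seed(300 + s, tibble::tibble(
      a = rnorm(400), b = rnorm(400),
      y = runif(400) < plogis(0.3 * a + 0.3 * b + 1.0 * a * b)))
    screen_interactions(d, "y", c("a", "b"), list(c("a", "b")))$relevant
  })
  expect_gt(mean(found), 0.8)
  empty <- screen_interactions(cached_cohort(), "uh", "sbp_night", list())
  expect_equal(nrow(empty), 0)
})
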