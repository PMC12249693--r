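test_that("dipping follows the day/night percentage definition", {
  expect_equal(dipping(120, 108), 10.0)
  expect_equal(dipping(120, 120), 0.0)
  expect_equal(dipping(100, 110), -10.0) # riser pattern
  expect_error(dipping(0, 50), class = "uhrisk_domain_error")
  # invariant under common rescaling of (day, night)
  set.seed(1)
  for (i in 1:20) {
    day <- runif(1, 80, 180)
    night <- runif(1, 60, 170)
    k <- runif(1, 0.5, 3)
    expect_equal(dipping(k * day, k * night), dipping(day, night))
  }
})

test_that("median and IQR match brute-force order statistics (type 7)", {
  # independent oracle: interpolate sorted values at h = (n - 1) p + 1
  oracle <- function(x, p) {
    s <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), tibble::tibble(median = 3, iqr = 2))
  expect_equal(median_iqr(7), tibble::tibble(median = 7, iqr = 0))
  expect_equal(median_iqr(c(2, 2, 2, 2)), tibble::tibble(median = 2, iqr = 0))
  set.seed(42)
  for (n in c(3, 6, 11, 50)) {
    x <- rnorm(n)
    got <- median_iqr(x)
    expect_equal(got$median, oracle(x, 0.5))
    expect_equal(got$iqr, oracle(x, 0.75) - oracle(x, 0.25))
  }
  expect_error(median_iqr(numeric(0)), class = "uhrisk_domain_error")
})

test_that("Mann-Whitney matches enumeration and the large-sample oracle", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$u, 0)
  expect_equal(mann_whitney(c(1, 2, 2, 3), c(1, 2, 2, 3))$p_value, 1.0)

  # exact p for a = {1,2}, b = {3,4} by hand enumeration of all 6 labelings:
  # U values are {0,1,2,2,3,4}; two of six are as extreme as U = 0
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / 6)

  # normal approximation close to exact enumeration at combined n = 10
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(5)
    b <- rnorm(5, mean = runif(1, 0, 2))
    pe <- mann_whitney(a, b, exact = TRUE)$p_value
    pn <- mann_whitney(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }

  # tie-free approximation agrees with stats::wilcox.test
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- rnorm(25, 0.4)
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mann_whitney(a, b)$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1), class = "uhrisk_domain_error")
})

test_that("2x2 testing switches correctly between Pearson and Fisher", {
  # antihypertensive-treatment table: controls 4/60 treated, cases 18/72
  ht <- matrix(c(4, 18, 56, 54), nrow = 2)
  res <- chi_squared_or_fisher(ht)
  expect_identical(res$test, "pearson")
  expect_equal(res$statistic, 7.92, tolerance = 1e-3)
  expect_equal(round(res$p_value, 3), 0.005)

  flat <- chi_squared_or_fisher(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # sparse table (miscarriages): expected counts < 5 trigger Fisher
  mis <- chi_squared_or_fisher(matrix(c(2, 3, 58, 69), nrow = 2))
  expect_identical(mis$test, "fisher")
  expect_gt(mis$p_value, 0.99)

  # proportional rows give a zero statistic
  prop <- chi_squared_or_fisher(matrix(c(10, 20, 30, 60), nrow = 2))
  expect_equal(prop$statistic, 0, tolerance = 1e-12)

  expect_error(chi_squared_or_fisher(matrix(c(0, 0, 5, 5), 2)),
               class = "uhrisk_domain_error")
})

test_that("the cohort description covers every variable with valid summaries", {
  d <- describe_cohort(cached_cohort())
  expect_true(all(d$p_value >= 0 & d$p_value <= 1, na.rm = TRUE))
  expect_true(all(c("uric_acid", "af_ratio", "sbp_dipping", "ht_drugs",
                    "essential_ht") %in% d$variable))
  cont <- d[d$kind == "continuous", ]
  expect_true(all(cont$iqr_no >= 0 & cont$iqr_yes >= 0))
  bin <- d[d$kind == "binary", ]
  expect_true(all(bin$percent_no >= 0 & bin$percent_no <= 100))
})
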