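test_that("polynomial term lists have the right size and order", {
  for (d in 1:5) {
    expect_equal(nrow(poly_spec(d)), (d + 1) * (d + 2) / 2 - 1)
  }
  expect_identical(poly_spec(2)$term, c("ua", "af", "ua2", "ua_af", "af2"))
  expect_error(poly_spec(0), class = "uhrisk_domain_error")

  expect_equal(unname(poly_expand(0, 0, 2)[1, ]), rep(0, 5))
  expect_equal(unname(poly_expand(1, 1, 2)[1, ]), rep(1, 5))
  expect_equal(poly_expand(2, 3, 2)[1, ],
               c(ua = 2, af = 3, ua2 = 4, ua_af = 6, af2 = 9))
})

test_that("the reference equation evaluates exactly on the model scale", {
  m <- index_model(reference_index_coefficients(), degree = 2)
  expect_equal(evaluate_index(m, 0, 0), 0.3855)
  expect_equal(evaluate_index(m, 1, 0), 0.3855 + 0.4989 - 0.9713)
  # determinism
  expect_identical(evaluate_index(m, 1.3, 0.7), evaluate_index(m, 1.3, 0.7))
  expect_error(evaluate_index(list(), 1, 1), class = "uhrisk_state_error")
})

test_that("degree selection prefers the simplest generalizing model", {
  flat <- tibble::tibble(degree = 1:5, train_accuracy = 0.7,
                         test_accuracy = 0.7)
  expect_equal(select_degree(flat), 1L)

  # the published cross-validation metrics point at degree 2
  printed <- tibble::tibble(degree = 1:5,
                            train_accuracy = c(0.56, 0.70, 0.72, 0.73, 0.73),
                            test_accuracy = c(0.53, 0.67, 0.67, 0.66, 0.65))
  expect_equal(select_degree(printed), 2L)

  # improving test accuracy is ignored once the train-test gap explodes
  overfit <- tibble::tibble(degree = 1:5,
                            train_accuracy = c(0.56, 0.67, 0.82, 0.89, 0.98),
                            test_accuracy = c(0.55, 0.65, 0.70, 0.74, 0.78))
  expect_equal(select_degree(overfit), 2L)
})

test_that("folds are stratified, seeded and keyed by subject id", {
  co <- cached_cohort()
  f1 <- stratified_folds(co$id, co$uh, k = 5, seed = 3)
  f2 <- stratified_folds(co$id, co$uh, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1$fold, stratified_folds(co$id, co$uh, 5, 4)$fold))
  # class balance preserved within one subject per fold
  tab <- table(f1$fold, co$uh)
  expect_lte(diff(range(tab[, "TRUE"])), 1)
  expect_lte(diff(range(tab[, "FALSE"])), 1)
  expect_lte(diff(range(table(f1$fold))), 1)
})

test_that("out-of-fold logits honour fold exclusion and survive reordering", {
  co <- cached_cohort()
  ix <- build_index(co, degree = 2, k = 5, seed = 11)

  # reordering subjects changes nothing per id
  perm <- withr::with_seed(1, sample(nrow(co)))
  ix_perm <- build_index(co[perm, ], degree = 2, k = 5, seed = 11)
  a <- dplyr::arrange(ix$oof, id)
  b <- dplyr::arrange(ix_perm$oof, id)
  expect_equal(a, b)

  # each oof logit reproduces from the stored fold model, and that model
  # refits identically from scratch on the data excluding the subject's fold
  i <- 17
  f <- ix$folds$fold[i]
  fm <- ix$fold_models[[f]]
  z <- with(fm$transform,
            list(ua = (log(co$uric_acid[i]) - center[["ua"]]) / scale[["ua"]],
                 af = (log(co$sflt1[i] / co$plgf[i]) - center[["af"]]) / scale[["af"]]))
  X <- poly_expand(z$ua, z$af, 2)
  expect_equal(unname(fm$coefficients[["intercept"]] + drop(X %*% fm$coefficients[-1])),
               ix$oof$oof_logit[i])
  train <- co[ix$folds$fold != f, ]
  expect_false(co$id[i] %in% train$id)
  zt <- log(train$uric_acid)
  za <- log(train$sflt1 / train$plgf)
  Xt <- poly_expand((zt - mean(zt)) / sd(zt), (za - mean(za)) / sd(za), 2)
  refit <- glmnet::glmnet(Xt, train$uh, family = "binomial", alpha = 0,
                          lambda = fm$lambda, standardize = FALSE)
  expect_equal(unname(fm$coefficients), as.numeric(coef(refit)),
               tolerance = 1e-8)
})

test_that("the index separates separable cohorts and tracks its equation", {
  # two well-separated biomarker clusters by outcome
  n <- 60
  sep <- withr::with_seed(5, tibble::tibble(
    id = sprintf("C%03d", 1:n),
    uric_acid = c(rnorm(n / 2, 3.2, 0.2), rnorm(n / 2, 6.5, 0.2)),
    sflt1 = c(rnorm(n / 2, 1200, 100), rnorm(n / 2, 3400, 120)),
    plgf = c(rnorm(n / 2, 300, 20), rnorm(n / 2, 110, 10)),
    uh = rep(c(FALSE, TRUE), each = n / 2)
  ))
  ix <- build_index(sep, degree = 2, k = 5, seed = 2)
  expect_gt(roc_auc(ix$oof$oof_logit, sep$uh)$auc, 0.9)

  # full-data equation ranks subjects like the out-of-fold values
  co <- cached_cohort()
  ix2 <- build_index(co, degree = 2, k = 5, seed = 2)
  eq <- evaluate_index(ix2, co$uric_acid, co$sflt1 / co$plgf)
  expect_gt(cor(eq, ix2$oof$oof_logit, method = "spearman"), 0)
})

test_that("degree sweep shows no skill on outcome-independent biomarkers", {
  co <- cached_cohort()
  null_co <- co
  null_co$uh <- withr::with_seed(13, sample(co$uh)) # break the link
  m <- cv_degree_sweep(null_co, degrees = 1:3, k = 5, seed = 5)
  # 3 * Hanley-McNeil SE at AUC 0.5 with 66/66 per class is about 0.15
  expect_true(all(abs(m$test_auc - 0.5) < 0.15))
})

test_that("the sweep reproduces the rise-then-overfit pattern on average", {
  # average fivefold test metrics over a few independent 132-subject cohorts
  ms <- purrr::map(1:4, function(s) {
    cv_degree_sweep(generate_cohort(degree2_config(132, 40 + s)),
                    seed = 50 + s)
  })
  test_acc <- colMeans(do.call(rbind, purrr::map(ms, "test_accuracy")))
  test_ll <- colMeans(do.call(rbind, purrr::map(ms, "test_logloss")))
  expect_gt(test_acc[2], test_acc[1]) # degree 2 beats degree 1
  expect_gt(test_ll[4], test_ll[2])   # degrees >= 4 overfit in log loss
  expect_gt(test_ll[5], test_ll[2])
})

test_that("out-of-fold log loss for the selected degree beats degree 1", {
  for (s in 1:3) {
    m <- cv_degree_sweep(generate_cohort(degree2_config(264, 60 + s)),
                         seed = 70 + s)
    d <- select_degree(m)
    expect_lte(m$test_logloss[m$degree == d], m$test_logloss[m$degree == 1])
  }
})

test_that("leave-one-out on a ten-subject cohort returns finite metrics", {
  m <- cv_degree_sweep(tiny_cohort(), degrees = 1:2, k = 10, seed = 1)
  expect_true(all(is.finite(unlist(m[, -1]))))
  expect_error(cv_degree_sweep(dplyr::mutate(tiny_cohort(), uh = TRUE),
                               k = 2, seed = 1),
               class = "uhrisk_domain_error")
})
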