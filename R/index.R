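#' Polynomial term specification for the two-biomarker expansion
#'
#' Enumerates the exponent pairs `(i, j)` with `0 < i + j <= degree` for a
#' bivariate polynomial in uric acid (`ua`) and the angiogenic-factor ratio
#' (`af`), in a fixed documented order: by total degree, then by decreasing
#' `ua` exponent — so degree 2 yields `ua, af, ua2, ua_af, af2`. The intercept
#' is handled separately by the fit. For degree `d` the number of terms is
#' `(d + 1)(d + 2) / 2 - 1`.
#'
#' @param degree Integer between 1 and 5.
#' @return A tibble with columns `i`, `j`, `term`.
#' @export
poly_spec <- function(degree) {
  if (!is.numeric(degree) || length(degree) != 1 || degree < 1 || degree > 5 ||
      degree != round(degree)) {
    abort("`degree` must be an integer between 1 and 5.",
          class = "uhrisk_domain_error")
  }
  grid <- tidyr::expand_grid(total = seq_len(degree), i = degree:0) |>
    dplyr::mutate(j = .data$total - .data$i) |>
    dplyr::filter(.data$j >= 0, .data$i >= 0) |>
    dplyr::arrange(.data$total, dplyr::desc(.data$i))
  term_name <- function(i, j) {
    parts <- c(
      if (i > 0) paste0("ua", if (i > 1) i else ""),
      if (j > 0) paste0("af", if (j > 1) j else "")
    )
    paste(parts, collapse = "_")
  }
  tibble::tibble(i = grid$i, j = grid$j,
                 term = purrr::map2_chr(grid$i, grid$j, term_name))
}

#' Expand biomarker pairs into polynomial features
#'
#' @param ua,af Numeric vectors (already on the model's internal scale).
#' @param spec A [poly_spec()] tibble, or an integer degree.
#' @return A numeric matrix with one column per term of `spec`, in its order.
#' @examples
#' poly_expand(c(0, 1), c(0, 1), 2)
#' @export
poly_expand <- function(ua, af, spec) {
  if (is.numeric(spec) && length(spec) == 1) spec <- poly_spec(spec)
  if (any(!is.finite(ua)) || any(!is.finite(af)) || length(ua) != length(af)) {
    abort("`ua` and `af` must be finite vectors of equal length.",
          class = "uhrisk_domain_error")
  }
  X <- mapply(function(i, j, term) ua^i * af^j, spec$i, spec$j, spec$term)
  X <- matrix(X, nrow = length(ua), dimnames = list(NULL, spec$term))
  X
}

# ---- biomarker scaling ------------------------------------------------------

# Fit the input transform on training data: optional natural log, then
# optional centering/scaling to zero mean and unit variance.
fit_transform <- function(ua, af, log_transform, standardize) {
  t_ua <- if (log_transform) log(ua) else ua
  t_af <- if (log_transform) log(af) else af
  if (standardize) {
    list(log_transform = log_transform,
         center = c(ua = mean(t_ua), af = mean(t_af)),
         scale = c(ua = sd(t_ua), af = sd(t_af)))
  } else {
    list(log_transform = log_transform,
         center = c(ua = 0, af = 0), scale = c(ua = 1, af = 1))
  }
}

apply_transform <- function(transform, ua, af) {
  if (transform$log_transform) {
    ua <- log(ua)
    af <- log(af)
  }
  list(ua = (ua - transform$center[["ua"]]) / transform$scale[["ua"]],
       af = (af - transform$center[["af"]]) / transform$scale[["af"]])
}

# Ridge-logistic (or plain ML when lambda = 0) fit of outcome on the
# polynomial expansion. Returns named coefficient vector, intercept first.
fit_poly_logit <- function(X, y, lambda) {
  if (lambda > 0) {
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = FALSE),
      # tiny training folds (e.g. leave-one-out) are a supported boundary case
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    beta <- as.numeric(coef(fit))
  } else {
    fit <- suppressWarnings(
      glm(y ~ X, family = binomial(),
          control = glm.control(epsilon = 1e-8, maxit = 100)))
    beta <- unname(coef(fit))
  }
  setNames(beta, c("intercept", colnames(X)))
}

#' Construct an index model from known coefficients
#'
#' Builds an evaluable index model directly from a coefficient vector — for
#' example the published full-data equation — without fitting. The transform
#' defaults to the identity, i.e. inputs are taken to be already on the
#' model's internal scale.
#'
#' @param coefficients Named numeric vector: `intercept` plus one entry per
#'   term of `poly_spec(degree)`.
#' @param degree Polynomial degree of the equation.
#' @param center,scale Named length-2 vectors (`ua`, `af`) for input scaling.
#' @param log_transform Whether inputs are log-transformed before scaling.
#' @return A `uaaf_index` object (unfitted variant: no out-of-fold values).
#' @export
index_model <- function(coefficients, degree = 2,
                        center = c(ua = 0, af = 0),
                        scale = c(ua = 1, af = 1),
                        log_transform = FALSE) {
  spec <- poly_spec(degree)
  need <- c("intercept", spec$term)
  if (!all(need %in% names(coefficients))) {
    abort(paste0("`coefficients` must be named: ", paste(need, collapse = ", ")),
          class = "uhrisk_domain_error")
  }
  structure(
    list(degree = degree, spec = spec,
         coefficients = coefficients[need],
         transform = list(log_transform = log_transform,
                          center = center, scale = scale),
         oof = NULL, folds = NULL, fold_models = NULL,
         k = NA_integer_, seed = NA_integer_, lambda = NA_real_),
    class = "uaaf_index"
  )
}

#' Evaluate an index model at raw biomarker values
#'
#' Applies the model's input transform (optional log, then centering/scaling
#' fitted on its training data) followed by the polynomial-logit equation.
#' The returned value is on the logit scale — the combined-variable value a
#' downstream risk model consumes.
#'
#' @param model A `uaaf_index` object.
#' @param ua Uric acid (mg/dL), positive.
#' @param af sFlt-1/PlGF ratio, positive.
#' @return Numeric vector of index values.
#' @export
evaluate_index <- function(model, ua, af) {
  if (!inherits(model, "uaaf_index")) {
    abort("`model` must be a `uaaf_index` object.", class = "uhrisk_state_error")
  }
  z <- apply_transform(model$transform, ua, af)
  X <- poly_expand(z$ua, z$af, model$spec)
  drop(model$coefficients[["intercept"]] + X %*% model$coefficients[-1])
}

#' @export
predict.uaaf_index <- function(object, newdata, ...) {
  evaluate_index(object, newdata$uric_acid, newdata$sflt1 / newdata$plgf)
}

# ---- cross-validation -------------------------------------------------------

#' Seeded stratified fold assignment keyed by subject id
#'
#' Subjects are assigned to `k` folds separately within each outcome class, in
#' the order of a deterministic hash of (subject id, seed). Fold membership
#' therefore depends only on ids, outcome and seed — not on row order — and
#' class proportions are preserved within one subject per fold.
#'
#' @param ids Character vector of unique subject ids.
#' @param y Logical outcome vector.
#' @param k Number of folds (>= 2; may equal the number of subjects).
#' @param seed Integer seed.
#' @return A tibble with columns `id` and `fold`, in the input id order.
#' @export
stratified_folds <- function(ids, y, k, seed) {
  if (anyDuplicated(ids)) {
    abort("`ids` must be unique.", class = "uhrisk_domain_error")
  }
  if (k < 2 || k > length(ids)) {
    abort("`k` must be between 2 and the number of subjects.",
          class = "uhrisk_domain_error")
  }
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present.", class = "uhrisk_domain_error")
  }
  h <- fnv1a32(paste(ids, seed, sep = ":"))
  fold <- integer(length(ids))
  offset <- 0L
  for (cls in c(FALSE, TRUE)) {
    idx <- which(y == cls)
    ord <- idx[order(h[idx], ids[idx])]
    # continue the cycle across classes so fold sizes stay within one subject
    fold[ord] <- ((offset + seq_along(ord) - 1L) %% k) + 1L
    offset <- offset + length(ord)
  }
  tibble::tibble(id = ids, fold = fold)
}

clamp_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

log_loss <- function(y, p) {
  p <- clamp_prob(p)
  -mean(ifelse(y, log(p), log(1 - p)))
}

fold_metrics <- function(y, lp) {
  p <- plogis(lp)
  tibble::tibble(
    accuracy = mean((p >= 0.5) == y),
    auc = if (length(unique(y)) == 2) auc_value(lp, y) else NA_real_,
    logloss = log_loss(y, p)
  )
}

# Run one k-fold CV pass at a given degree. Returns per-fold metrics and the
# out-of-fold linear predictors plus the per-fold models (for bookkeeping).
cv_one_degree <- function(ua, af, y, folds, degree, lambda,
                          log_transform, standardize) {
  spec <- poly_spec(degree)
  k <- max(folds)
  per_fold <- vector("list", k)
  fold_models <- vector("list", k)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    transform <- fit_transform(ua[tr], af[tr], log_transform, standardize)
    ztr <- apply_transform(transform, ua[tr], af[tr])
    Xtr <- poly_expand(ztr$ua, ztr$af, spec)
    lam <- if (is.null(lambda)) 1 / sum(tr) else lambda
    beta <- fit_poly_logit(Xtr, y[tr], lam)
    lp_tr <- drop(beta[["intercept"]] + Xtr %*% beta[-1])
    zte <- apply_transform(transform, ua[te], af[te])
    Xte <- poly_expand(zte$ua, zte$af, spec)
    lp_te <- drop(beta[["intercept"]] + Xte %*% beta[-1])
    oof[te] <- lp_te
    fold_models[[f]] <- list(coefficients = beta, transform = transform,
                             lambda = lam)
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      dplyr::rename_with(fold_metrics(y[tr], lp_tr), ~ paste0("train_", .x)),
      dplyr::rename_with(fold_metrics(y[te], lp_te), ~ paste0("test_", .x))
    )
  }
  list(per_fold = dplyr::bind_rows(per_fold), oof = oof,
       fold_models = fold_models)
}

summarize_cv <- function(per_fold, oof, y) {
  out <- dplyr::summarise(per_fold, dplyr::across(
    dplyr::starts_with(c("train_", "test_")), ~ mean(.x, na.rm = TRUE)))
  # every test fold single-class (e.g. leave-one-out): pool the out-of-fold
  # predictions so the test AUC is still defined
  if (all(is.na(per_fold$test_auc))) out$test_auc <- auc_value(oof, y)
  out
}

#' Cross-validated metrics per polynomial degree
#'
#' For each candidate degree, fits the polynomial-logit model of
#' [build_index()] under seeded stratified k-fold cross-validation and reports
#' the across-fold mean train and test accuracy (probability threshold 0.5),
#' AUC and log loss.
#'
#' @param cohort Cohort tibble with `id`, `uric_acid`, `sflt1`, `plgf` and the
#'   outcome column; both outcome classes must be present.
#' @param degrees Integer vector of degrees to sweep (subset of 1..5).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty for the internal logistic fits; `NULL`
#'   (default) uses a mild `1 / n_train`; `0` requests the unpenalized fit.
#' @param log_transform,standardize Input transform applied before the
#'   polynomial expansion; fitted on each training fold. Defaults: log then
#'   standardize.
#' @param outcome Name of the logical outcome column.
#' @return A `uaaf_cv` tibble: one row per degree with columns
#'   `train_accuracy`, `test_accuracy`, `train_auc`, `test_auc`,
#'   `train_logloss`, `test_logloss`.
#' @export
cv_degree_sweep <- function(cohort, degrees = 1:5, k = 5, seed = 1L,
                            lambda = NULL, log_transform = TRUE,
                            standardize = TRUE, outcome = "uh") {
  y <- cohort[[outcome]]
  folds <- stratified_folds(cohort$id, y, k, seed)$fold
  ua <- cohort$uric_acid
  af <- cohort$sflt1 / cohort$plgf
  res <- purrr::map_dfr(degrees, function(d) {
    cv <- cv_one_degree(ua, af, y, folds, d, lambda, log_transform, standardize)
    dplyr::bind_cols(tibble::tibble(degree = d),
                     summarize_cv(cv$per_fold, cv$oof, y))
  })
  structure(res, class = c("uaaf_cv", class(res)),
            k = k, seed = seed, lambda = lambda)
}

#' Select the polynomial degree from cross-validated metrics
#'
#' Picks the simplest degree that generalizes: among degrees whose
#' train-minus-test accuracy gap does not exceed `gap_threshold`, the lowest
#' degree whose test accuracy is within `accuracy_tol` of the best test
#' accuracy in that subset. If no degree passes the gap rule the fallback is
#' the lowest degree within `accuracy_tol` of the overall best test accuracy.
#' Ties always break toward the lower degree.
#'
#' @param metrics A [cv_degree_sweep()] result (or any tibble with `degree`,
#'   `train_accuracy`, `test_accuracy`).
#' @param accuracy_tol Tolerance band below the best test accuracy (default
#'   0.04, roughly one standard error of a fivefold mean accuracy at a cohort
#'   of ~130 subjects — a one-SE-style parsimony band).
#' @param gap_threshold Maximum tolerated train-test accuracy gap (default
#'   0.05).
#' @return The selected degree (integer).
#' @export
select_degree <- function(metrics, accuracy_tol = 0.04, gap_threshold = 0.05) {
  if (nrow(metrics) < 2) {
    abort("metrics for at least two degrees are required.",
          class = "uhrisk_domain_error")
  }
  m <- dplyr::arrange(tibble::as_tibble(metrics), .data$degree)
  gap_ok <- (m$train_accuracy - m$test_accuracy) <= gap_threshold + 1e-12
  pool <- if (any(gap_ok)) m[gap_ok, ] else m
  best <- max(pool$test_accuracy)
  as.integer(min(pool$degree[pool$test_accuracy >= best - accuracy_tol - 1e-12]))
}

#' Build the combined biomarker index
#'
#' Fits the degree-`degree` polynomial-logit model of uric acid and the
#' sFlt-1/PlGF ratio under seeded stratified k-fold cross-validation and
#' returns (a) each subject's out-of-fold logit — the linear predictor from
#' the fold model that excluded that subject, with input scaling fitted on
#' that fold's training data only — and (b) the full-data equation for
#' evaluating the index on new subjects. The out-of-fold values are the
#' leakage-free combined variable intended as a predictor in downstream risk
#' models.
#'
#' @inheritParams cv_degree_sweep
#' @param degree The polynomial degree (typically chosen by
#'   [select_degree()]).
#' @return A fitted `uaaf_index` object: full-data `coefficients` and
#'   `transform`, an `oof` tibble (`id`, `fold`, `oof_logit`), the fold
#'   assignment, and per-fold models for audit.
#' @export
build_index <- function(cohort, degree = 2, k = 5, seed = 1L, lambda = NULL,
                        log_transform = TRUE, standardize = TRUE,
                        outcome = "uh") {
  y <- cohort[[outcome]]
  folds_tbl <- stratified_folds(cohort$id, y, k, seed)
  ua <- cohort$uric_acid
  af <- cohort$sflt1 / cohort$plgf
  cv <- cv_one_degree(ua, af, y, folds_tbl$fold, degree, lambda,
                      log_transform, standardize)
  transform <- fit_transform(ua, af, log_transform, standardize)
  z <- apply_transform(transform, ua, af)
  X <- poly_expand(z$ua, z$af, poly_spec(degree))
  lam <- if (is.null(lambda)) 1 / length(y) else lambda
  beta <- fit_poly_logit(X, y, lam)
  structure(
    list(degree = degree, spec = poly_spec(degree),
         coefficients = beta, transform = transform,
         oof = tibble::tibble(id = cohort$id, fold = folds_tbl$fold,
                              oof_logit = cv$oof),
         folds = folds_tbl, fold_models = cv$fold_models,
         per_fold_metrics = cv$per_fold,
         k = k, seed = seed, lambda = lam),
    class = "uaaf_index"
  )
}

#' @export
print.uaaf_index <- function(x, ...) {
  cat("Combined biomarker index (polynomial-logit)\n")
  cat("  degree:", x$degree, "\n")
  eq <- paste(sprintf("%+.4f*%s", x$coefficients[-1],
                      names(x$coefficients)[-1]), collapse = " ")
  cat(sprintf("  index = %.4f %s\n", x$coefficients[["intercept"]], eq))
  if (!is.null(x$oof)) {
    cat("  out-of-fold logits:", nrow(x$oof), "subjects,", x$k, "folds\n")
  }
  invisible(x)
}

#' @export
tidy.uaaf_index <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.uaaf_index <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_terms = nrow(x$spec),
                 lambda = x$lambda, k = x$k,
                 n = if (is.null(x$oof)) NA_integer_ else nrow(x$oof))
}

#' Plot cross-validated degree-sweep metrics
#'
#' Train and test accuracy, AUC and log loss against polynomial degree, one
#' panel per metric — the overfitting diagnostic used to pick the degree.
#'
#' @param object A `uaaf_cv` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uaaf_cv <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"degree", names_to = c("set", "metric"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degree, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "polynomial degree", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
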