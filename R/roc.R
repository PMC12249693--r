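# ROC / AUC machinery shared by the index and risk-model modules.

# AUC as the tie-adjusted concordance probability, via the rank formula;
# numerically exact (integer arithmetic divided once).
auc_value <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  n1 <- sum(y)
  n0 <- sum(!y)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with AUC, Hanley-McNeil standard error and confidence interval
#'
#' Sweeps all score thresholds (descending) to build the ROC curve and
#' computes the area by trapezoidal integration, which equals the
#' concordance probability with ties counted one half. The standard error of
#' the AUC uses the Hanley-McNeil formula with the exponential approximations
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`; the 95% confidence interval is
#' `AUC +/- 1.96 * SE` truncated to \[0, 1\], and the p-value is a two-sided
#' normal test of AUC = 0.5.
#'
#' @param scores Numeric predictor values (higher = more likely positive).
#' @param outcomes Logical (or 0/1) outcome vector; both classes required.
#' @return A `uh_roc` object: list with `points` (tibble of `threshold`,
#'   `fpr`, `tpr`), `auc`, `se`, `ci_lower`, `ci_upper`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc
#' @export
roc_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  if (any(is.na(scores)) || any(is.na(y))) {
    abort("`scores` and `outcomes` must be complete.",
          class = "uhrisk_domain_error")
  }
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    abort("both outcome classes must be present.", class = "uhrisk_domain_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !y), numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr),
                           fpr = c(0, fp) / n0, tpr = c(0, tp) / n1)
  # trapezoid on integer counts, divided once: exact concordance with ties 1/2
  auc <- sum(diff(c(0, fp)) * (c(0, tp)[-1] + c(0, tp)[-length(tp) - 1])) /
    (2 * n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  p <- if (se == 0) 0 else 2 * pnorm(-abs(auc - 0.5) / se)
  structure(
    list(points = points, auc = auc, se = se,
         ci_lower = max(0, auc - 1.96 * se),
         ci_upper = min(1, auc + 1.96 * se),
         p_value = p, n_pos = n1, n_neg = n0),
    class = "uh_roc"
  )
}

#' @export
print.uh_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f, SE %.3f, 95%%CI %.3f-%.3f, p %s (n+ = %d, n- = %d)\n",
              x$auc, x$se, x$ci_lower, x$ci_upper,
              format.pval(x$p_value, eps = 1e-3), x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.uh_roc <- function(x, ...) x$points

#' @export
glance.uh_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, p_value = x$p_value,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve
#'
#' @param object A `uh_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uh_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      subtitle = sprintf("AUC %.3f (SE %.3f, 95%%CI %.3f-%.3f)",
                         object$auc, object$se, object$ci_lower, object$ci_upper)
    ) +
    ggplot2::theme_minimal()
}

#' Classification accuracy at a probability threshold
#'
#' @param probabilities Fitted probabilities in \[0, 1\].
#' @param outcomes Logical (or 0/1) outcomes.
#' @param threshold Decision threshold; a subject is classified positive when
#'   the probability is at least the threshold. Default 0.5.
#' @return The proportion of correct classifications.
#' @export
classification_accuracy <- function(probabilities, outcomes, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("`probabilities` must lie in [0, 1].", class = "uhrisk_domain_error")
  }
  mean((probabilities >= threshold) == as.logical(outcomes))
}
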