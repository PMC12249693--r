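#' Beta posterior for a classifier's accuracy
#'
#' Conjugate Beta-Binomial update from a uniform Beta(1, 1) prior: with `k`
#' correct predictions out of `n`, the posterior is `Beta(1 + k, 1 + n - k)`.
#' When only the reported accuracy is available, `k` is recovered as
#' `round(accuracy * n)` (half away from zero).
#'
#' @param accuracy Observed accuracy in \[0, 1\].
#' @param n Total number of predictions (>= 1).
#' @return A `beta_posterior` object with fields `alpha`, `beta`, `n`, `k`.
#' @examples
#' posterior_from_accuracy(0.83, 132) # Beta(111, 23)
#' @export
posterior_from_accuracy <- function(accuracy, n) {
  if (!is.numeric(accuracy) || length(accuracy) != 1 ||
      accuracy < 0 || accuracy > 1) {
    abort("`accuracy` must lie in [0, 1].", class = "uhrisk_domain_error")
  }
  check_number(n, "n", lower = 1)
  k <- round_half_up(accuracy * n)
  structure(list(alpha = 1 + k, beta = 1 + n - k, n = as.integer(n),
                 k = as.integer(k)),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) posterior (k = %d of n = %d, Beta(1,1) prior); mean %.4f\n",
              x$alpha, x$beta, x$k, x$n, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Equal-tailed credible interval of a Beta posterior
#'
#' @param posterior A `beta_posterior` object.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return A tibble with `lower` and `upper` Beta quantiles.
#' @export
credible_interval <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "beta_posterior"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must lie strictly inside (0, 1).",
          class = "uhrisk_domain_error")
  }
  a <- (1 - level) / 2
  tibble::tibble(lower = qbeta(a, posterior$alpha, posterior$beta),
                 upper = qbeta(1 - a, posterior$alpha, posterior$beta))
}

# Exact P(theta1 > theta0) for independent Beta posteriors, by quadrature of
# integral F0(t) f1(t) dt. Used for the k +/- 1 sensitivity report; tests use
# their own independent quadrature.
prob_superior_exact <- function(a1, b1, a0, b0) {
  stats::integrate(function(t) pbeta(t, a0, b0) * stats::dbeta(t, a1, b1),
                   0, 1, rel.tol = 1e-10)$value
}

#' Bayesian comparison of two classifiers' accuracies
#'
#' Draws `n_draws` Monte-Carlo samples from each accuracy posterior and
#' estimates the probability that model 1 outperforms model 0,
#' `P(theta1 > theta0)`. Accuracy credible intervals use exact Beta
#' quantiles; the interval for the accuracy difference uses the empirical
#' 2.5/97.5 percentiles of the sampled differences. Because the reported
#' accuracies may hide the exact correct count, the sensitivity of the
#' superiority probability to shifting either count by one is reported
#' alongside (computed by quadrature, not sampling).
#'
#' @param posterior_1 `beta_posterior` for the model of interest.
#' @param posterior_0 `beta_posterior` for the baseline model.
#' @param n_draws Number of Monte-Carlo draws per posterior (default 100000;
#'   fewer than 1000 triggers a warning).
#' @param seed Integer seed for the draws.
#' @param level Credibility level (default 0.95).
#' @return A `uh_beta_comparison` object: the two posteriors, `p_superior`,
#'   `ci_1`, `ci_0` (exact Beta intervals), `ci_diff` (Monte-Carlo interval
#'   for `theta1 - theta0`), `diff_mean`, `p_superior_sensitivity` (range
#'   over the four k +/- 1 variants), `n_draws`, `seed`.
#' @examples
#' compare_accuracy(posterior_from_accuracy(0.83, 132),
#'                  posterior_from_accuracy(0.69, 132), seed = 1)
#' @export
compare_accuracy <- function(posterior_1, posterior_0, n_draws = 100000,
                             seed = 1L, level = 0.95) {
  stopifnot(inherits(posterior_1, "beta_posterior"),
            inherits(posterior_0, "beta_posterior"))
  check_number(n_draws, "n_draws", lower = 1)
  if (n_draws < 1000) {
    warn("fewer than 1000 draws: the superiority estimate will be unstable.")
  }
  draws <- withr::with_seed(seed, {
    t1 <- rbeta(n_draws, posterior_1$alpha, posterior_1$beta)
    t0 <- rbeta(n_draws, posterior_0$alpha, posterior_0$beta)
    list(t1 = t1, t0 = t0)
  })
  d <- draws$t1 - draws$t0
  a <- (1 - level) / 2
  sens <- vapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), function(s) {
    prob_superior_exact(posterior_1$alpha + s[1], posterior_1$beta - s[1],
                        posterior_0$alpha + s[2], posterior_0$beta - s[2])
  }, numeric(1))
  structure(
    list(posterior_1 = posterior_1, posterior_0 = posterior_0,
         p_superior = mean(d > 0),
         ci_1 = credible_interval(posterior_1, level),
         ci_0 = credible_interval(posterior_0, level),
         ci_diff = tibble::tibble(lower = unname(quantile(d, a, type = 7)),
                                  upper = unname(quantile(d, 1 - a, type = 7))),
         diff_mean = mean(d),
         p_superior_sensitivity = range(sens),
         n_draws = as.integer(n_draws), seed = as.integer(seed),
         level = level),
    class = "uh_beta_comparison"
  )
}

#' @export
print.uh_beta_comparison <- function(x, ...) {
  cat(sprintf("P(theta1 > theta0) = %.3f  [k +/- 1 sensitivity: %.3f-%.3f]\n",
              x$p_superior, x$p_superior_sensitivity[1],
              x$p_superior_sensitivity[2]))
  cat(sprintf("model 1: Beta(%g, %g), %g%% CI [%.3f, %.3f]\n",
              x$posterior_1$alpha, x$posterior_1$beta, 100 * x$level,
              x$ci_1$lower, x$ci_1$upper))
  cat(sprintf("model 0: Beta(%g, %g), %g%% CI [%.3f, %.3f]\n",
              x$posterior_0$alpha, x$posterior_0$beta, 100 * x$level,
              x$ci_0$lower, x$ci_0$upper))
  cat(sprintf("difference: %g%% CI [%.3f, %.3f]\n", 100 * x$level,
              x$ci_diff$lower, x$ci_diff$upper))
  invisible(x)
}

#' @export
tidy.uh_beta_comparison <- function(x, ...) {
  tibble::tibble(
    model = c("model_1", "model_0", "difference"),
    alpha = c(x$posterior_1$alpha, x$posterior_0$alpha, NA),
    beta = c(x$posterior_1$beta, x$posterior_0$beta, NA),
    mean = c(x$posterior_1$alpha / (x$posterior_1$alpha + x$posterior_1$beta),
             x$posterior_0$alpha / (x$posterior_0$alpha + x$posterior_0$beta),
             x$diff_mean),
    ci_lower = c(x$ci_1$lower, x$ci_0$lower, x$ci_diff$lower),
    ci_upper = c(x$ci_1$upper, x$ci_0$upper, x$ci_diff$upper)
  )
}

#' @export
glance.uh_beta_comparison <- function(x, ...) {
  tibble::tibble(p_superior = x$p_superior,
                 p_superior_low = x$p_superior_sensitivity[1],
                 p_superior_high = x$p_superior_sensitivity[2],
                 diff_mean = x$diff_mean,
                 diff_ci_lower = x$ci_diff$lower,
                 diff_ci_upper = x$ci_diff$upper,
                 n_draws = x$n_draws, seed = x$seed)
}

#' Plot the posterior densities of a Bayesian accuracy comparison
#'
#' @param object A `uh_beta_comparison` object.
#' @param ... Unused.
#' @return A ggplot object with both Beta posterior densities.
#' @export
autoplot.uh_beta_comparison <- function(object, ...) {
  grid <- seq(0.3, 1, length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(model = "model 1", theta = grid,
                   density = stats::dbeta(grid, object$posterior_1$alpha,
                                          object$posterior_1$beta)),
    tibble::tibble(model = "model 0", theta = grid,
                   density = stats::dbeta(grid, object$posterior_0$alpha,
                                          object$posterior_0$beta))
  )
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$theta, y = .data$density,
                                     fill = .data$model)) +
    ggplot2::geom_area(alpha = 0.4, position = "identity") +
    ggplot2::labs(
      x = "accuracy", y = "posterior density", fill = NULL,
      subtitle = sprintf("P(theta1 > theta0) = %.3f", object$p_superior)
    ) +
    ggplot2::theme_minimal()
}
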