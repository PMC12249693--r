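default_model_roster <- function() {
  list(
    list(name = "office_sbp", bp_index = "office_sbp", with_index = FALSE),
    list(name = "office_sbp_uaaf", bp_index = "office_sbp", with_index = TRUE),
    list(name = "nsbp", bp_index = "sbp_night", with_index = FALSE),
    list(name = "nsbp_uaaf", bp_index = "sbp_night", with_index = TRUE),
    list(name = "office_dbp", bp_index = "office_dbp", with_index = FALSE),
    list(name = "office_dbp_uaaf", bp_index = "office_dbp", with_index = TRUE),
    list(name = "ndbp", bp_index = "dbp_night", with_index = FALSE),
    list(name = "ndbp_uaaf", bp_index = "dbp_night", with_index = TRUE)
  )
}

#' Configure an end-to-end analysis run
#'
#' Assembles the configuration consumed by [run_uh_pipeline()]: the cohort
#' source, index settings, the roster of risk models (one blood-pressure
#' index each, with or without the combined biomarker index, sharing a pool
#' of candidate confounders), and the Bayesian accuracy comparisons. Every
#' random stage derives its own sub-seed from `seed`.
#'
#' The default roster is the office/nighttime, systolic/diastolic grid with
#' and without the biomarker index (8 models); the default comparisons pit
#' each nighttime-plus-index model against its office baseline.
#'
#' @param seed Master integer seed.
#' @param cohort Either `list(synthetic = list(...))` with arguments for
#'   [cohort_config()] (the default, n = 132), or `list(csv = "path")` to
#'   load a cohort file.
#' @param index List of [cv_degree_sweep()]/[build_index()] settings:
#'   `degrees`, `k`, `lambda`, `log_transform`, `standardize`.
#' @param models Model roster: a list of `list(name, bp_index, with_index)`.
#' @param candidates Candidate confounder pool screened for every model.
#' @param comparisons List of `c(model_of_interest, baseline_model)` name
#'   pairs.
#' @return A `uh_pipeline_config` list.
#' @export
uh_pipeline_config <- function(seed = 1L,
                               cohort = list(synthetic = list()),
                               index = list(),
                               models = default_model_roster(),
                               candidates = c("age", "bmi", "ht_drugs",
                                              "essential_ht", "former_smoker"),
                               comparisons = list(c("nsbp_uaaf", "office_sbp"),
                                                  c("ndbp_uaaf", "office_dbp"))) {
  check_number(seed, "seed")
  index <- modifyList(list(degrees = 1:5, k = 5, lambda = NULL,
                           log_transform = TRUE, standardize = TRUE), index)
  structure(list(seed = as.integer(seed), cohort = cohort, index = index,
                 models = models, candidates = candidates,
                 comparisons = comparisons),
            class = "uh_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [uh_pipeline_config()].
#' @return A `uh_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(uh_pipeline_config, raw)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

table3_style <- function(fit) {
  tab <- tidy(fit)
  tibble::tibble(
    "Variable" = sub("\\(Intercept\\)", "Constant", tab$term),
    "B" = tab$estimate, "SE" = tab$std_error, "Wald" = tab$wald,
    "p-Value" = tab$p_value, "Exp(B)" = tab$odds_ratio,
    "95%CI Lower" = tab$ci_lower, "95%CI Upper" = tab$ci_upper
  )
}

#' Run the full analysis pipeline
#'
#' Executes generate/load -> describe -> build index -> fit risk models ->
#' compare accuracies, writing a report bundle to `out_dir`:
#' `cohort.csv`, `descriptives.csv`, `degree_metrics.csv`,
#' `index_model.json`, one `model_<name>.csv` (coefficient table) and
#' `roc_<name>.csv` (ROC points) per roster entry, one
#' `comparison_<a>_vs_<b>.json` per configured pair, and `manifest.json`
#' recording seeds, stage row counts and the selected degree. Identical
#' configurations produce byte-identical bundles. A failure in any stage
#' aborts with the stage name; the manifest then records the failed stage so
#' partial output is recognizable.
#'
#' @param config A [uh_pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory; created if needed.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the cohort, the fitted index, the model
#'   fits, accuracy table and comparison objects.
#' @export
run_uh_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "uh_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message(sprintf(...))
  current_stage <- "setup"
  stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      write_json_report(list(status = "failed", stage = name,
                             error = conditionMessage(e)),
                        file.path(out_dir, "manifest.json"))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "uhrisk_pipeline_error", parent = e)
    })
  }
  seeds <- list(cohort = config$seed + 11L, index = config$seed + 23L,
                compare = config$seed + 37L)

  cohort <- stage("cohort", {
    if (!is.null(config$cohort$csv)) {
      read_cohort(config$cohort$csv)
    } else {
      args <- config$cohort$synthetic %||% list()
      if (is.null(args$seed)) args$seed <- seeds$cohort
      generate_cohort(do.call(cohort_config, args))
    }
  })
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  note("cohort: %d subjects, %d events", nrow(cohort), sum(cohort$uh))

  desc <- stage("describe", describe_cohort(cohort))
  readr::write_csv(desc, file.path(out_dir, "descriptives.csv"))
  note("descriptives: %d variables compared", nrow(desc))

  ix <- config$index
  metrics <- stage("index", cv_degree_sweep(
    cohort, degrees = ix$degrees, k = ix$k, seed = seeds$index,
    lambda = ix$lambda, log_transform = ix$log_transform,
    standardize = ix$standardize))
  readr::write_csv(tibble::as_tibble(metrics),
                   file.path(out_dir, "degree_metrics.csv"))
  degree <- select_degree(metrics)
  index <- stage("index", build_index(
    cohort, degree = degree, k = ix$k, seed = seeds$index, lambda = ix$lambda,
    log_transform = ix$log_transform, standardize = ix$standardize))
  write_json_report(
    list(degree = index$degree,
         coefficients = as.list(index$coefficients),
         transform = list(log_transform = index$transform$log_transform,
                          center = as.list(index$transform$center),
                          scale = as.list(index$transform$scale)),
         lambda = index$lambda, k = index$k, seed = index$seed),
    file.path(out_dir, "index_model.json"))
  cohort <- dplyr::left_join(cohort, index$oof[, c("id", "oof_logit")],
                             by = "id") |>
    dplyr::rename(uaaf_index = "oof_logit")
  note("index: selected degree %d", degree)

  fits <- stage("fit", {
    purrr::map(config$models, function(m) {
      need <- c(m$bp_index, config$candidates)
      missing_cols <- setdiff(need, names(cohort))
      if (length(missing_cols) > 0) {
        abort(sprintf("model '%s' needs missing column(s): %s", m$name,
                      paste(missing_cols, collapse = ", ")),
              class = "uhrisk_domain_error")
      }
      base_cov <- if (isTRUE(m$with_index)) "uaaf_index" else character()
      screen <- screen_confounders(cohort, "uh", m$bp_index,
                                   setdiff(config$candidates, m$bp_index),
                                   covariates = base_cov)
      retained <- screen$candidate[which(screen$retained)]
      fit <- fit_logistic(cohort, "uh", c(m$bp_index, base_cov, retained))
      list(name = m$name, fit = fit, screen = screen)
    })
  })
  accuracy_tbl <- purrr::map_dfr(fits, function(f) {
    g <- glance(f$fit)
    tibble::tibble(model = f$name, n = g$n, accuracy = g$accuracy,
                   n_correct = round_half_up(g$accuracy * g$n),
                   nagelkerke_r2 = g$nagelkerke_r2,
                   auc = roc_auc(f$fit$fitted, f$fit$y)$auc)
  })
  for (f in fits) {
    readr::write_csv(table3_style(f$fit),
                     file.path(out_dir, paste0("model_", f$name, ".csv")))
    readr::write_csv(tidy(roc_auc(f$fit$fitted, f$fit$y)),
                     file.path(out_dir, paste0("roc_", f$name, ".csv")))
  }
  readr::write_csv(accuracy_tbl, file.path(out_dir, "model_accuracy.csv"))
  note("fit: %d models", length(fits))

  comparisons <- stage("compare", {
    purrr::imap(config$comparisons, function(pair, i) {
      row1 <- accuracy_tbl[accuracy_tbl$model == pair[[1]], ]
      row0 <- accuracy_tbl[accuracy_tbl$model == pair[[2]], ]
      if (nrow(row1) != 1 || nrow(row0) != 1) {
        abort(sprintf("comparison names unknown model: %s vs %s",
                      pair[[1]], pair[[2]]), class = "uhrisk_domain_error")
      }
      cmp <- compare_accuracy(posterior_from_accuracy(row1$accuracy, row1$n),
                              posterior_from_accuracy(row0$accuracy, row0$n),
                              seed = seeds$compare + i)
      g <- glance(cmp)
      write_json_report(
        list(model_1 = pair[[1]], model_0 = pair[[2]],
             accuracy_1 = row1$accuracy, accuracy_0 = row0$accuracy,
             p_superior = g$p_superior,
             ci_1 = as.list(cmp$ci_1), ci_0 = as.list(cmp$ci_0),
             ci_diff = as.list(cmp$ci_diff),
             n_draws = cmp$n_draws, seed = cmp$seed),
        file.path(out_dir, sprintf("comparison_%s_vs_%s.json",
                                   pair[[1]], pair[[2]])))
      cmp
    })
  })

  write_json_report(
    list(status = "ok",
         package_version = as.character(utils::packageVersion("uhrisk")),
         master_seed = config$seed, stage_seeds = seeds,
         n_subjects = nrow(cohort), n_events = sum(cohort$uh),
         selected_degree = degree,
         models = accuracy_tbl$model, accuracies = accuracy_tbl$accuracy),
    file.path(out_dir, "manifest.json"))
  note("done: bundle written to %s", out_dir)
  invisible(list(cohort = cohort, index = index, fits = fits,
                 accuracy = accuracy_tbl, comparisons = comparisons))
}
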