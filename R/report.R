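# Report assembly: a comparative frequentist/Bayesian summary table,
# plot-ready forest and trajectory CSVs, and a machine-readable JSON of
# everything, with the run configuration echoed for provenance. Human
# tables round to 3 decimals (4 for p-values); the JSON carries full
# precision. The engine is quadrature-based and seed-free, so identical
# inputs give byte-identical reports.

round_df <- function(df, digits = 3, p_cols = character()) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- round(df[[nm]], if (nm %in% p_cols) 4 else digits)
    }
  }
  df
}

# Comparative summary rows (frequentist RE + Bayesian model-averaged).
comparison_table <- function(freq, bayes) {
  data.frame(
    method = c("frequentist_random_effects", "bayesian_model_averaged"),
    log_or = c(freq$mu_hat, bayes$mu_mean),
    interval_low = c(freq$ci_low, bayes$cri_low),
    interval_high = c(freq$ci_high, bayes$cri_high),
    or = c(freq$or, bayes$or),
    or_low = c(freq$or_ci[1], bayes$or_cri[1]),
    or_high = c(freq$or_ci[2], bayes$or_cri[2]),
    tau2 = c(freq$tau2, NA_real_),
    I2 = c(freq$I2, NA_real_),
    p = c(freq$p, NA_real_),
    bf10 = c(NA_real_, bayes$bf10),
    bf_rf = c(NA_real_, bayes$bf_rf))
}

# Per-study frequentist forest rows plus FE/RE summary rows.
forest_freq_data <- function(dataset, freq_fe, freq_re) {
  s <- dataset$studies
  rbind(
    data.frame(row = "study", label = s$label, estimate = s$y,
               low = s$y - 1.96 * s$se, high = s$y + 1.96 * s$se),
    data.frame(row = "summary", label = "fixed_effect",
               estimate = freq_fe$mu_hat, low = freq_fe$ci_low,
               high = freq_fe$ci_high),
    data.frame(row = "summary", label = "random_effects",
               estimate = freq_re$mu_hat, low = freq_re$ci_low,
               high = freq_re$ci_high))
}

# Bayesian forest rows: observed effects, shrinkage estimates, and the
# component / averaged summary rows plus the posterior null-model weight.
forest_bayes_data <- function(dataset, bayes) {
  s <- dataset$studies
  shr <- bayes$shrinkage
  if (is.null(shr)) shr <- shrinkage_estimates(dataset, bayes$prior)
  comp <- bayes$posterior$components
  p_null <- sum(bayes$post_model_probs[c("fe0", "re0")])
  rbind(
    data.frame(row = "observed", label = s$label, estimate = s$y,
               low = s$y - 1.96 * s$se, high = s$y + 1.96 * s$se),
    data.frame(row = "estimated", label = shr$label,
               estimate = shr$theta_mean, low = shr$cri_low,
               high = shr$cri_high),
    data.frame(row = "summary", label = "fixed_effect",
               estimate = comp$fe1$mean, low = comp$fe1$cri_low,
               high = comp$fe1$cri_high),
    data.frame(row = "summary", label = "random_effects",
               estimate = comp$re1$mean, low = comp$re1$cri_low,
               high = comp$re1$cri_high),
    data.frame(row = "summary", label = "model_averaged",
               estimate = bayes$mu_mean, low = bayes$cri_low,
               high = bayes$cri_high),
    data.frame(row = "weight", label = "posterior_prob_null",
               estimate = p_null, low = NA_real_, high = NA_real_))
}

#' Run the full comparative analysis and write a report bundle
#'
#' Executes the requested engines on one dataset and writes, under
#' `out_dir`: `table1.csv` (the side-by-side frequentist/Bayesian summary),
#' `forest_freq.csv` and `forest_bayes.csv` (plot-ready forest data),
#' `cumulative.csv` and `bf_trajectory.csv` when the sequential track is
#' requested, and `report.json` holding every numeric result at full
#' precision together with the input studies and the run configuration.
#'
#' @param dataset A [meta_dataset()].
#' @param methods Subset of `c("frequentist", "bayes", "sequential")`.
#' @param tau2_method Passed to [meta_random()].
#' @param prior A [prior_spec()].
#' @param control A [quad_control()].
#' @param order_by Sequential ordering, `"year"` or `"input"`.
#' @param out_dir Output directory (created if absent); `NULL` computes
#'   everything but writes nothing.
#' @return Invisibly, the report list.
#' @export
meta_report <- function(dataset,
                        methods = c("frequentist", "bayes", "sequential"),
                        tau2_method = "REML", prior = prior_spec(),
                        control = quad_control(), order_by = "year",
                        out_dir = NULL) {
  assert_dataset(dataset)
  methods <- match.arg(methods, several.ok = TRUE)
  config <- list(methods = methods, tau2_method = tau2_method,
                 order_by = order_by,
                 prior = unclass(prior), control = unclass(control))
  report <- list(config = config,
                 input = list(outcome_label = dataset$outcome_label,
                              studies = dataset$studies))
  freq_fe <- freq_re <- bayes <- seq_res <- NULL
  if ("frequentist" %in% methods || "bayes" %in% methods) {
    freq_fe <- meta_fixed(dataset)
    freq_re <- if (n_studies(dataset) >= 2) {
      meta_random(dataset, tau2_method = tau2_method)
    } else {
      suppressWarnings(meta_random(dataset, tau2_method = tau2_method))
    }
    report$frequentist <- list(
      fixed = unclass(freq_fe), random = unclass(freq_re),
      pseudo_lr = if (freq_re$p > 0 && freq_re$p < 1) pseudo_lr(freq_re$p)
                  else NA_real_)
  }
  if ("bayes" %in% methods) {
    bayes <- meta_bayes(dataset, prior = prior, control = control)
    report$bayes <- list(
      bf10 = bayes$bf10, bf_rf = bayes$bf_rf,
      post_model_probs = as.list(bayes$post_model_probs),
      logml = as.list(bayes$marginals$logml),
      mu_mean = bayes$mu_mean, mu_median = bayes$mu_median,
      cri_low = bayes$cri_low, cri_high = bayes$cri_high,
      or = bayes$or, or_cri = bayes$or_cri,
      shrinkage = bayes$shrinkage,
      interpretation = interpret_bf(bayes$bf10)$text)
  }
  if ("sequential" %in% methods) {
    seq_res <- meta_sequential(dataset, order_by = order_by, prior = prior,
                               control = control, tau2_method = tau2_method)
    report$sequential <- list(order = seq_res$order,
                              bf_trajectory = seq_res$bf_trajectory,
                              cumulative = seq_res$cumulative)
  }
  if (!is.null(freq_re) && !is.null(bayes)) {
    report$comparison <- comparison_table(freq_re, bayes)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$comparison)) {
      write.csv(round_df(report$comparison, p_cols = "p"),
                file.path(out_dir, "table1.csv"), row.names = FALSE)
    }
    if (!is.null(freq_fe)) {
      write.csv(round_df(forest_freq_data(dataset, freq_fe, freq_re)),
                file.path(out_dir, "forest_freq.csv"), row.names = FALSE)
    }
    if (!is.null(bayes)) {
      write.csv(round_df(forest_bayes_data(dataset, bayes)),
                file.path(out_dir, "forest_bayes.csv"), row.names = FALSE)
    }
    if (!is.null(seq_res)) {
      write.csv(round_df(seq_res$cumulative),
                file.path(out_dir, "cumulative.csv"), row.names = FALSE)
      write.csv(round_df(data.frame(k = seq_along(seq_res$bf_trajectory),
                                    bf10 = seq_res$bf_trajectory)),
                file.path(out_dir, "bf_trajectory.csv"), row.names = FALSE)
    }
    jsonlite::write_json(strip_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(report)
}

# Drop non-serializable closures/classes before JSON export.
strip_report <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_report)
    attributes(x)[setdiff(names(attributes(x)), "names")] <- NULL
  }
  x
}

#' Re-validate a written report
#'
#' Reads `report.json`, re-runs the engines on the embedded input with the
#' embedded configuration, and checks that every scalar numeric field is
#' reproduced within `tol`. Returns the maximum absolute discrepancy
#' (invisibly) and errors if it exceeds `tol`.
#'
#' @param path Path to a `report.json` written by [meta_report()].
#' @param tol Numeric tolerance.
#' @export
revalidate_report <- function(path, tol = 1e-8) {
  old <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s <- old$input$studies
  dataset <- meta_dataset(label = s$label, y = s$y, se = s$se,
                          year = if (all(is.na(s$year))) NULL else s$year,
                          outcome_label = old$input$outcome_label)
  prior <- do.call(prior_spec, old$config$prior[
    c("cauchy_location", "cauchy_scale", "tau_shape", "tau_scale",
      "model_prior")])
  control <- do.call(quad_control, old$config$control)
  new <- meta_report(dataset, methods = old$config$methods,
                     tau2_method = old$config$tau2_method,
                     prior = prior, control = control,
                     order_by = old$config$order_by, out_dir = NULL)
  max_diff <- 0
  compare <- function(a, b) {
    if (is.numeric(a) && is.numeric(b) && length(a) == length(b)) {
      d <- abs(a - b)
      d <- d[is.finite(d)]
      if (length(d)) max_diff <<- max(max_diff, d)
    } else if (is.list(a) && is.list(b)) {
      for (nm in intersect(names(a), names(b))) compare(a[[nm]], b[[nm]])
    }
  }
  for (section in c("frequentist", "bayes")) {
    compare(old[[section]], new[[section]])
  }
  if (!is.null(old$sequential)) {
    compare(old$sequential$bf_trajectory, new$sequential$bf_trajectory)
  }
  if (max_diff > tol) {
    stop("report failed re-validation: max discrepancy ", max_diff,
         call. = FALSE)
  }
  invisible(max_diff)
}

#' Generate a simulation fixture and experiment summary on disk
#'
#' Thin orchestration over [simulate_trials()] and
#' [recovery_experiment()]: writes the generated studies as a counts or
#' effects CSV (the same schemas [read_studies()] accepts) plus the
#' experiment summary as CSV and JSON.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param replicates Replicates for the recovery experiment; 0 skips it.
#' @param estimators Passed to [recovery_experiment()].
#' @return Invisibly, a list with the dataset and (optionally) the summary.
#' @export
run_simulation <- function(config, out_dir, replicates = 0,
                           estimators = c("FE", "RE-DL", "RE-REML", "BMA")) {
  dataset <- simulate_trials(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- if (config$mode == "binomial-trials") "counts" else "effects"
  write_studies(dataset, file.path(out_dir, "studies.csv"), schema = schema)
  out <- list(dataset = dataset)
  if (replicates > 0) {
    summary <- recovery_experiment(config, replicates, estimators)
    write.csv(summary, file.path(out_dir, "experiment_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir,
                                            "experiment_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$summary <- summary
  }
  invisible(out)
}
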