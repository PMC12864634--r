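# Study-level data model: 2x2 tables -> log odds ratios, dataset container,
# CSV/JSON ingest and export.

#' Log odds ratio and its standard error from a 2x2 table
#'
#' Computes the Woolf log odds ratio `log(ad/bc)` for a two-arm trial with a
#' binary outcome, where `a = events_treat`, `b = n_treat - events_treat`,
#' `c = events_ctrl`, `d = n_ctrl - events_ctrl`, together with the standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' When any of the four cells is zero the log odds ratio is undefined; with
#' `correction = TRUE` the Haldane-Anscombe correction adds 0.5 to *all four*
#' cells of the affected table before computing both the estimate and its
#' standard error. The correction is applied only to tables that contain a
#' zero. Tables with zero events in both arms (or events in every subject of
#' both arms) carry no information about the odds ratio and are rejected.
#'
#' @param events_treat,n_treat Events and arm size in the treatment arm.
#' @param events_ctrl,n_ctrl Events and arm size in the control arm.
#' @param correction Apply the Haldane-Anscombe 0.5 correction to tables
#'   containing a zero cell? If `FALSE`, such tables raise an error.
#' @return A data frame with columns `y` (log odds ratio) and `se`. Inputs
#'   are vectorized over studies.
#' @examples
#' log_odds_ratio(5, 20, 10, 20)   # OR = 1/3
#' log_odds_ratio(0, 20, 5, 20)    # corrected cells (0.5, 20.5, 5.5, 15.5)
#' @export
log_odds_ratio <- function(events_treat, n_treat, events_ctrl, n_ctrl,
                           correction = TRUE) {
  a <- as.numeric(events_treat); c <- as.numeric(events_ctrl)
  nt <- as.numeric(n_treat); nc <- as.numeric(n_ctrl)
  if (any(!is.finite(c(a, c, nt, nc)))) {
    stop("counts must be finite numbers", call. = FALSE)
  }
  if (any(nt < 1) || any(nc < 1)) {
    stop("arm sizes must be >= 1", call. = FALSE)
  }
  if (any(a < 0) || any(c < 0) || any(a > nt) || any(c > nc)) {
    stop("events must satisfy 0 <= events <= n in each arm", call. = FALSE)
  }
  if (any(a != round(a) | c != round(c) | nt != round(nt) | nc != round(nc))) {
    stop("counts must be integers", call. = FALSE)
  }
  b <- nt - a
  d <- nc - c
  degenerate <- (a == 0 & c == 0) | (b == 0 & d == 0)
  if (any(degenerate)) {
    stop(errorCondition(
      paste0("table(s) ", paste(which(degenerate), collapse = ", "),
             " have no events (or no non-events) in either arm; ",
             "the odds ratio is undefined"),
      class = c("metabf_degenerate_table_error", "error", "condition")))
  }
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  if (any(zero) && !correction) {
    stop(errorCondition(
      paste0("zero cell in table(s) ", paste(which(zero), collapse = ", "),
             " and continuity correction is disabled"),
      class = c("metabf_zero_cell_error", "error", "condition")))
  }
  k <- ifelse(zero, 0.5, 0)
  a <- a + k; b <- b + k; c <- c + k; d <- d + k
  data.frame(y = log(a * d / (b * c)),
             se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

#' Standard error of a log odds ratio from a published 95% confidence interval
#'
#' Recovers the standard error on the log odds ratio scale from the bounds of
#' a published 95% interval, `se = (upper - lower) / (2 * 1.96)`. This is the
#' usual route when extracting study-level effects from a published
#' meta-analysis that reports odds ratios with confidence intervals. The
#' normal quantile is fixed at 1.96.
#'
#' @param ci_low,ci_high Interval bounds on the *log* odds ratio scale.
#' @return Standard error(s), one per interval.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(!is.finite(ci_low)) || any(!is.finite(ci_high))) {
    stop("interval bounds must be finite", call. = FALSE)
  }
  if (any(ci_high <= ci_low)) {
    stop("ci_high must exceed ci_low", call. = FALSE)
  }
  (ci_high - ci_low) / (2 * 1.96)
}

#' Back-transform log odds ratios to the odds ratio scale
#'
#' @param y Log odds ratio estimate(s).
#' @param interval Optional length-2 vector of interval bounds on the log
#'   odds ratio scale; exponentiated alongside the estimate.
#' @return If `interval` is `NULL`, `exp(y)`; otherwise a list with elements
#'   `or` and `interval`.
#' @export
back_transform <- function(y, interval = NULL) {
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (is.null(interval)) return(exp(y))
  if (length(interval) != 2L || any(!is.finite(interval))) {
    stop("interval must be two finite bounds", call. = FALSE)
  }
  list(or = exp(y), interval = exp(sort(interval)))
}

#' Assemble a validated meta-analysis dataset
#'
#' Builds the dataset object consumed by every analysis function in the
#' package from per-study effect sizes, 2x2 counts, or both. When counts are
#' supplied without effects, `y` and `se` are computed via
#' [log_odds_ratio()]; when both are supplied, the stored effects must agree
#' with the counts to within 1e-9 or the input is rejected.
#'
#' Studies keep their input order; ordering by publication year (ties broken
#' by input order) happens downstream in [meta_sequential()].
#'
#' @param label Unique study labels.
#' @param y,se Log odds ratios and standard errors (optional if counts given).
#' @param events_treat,n_treat,events_ctrl,n_ctrl Optional 2x2 counts.
#' @param year Optional publication year (or any integer ordering key).
#' @param outcome_label Free-text description of the pooled outcome.
#' @param correction Passed to [log_odds_ratio()] when effects are computed
#'   from counts.
#' @return An object of class `meta_dataset`: a list with a `studies` data
#'   frame and the `outcome_label`.
#' @export
meta_dataset <- function(label, y = NULL, se = NULL,
                         events_treat = NULL, n_treat = NULL,
                         events_ctrl = NULL, n_ctrl = NULL,
                         year = NULL, outcome_label = "outcome",
                         correction = TRUE) {
  label <- as.character(label)
  K <- length(label)
  if (K < 1L) stop("at least one study is required", call. = FALSE)
  if (anyDuplicated(label)) {
    stop("study labels must be unique", call. = FALSE)
  }
  has_counts <- !is.null(events_treat)
  has_effects <- !is.null(y)
  if (!has_counts && !has_effects) {
    stop("supply either (y, se) or 2x2 counts", call. = FALSE)
  }
  if (has_counts) {
    for (nm in c("n_treat", "events_ctrl", "n_ctrl")) {
      if (is.null(get(nm))) stop("incomplete counts: missing ", nm, call. = FALSE)
    }
    eff <- log_odds_ratio(events_treat, n_treat, events_ctrl, n_ctrl,
                          correction = correction)
    if (has_effects) {
      if (is.null(se)) stop("y supplied without se", call. = FALSE)
      if (any(abs(eff$y - y) > 1e-9) || any(abs(eff$se - se) > 1e-9)) {
        stop("supplied (y, se) disagree with values recomputed from counts",
             call. = FALSE)
      }
    }
    y <- eff$y
    se <- eff$se
  }
  y <- as.numeric(y); se <- as.numeric(se)
  if (length(y) != K || length(se) != K) {
    stop("y and se must have one value per study", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(se))) {
    stop("y and se must be finite", call. = FALSE)
  }
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  studies <- data.frame(
    label = label,
    year = if (is.null(year)) rep(NA_integer_, K) else as.integer(year),
    events_treat = if (has_counts) as.integer(events_treat) else NA_integer_,
    n_treat = if (has_counts) as.integer(n_treat) else NA_integer_,
    events_ctrl = if (has_counts) as.integer(events_ctrl) else NA_integer_,
    n_ctrl = if (has_counts) as.integer(n_ctrl) else NA_integer_,
    y = y, se = se,
    stringsAsFactors = FALSE
  )
  structure(list(studies = studies, outcome_label = outcome_label),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("meta_dataset:", nrow(x$studies), "studies;",
      "outcome:", x$outcome_label, "\n")
  print(x$studies, row.names = FALSE)
  invisible(x)
}

n_studies <- function(dataset) nrow(dataset$studies)

assert_dataset <- function(dataset) {
  if (!inherits(dataset, "meta_dataset")) {
    stop("expected a meta_dataset (see meta_dataset() or read_studies())",
         call. = FALSE)
  }
  dataset
}

# Subset the first k studies (or an arbitrary index vector), keeping order.
dataset_subset <- function(dataset, idx) {
  s <- dataset$studies[idx, , drop = FALSE]
  structure(list(studies = s, outcome_label = dataset$outcome_label),
            class = "meta_dataset")
}

#' Read study-level data from CSV
#'
#' Two schemas are accepted. `counts`: columns `label, year, events_treat,
#' n_treat, events_ctrl, n_ctrl`, with effects computed via
#' [log_odds_ratio()]. `effects`: columns `label, year, log_or` and either
#' `se` or the pair `ci_low, ci_high` (95% bounds on the log odds ratio
#' scale, converted with [se_from_ci()]). Comma-separated, header row
#' required, decimal point. Row order is preserved.
#'
#' @param path CSV file path.
#' @param schema `"counts"` or `"effects"`.
#' @param outcome_label Outcome description attached to the dataset.
#' @param correction Continuity correction for zero cells (counts schema).
#' @return A [meta_dataset()].
#' @export
read_studies <- function(path, schema = c("counts", "effects"),
                         outcome_label = "outcome", correction = TRUE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- if (schema == "counts") {
    c("label", "year", "events_treat", "n_treat", "events_ctrl", "n_ctrl")
  } else {
    c("label", "year", "log_or")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema '", schema, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (schema == "effects" && !("se" %in% names(df)) &&
      !all(c("ci_low", "ci_high") %in% names(df))) {
    stop("effects schema requires either 'se' or both 'ci_low' and 'ci_high'",
         call. = FALSE)
  }
  num_cols <- if (schema == "counts") {
    c("year", "events_treat", "n_treat", "events_ctrl", "n_ctrl")
  } else {
    intersect(c("year", "log_or", "se", "ci_low", "ci_high"), names(df))
  }
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           call. = FALSE)
    }
    if (col != "year" && anyNA(v)) {
      stop("missing value in column '", col, "' at row ",
           which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  dup <- which(duplicated(df$label))
  if (length(dup)) {
    stop("duplicate study label '", df$label[dup[1]], "' at row ", dup[1],
         call. = FALSE)
  }
  if (schema == "counts") {
    meta_dataset(label = df$label, year = df$year,
                 events_treat = df$events_treat, n_treat = df$n_treat,
                 events_ctrl = df$events_ctrl, n_ctrl = df$n_ctrl,
                 outcome_label = outcome_label, correction = correction)
  } else {
    se <- if ("se" %in% names(df)) df$se else se_from_ci(df$ci_low, df$ci_high)
    meta_dataset(label = df$label, y = df$log_or, se = se, year = df$year,
                 outcome_label = outcome_label)
  }
}

#' Write study-level data to CSV
#'
#' Emits the same `counts` / `effects` schemas that [read_studies()] accepts,
#' so generated datasets round-trip through files.
#'
#' @param dataset A [meta_dataset()].
#' @param path Output CSV path.
#' @param schema `"counts"` (requires count columns to be present) or
#'   `"effects"`.
#' @return `path`, invisibly.
#' @export
write_studies <- function(dataset, path, schema = c("effects", "counts")) {
  assert_dataset(dataset)
  schema <- match.arg(schema)
  s <- dataset$studies
  out <- if (schema == "counts") {
    if (anyNA(s$events_treat)) {
      stop("dataset has no 2x2 counts; use schema = 'effects'", call. = FALSE)
    }
    s[, c("label", "year", "events_treat", "n_treat", "events_ctrl", "n_ctrl")]
  } else {
    data.frame(label = s$label, year = s$year, log_or = s$y, se = s$se)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a dataset to JSON (and back)
#'
#' @param dataset A [meta_dataset()].
#' @return JSON text with an explicit `schema_version` field.
#' @export
dataset_to_json <- function(dataset) {
  assert_dataset(dataset)
  jsonlite::toJSON(list(schema_version = "1.0",
                        outcome_label = dataset$outcome_label,
                        studies = dataset$studies),
                   dataframe = "rows", na = "null", auto_unbox = TRUE,
                   digits = NA)
}

#' @rdname dataset_to_json
#' @param json JSON text produced by `dataset_to_json()`.
#' @export
dataset_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (is.null(obj$schema_version) || obj$schema_version != "1.0") {
    stop("unsupported dataset schema version", call. = FALSE)
  }
  s <- obj$studies
  has_counts <- !is.null(s$events_treat) && !anyNA(s$events_treat)
  meta_dataset(label = s$label, y = s$y, se = s$se,
               events_treat = if (has_counts) s$events_treat,
               n_treat = if (has_counts) s$n_treat,
               events_ctrl = if (has_counts) s$events_ctrl,
               n_ctrl = if (has_counts) s$n_ctrl,
               year = s$year, outcome_label = obj$outcome_label)
}
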