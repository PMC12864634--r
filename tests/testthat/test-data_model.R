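test_that("log odds ratio and SE match the closed form", {
  cases <- list(
    # (a, n1, c, n2) -> expected y, se
    list(c(10, 20, 10, 20), 0, sqrt(0.4)),
    list(c(5, 20, 10, 20), log(1 / 3), sqrt(1 / 5 + 1 / 15 + 1 / 10 + 1 / 10)),
    list(c(12, 120, 25, 130), log((12 * 105) / (108 * 25)),
         sqrt(1 / 12 + 1 / 108 + 1 / 25 + 1 / 105))
  )
  for (cs in cases) {
    eff <- do.call(log_odds_ratio, as.list(cs[[1]]))
    expect_equal(eff$y, cs[[2]], tolerance = 1e-12)
    expect_equal(eff$se, cs[[3]], tolerance = 1e-12)
  }
})

test_that("continuity correction adds 0.5 to all cells only when needed", {
  eff <- log_odds_ratio(0, 20, 5, 20, correction = TRUE)
  expect_equal(eff$y, log((0.5 * 15.5) / (20.5 * 5.5)))
  expect_equal(eff$se, sqrt(1 / 0.5 + 1 / 20.5 + 1 / 5.5 + 1 / 15.5))
  # no zero cell: correction flag has no effect
  expect_identical(log_odds_ratio(5, 20, 10, 20, correction = TRUE),
                   log_odds_ratio(5, 20, 10, 20, correction = FALSE))
  expect_error(log_odds_ratio(0, 20, 5, 20, correction = FALSE),
               class = "metabf_zero_cell_error")
  expect_error(log_odds_ratio(0, 20, 0, 30),
               class = "metabf_degenerate_table_error")
  expect_error(log_odds_ratio(20, 20, 30, 30),
               class = "metabf_degenerate_table_error")
  expect_error(log_odds_ratio(25, 20, 5, 20))
})

test_that("log odds ratio is antisymmetric under swapping arms", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    a <- sample(1:(n1 - 1), 1); c <- sample(1:(n2 - 1), 1)
    fwd <- log_odds_ratio(a, n1, c, n2, correction = FALSE)
    rev <- log_odds_ratio(c, n2, a, n1, correction = FALSE)
    expect_equal(rev$y, -fwd$y, tolerance = 1e-12)
    expect_equal(rev$se, fwd$se, tolerance = 1e-12)
  }
})

test_that("SE recovery from published intervals and OR back-transform", {
  y <- -0.45
  se <- 0.21
  ci <- c(y - 1.96 * se, y + 1.96 * se)
  expect_equal(se_from_ci(ci[1], ci[2]), se, tolerance = 1e-12)
  bt <- back_transform(y, ci)
  expect_equal(log(bt$or), y, tolerance = 1e-12)
  expect_equal(log(bt$interval), ci, tolerance = 1e-12)
  expect_equal(back_transform(0), 1)
  expect_error(se_from_ci(0.5, 0.1))
})

test_that("dataset construction enforces the study-level invariants", {
  expect_error(meta_dataset(c("a", "a"), y = c(0, 1), se = c(1, 1)),
               "unique")
  expect_error(meta_dataset("a", y = 0, se = 0), "> 0")
  expect_error(meta_dataset("a", y = Inf, se = 1), "finite")
  # counts and effects must agree to 1e-9
  eff <- log_odds_ratio(5, 20, 10, 20)
  expect_silent(meta_dataset("a", y = eff$y, se = eff$se,
                             events_treat = 5, n_treat = 20,
                             events_ctrl = 10, n_ctrl = 20))
  expect_error(meta_dataset("a", y = eff$y + 1e-6, se = eff$se,
                            events_treat = 5, n_treat = 20,
                            events_ctrl = 10, n_ctrl = 20),
               "disagree")
})

test_that("CSV round trip preserves both schemas and rejects bad input", {
  d <- meta_dataset(label = c("x", "y", "z"), year = c(2003, 2001, 2002),
                    events_treat = c(4, 9, 0), n_treat = c(50, 120, 60),
                    events_ctrl = c(9, 14, 5), n_ctrl = c(55, 115, 62))
  counts_csv <- withr::local_tempfile(fileext = ".csv")
  write_studies(d, counts_csv, schema = "counts")
  d2 <- read_studies(counts_csv, schema = "counts")
  expect_equal(d2$studies[c("label", "year", "y", "se")],
               d$studies[c("label", "year", "y", "se")])

  eff_csv <- withr::local_tempfile(fileext = ".csv")
  write_studies(d, eff_csv, schema = "effects")
  d3 <- read_studies(eff_csv, schema = "effects")
  expect_equal(d3$studies$y, d$studies$y, tolerance = 1e-12)
  expect_equal(d3$studies$se, d$studies$se, tolerance = 1e-12)

  # effects schema via ci bounds instead of se
  df <- data.frame(label = "a", year = 2001, log_or = -0.4,
                   ci_low = -0.4 - 1.96 * 0.3, ci_high = -0.4 + 1.96 * 0.3)
  ci_csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, ci_csv, row.names = FALSE)
  expect_equal(read_studies(ci_csv, schema = "effects")$studies$se, 0.3,
               tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("a", "b"), year = 1:2,
                       log_or = c(0.1, 0.2), se = c(0.3, 0)),
            bad, row.names = FALSE)
  expect_error(read_studies(bad, schema = "effects"), "> 0")
  write.csv(data.frame(label = c("a", "a"), year = 1:2,
                       log_or = c(0.1, 0.2), se = c(0.3, 0.2)),
            bad, row.names = FALSE)
  expect_error(read_studies(bad, schema = "effects"), "duplicate")
  write.csv(data.frame(label = "a", year = 1, log_or = "oops", se = 0.3),
            bad, row.names = FALSE)
  expect_error(read_studies(bad, schema = "effects"), "non-numeric")
  expect_error(read_studies(bad, schema = "counts"), "missing column")
})

test_that("JSON serialization round-trips a dataset field-for-field", {
  d <- meta_dataset(label = c("a", "b"), y = c(-0.2, 0.4), se = c(0.3, 0.5),
                    year = c(2010, 2011), outcome_label = "leak")
  d2 <- dataset_from_json(dataset_to_json(d))
  expect_equal(d2$studies, d$studies)
  expect_identical(d2$outcome_label, d$outcome_label)
})
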