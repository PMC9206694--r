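# hand-built retained screen + db with fully controlled fields
summary_fixture <- function() {
  reports <- tibble::tibble(
    case_id = sprintf("c%d", 1:4),
    country = c("FR", "US", "JP", "FR"),
    report_year = c(1995L, 2005L, 2015L, 2019L),
    age_years = c(40, 60, NA, 20),
    sex = c("female", "female", "male", "unknown"),
    outcomes = list("death", character(0), character(0), "hospitalisation"))
  drugs <- tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4", "c2", "c3"),
    drug_id = c("dX", "dX", "dX", "dX", "dY", "dZ"),
    drug_name = c(rep("xdrug", 4), "ydrug", "zdrug"),
    role = c(rep("suspect", 5), "concomitant"),
    time_to_onset_days = c(10L, 16L, NA, NA, 5L, 2L),
    action_taken = c("withdrawn", "continued", "unknown", "unknown",
                     "withdrawn", "unknown"))
  reactions <- tibble::tibble(
    case_id = c("c1", "c2", "c3", "c4", "c1", "c3"),
    pt = c(rep("Hyperammonaemia", 4), "Hepatic failure", "Seizure"))
  db <- icsr_db(reports, drugs, reactions)
  excl <- tibble::tibble(
    drug_id = "dX", drug_name = "xdrug", n_observed = 4L, n_drug = 4L,
    n_effect = 4L, n_total = 4L, expected = 4, ic = 0, ic025 = 0.8,
    ic975 = 2, significant = TRUE,
    case_ids = list(sprintf("c%d", 1:4)),
    exclusion_reason = factor(NA, levels = c("not_significant",
                                             "single_country", "protopathic")),
    retained = TRUE)
  class(excl) <- c("ic_screen", class(excl))
  list(db = db, excl = excl)
}

test_that("per-drug summaries use available-case denominators", {
  fx <- summary_fixture()
  s <- summarize_drugs(fx$excl, fx$db, hyperammonaemia_event())
  expect_equal(nrow(s), 1L)
  expect_equal(s$n_cases, 4L)
  expect_equal(s$pct_death, 25)                      # 1 death / 4 cases
  expect_equal(s$pct_female, 100 * 2 / 3)            # sex known in 3
  expect_equal(s$denom_sex, 3L)
  expect_equal(s$age_mean, mean(c(40, 60, 20)))      # age known in 3
  expect_equal(s$age_min, 20)
  expect_equal(s$age_max, 60)
  expect_equal(s$median_tto_days, 13)                # known TTOs 10, 16
  expect_equal(s$denom_tto, 2L)
  # c2 has two suspects (dX, dY); the others only dX; concomitant dZ ignored
  expect_equal(s$pct_single_suspect, 75)
  expect_equal(s$mean_n_suspect, mean(c(1, 2, 1, 1)))
  # interruption among cases with described action (c1 withdrawn, c2 continued)
  expect_equal(s$pct_interruption, 50)
  expect_equal(s$denom_action, 2L)
  # liver term co-reported in c1 only; NI: c1 = NI2, c2 = NI1, c3/c4 = NI0
  expect_equal(s$pct_liver, 25)
  expect_equal(s$pct_kidney, 0)
  expect_equal(s$pct_ni0, 50)
  expect_equal(s$miss_age, 25)
  # no knowledge table supplied: B1
  expect_equal(as.character(s$imputability), "B1")
})

test_that("summaries propagate missingness instead of fabricating zeros", {
  fx <- summary_fixture()
  fx$db$drugs$time_to_onset_days <- NA_integer_
  s <- summarize_drugs(fx$excl, fx$db, hyperammonaemia_event())
  expect_true(is.na(s$median_tto_days))
  expect_equal(s$denom_tto, 0L)
  expect_equal(s$miss_tto, 100)
})

test_that("summarize_drug rejects drugs that were not retained", {
  fx <- summary_fixture()
  expect_error(summarize_drug(fx$excl, fx$db, hyperammonaemia_event(), "dY"),
               class = "icscreen_lookup_error")
  one <- summarize_drug(fx$excl, fx$db, hyperammonaemia_event(), "dX")
  expect_equal(one$drug_id, "dX")
})

test_that("imputability joins the label-knowledge table by normalised name", {
  fx <- summary_fixture()
  know <- tibble::tibble(drug_name = "XDRUG ", in_label = FALSE,
                         widely_published = TRUE,
                         case_reports_published = TRUE)
  s <- summarize_drugs(fx$excl, fx$db, hyperammonaemia_event(),
                       knowledge = know)
  expect_equal(as.character(s$imputability), "B3")
})

test_that("a planted log-normal time to onset is recovered by the median", {
  # a strongly associated drug taken by a fifth of the cohort, TTO ~
  # logN(ln 13, 1): the sample median at n > 500 lies inside the
  # order-statistic band [9, 18]
  cat1 <- tibble::tibble(
    drug_id = c("d_tto", "filler"), class_label = "a",
    popularity_weight = c(0.2, 0.8), rr_event = c(40, 1),
    death_prob = 0.05, tto_log_mean = log(13), tto_log_sd = 1)
  cfg <- generator_config(4000, cat1, p0 = 0.02, mean_extra_drugs = 0,
                          missingness = c(time_to_onset_days = 0), seed = 14L)
  g <- generate_database(cfg)
  sc <- screen_drugs(g$db, hyperammonaemia_event())
  ex <- apply_exclusions(sc, g$db)
  expect_true(ex$retained[1])
  expect_gte(ex$n_observed[1], 500)
  s <- summarize_drugs(ex, g$db, hyperammonaemia_event())
  expect_gte(s$median_tto_days, 9)
  expect_lte(s$median_tto_days, 18)
})

test_that("cohort summary computes the descriptives it reports", {
  fx <- summary_fixture()
  co <- cohort_summary(fx$db, case_ids = c("c1", "c2"))
  expect_equal(co$stats$age_mean, 50)
  expect_equal(co$stats$age_min, 40)
  expect_equal(co$stats$age_max, 60)
  expect_equal(co$stats$pct_female, 100)
  # median of TTO values {10, 16, 5} across analysed mentions
  expect_equal(co$stats$tto_median, 10)
  # shares normalise
  expect_equal(sum(co$countries$pct), 100)
  expect_equal(sum(co$continents$pct), 100, tolerance = 1e-9)
  expect_equal(sum(co$decades$n), co$stats$n_cases)
  expect_error(cohort_summary(fx$db, case_ids = character(0)),
               class = "icscreen_empty_cohort")
})

test_that("cohort TTO median matches the direct quantile", {
  db <- summary_fixture()$db
  db$drugs$time_to_onset_days <- c(2L, 13L, 59L, NA, NA, NA)
  co <- cohort_summary(db)
  expect_equal(co$stats$tto_median, 13)
  expect_equal(co$stats$denom_tto, 3L)
})

test_that("run_pipeline writes a complete, reproducible result set", {
  g <- generate_database(small_config(n_cases = 2500, seed = 19L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out <- run_pipeline(g$db, hyperammonaemia_event(), d1)
  expect_setequal(list.files(d1),
                  c("screen.csv", "retained.csv", "excluded.csv",
                    "drug_summaries.csv", "cohort.json", "run_log.json"))
  # one summary row per retained drug; partition preserved in the CSVs
  retained <- readr::read_csv(file.path(d1, "retained.csv"),
                              show_col_types = FALSE)
  summaries <- readr::read_csv(file.path(d1, "drug_summaries.csv"),
                               show_col_types = FALSE)
  screen <- readr::read_csv(file.path(d1, "screen.csv"),
                            show_col_types = FALSE)
  expect_equal(nrow(summaries), nrow(retained))
  expect_equal(nrow(screen), nrow(out$screen))
  # every percentage column is within [0, 100] with numerator <= denominator
  pcts <- unlist(summaries[grepl("^(pct_|miss_)", names(summaries))])
  expect_true(all(is.na(pcts) | (pcts >= 0 & pcts <= 100)))
  # rerun on the same inputs is byte-identical
  run_pipeline(g$db, hyperammonaemia_event(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("an empty event definition is rejected before any computation", {
  expect_error(event_definition("empty", character(0)),
               class = "icscreen_config_error")
  expect_error(event_definition("blank", "   "),
               class = "icscreen_config_error")
})
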