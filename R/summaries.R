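pct <- function(x) {
  # available-case percentage: NA entries leave the denominator
  if (!sum(!is.na(x))) return(NA_real_)
  100 * mean(x, na.rm = TRUE)
}

#' Country to continent lookup
#'
#' Packaged mapping for the country codes used by the generator and
#' fixtures; continent shares in [cohort_summary()] are computed from it.
#' Codes outside the table map to `"other"`.
#'
#' @return Tibble with columns `country` and `continent`.
#' @export
country_continents <- function() {
  m <- list(
    americas = c("US", "CA", "BR", "MX", "AR", "CL"),
    europe = c("FR", "DE", "GB", "IT", "ES", "SE", "NL", "CH", "PL", "BE",
               "PT", "AT", "DK", "NO", "FI", "IE"),
    asia = c("JP", "CN", "KR", "IN", "TH", "SG", "MY", "PH", "VN", "TW"),
    oceania = c("AU", "NZ"),
    middle_east = c("IL", "SA", "AE", "TR", "IR"),
    africa = c("ZA", "EG", "NG", "KE", "MA", "TN")
  )
  tibble(continent = rep(names(m), lengths(m)),
         country = unlist(m, use.names = FALSE))
}

# per-(case, drug) record for the retained drugs: one row per pair with the
# drug-level fields collapsed (first non-missing TTO; withdrawn if any
# eligible mention was withdrawn; best-documented NI)
drug_case_records <- function(excluded, db, event,
                              phenotype_map = default_phenotype_map()) {
  retained <- filter(excluded, .data$retained)
  pairs <- retained |>
    select("drug_id", "drug_name", "ic025", "case_ids") |>
    tidyr::unnest("case_ids") |>
    dplyr::rename(case_id = "case_ids")

  mentions <- db$drugs |>
    filter(.data$role %in% c("suspect", "interacting")) |>
    informativity() |>
    group_by(.data$case_id, .data$drug_id) |>
    summarise(
      time_to_onset_days = suppressWarnings(
        min(.data$time_to_onset_days, na.rm = TRUE)),
      withdrawn = any(.data$action_taken == "withdrawn"),
      action_known = any(.data$action_taken != "unknown"),
      ni = max(.data$ni),
      .groups = "drop"
    ) |>
    mutate(time_to_onset_days = ifelse(is.finite(.data$time_to_onset_days),
                                       .data$time_to_onset_days, NA_real_))

  n_elig <- eligible_drugs(db$drugs) |> count(.data$case_id, name = "n_suspect")
  pres <- classify_presentation(db, phenotype_map, event = event) |>
    mutate(hit = TRUE) |>
    tidyr::pivot_wider(names_from = "category", values_from = "hit",
                       values_fill = FALSE, names_prefix = "pres_")
  for (cat_name in unique(phenotype_map$category)) {
    col <- paste0("pres_", cat_name)
    if (!col %in% names(pres)) pres[[col]] <- logical(nrow(pres))
  }

  pairs |>
    left_join(mentions, by = c("case_id", "drug_id")) |>
    left_join(select(is_serious(db$reports), "case_id", "country",
                     "age_years", "sex", "outcomes", "serious"),
              by = "case_id") |>
    left_join(n_elig, by = "case_id") |>
    left_join(pres, by = "case_id") |>
    mutate(across(dplyr::starts_with("pres_"),
                  ~ ifelse(is.na(.x), FALSE, .x)),
           death = purrr::map_lgl(.data$outcomes, ~ "death" %in% .x))
}

#' Per-drug clinical summary table
#'
#' One row per retained drug with the analytical quantities of a per-drug
#' safety profile: case count, IC025, age distribution (mean, min, max),
#' median time to onset, percentage female, mortality, single-suspect share,
#' mean number of suspect/interacting drugs per case, drug-interruption
#' percentage, liver- and kidney-dysfunction percentages, NI0 percentage,
#' extrinsic imputability, the clinical-presentation profile and per-field
#' missingness. Every percentage uses an available-case denominator (cases
#' with the field non-missing); the `denom_*` columns report those
#' denominators so the missing-data accounting is explicit.
#'
#' @param excluded Output of [apply_exclusions()].
#' @param db The `icsr_db` screened.
#' @param event The [event_definition()] used for screening (its PTs are
#'   excluded from presentation classification).
#' @param knowledge Optional label-knowledge tibble (`drug_name`,
#'   `in_label`, `widely_published`, `case_reports_published`); drugs
#'   absent from it grade B1.
#' @param phenotype_map Phenotype map tibble; default
#'   [default_phenotype_map()].
#' @return Tibble with one row per retained drug, ordered by descending case
#'   count then drug id.
#' @export
summarize_drugs <- function(excluded, db, event,
                            knowledge = NULL,
                            phenotype_map = default_phenotype_map()) {
  stopifnot(inherits(db, "icsr_db"))
  check_cols(excluded, c("retained", "ic025", "case_ids"), "excluded screen")
  rec <- drug_case_records(excluded, db, event, phenotype_map)
  pres_cols <- grep("^pres_", names(rec), value = TRUE)

  out <- rec |>
    group_by(.data$drug_id, .data$drug_name, .data$ic025) |>
    summarise(
      n_cases = n(),
      age_mean = if (any(!is.na(.data$age_years)))
        mean(.data$age_years, na.rm = TRUE) else NA_real_,
      age_min = if (any(!is.na(.data$age_years)))
        min(.data$age_years, na.rm = TRUE) else NA_real_,
      age_max = if (any(!is.na(.data$age_years)))
        max(.data$age_years, na.rm = TRUE) else NA_real_,
      median_tto_days = if (any(!is.na(.data$time_to_onset_days)))
        stats::median(.data$time_to_onset_days, na.rm = TRUE) else NA_real_,
      pct_female = pct(ifelse(.data$sex == "unknown", NA,
                              .data$sex == "female")),
      pct_death = 100 * mean(.data$death),
      pct_serious = 100 * mean(.data$serious),
      pct_single_suspect = 100 * mean(.data$n_suspect == 1L),
      mean_n_suspect = mean(.data$n_suspect),
      pct_interruption = pct(ifelse(.data$action_known, .data$withdrawn, NA)),
      pct_liver = 100 * mean(.data$pres_liver_dysfunction),
      pct_kidney = 100 * mean(.data$pres_kidney_dysfunction),
      pct_ni0 = 100 * mean(.data$ni == "NI0"),
      across(dplyr::all_of(pres_cols), ~ 100 * mean(.x),
             .names = "pct_{.col}"),
      denom_age = sum(!is.na(.data$age_years)),
      denom_sex = sum(.data$sex != "unknown"),
      denom_tto = sum(!is.na(.data$time_to_onset_days)),
      denom_action = sum(.data$action_known),
      miss_age = 100 * mean(is.na(.data$age_years)),
      miss_sex = 100 * mean(.data$sex == "unknown"),
      miss_tto = 100 * mean(is.na(.data$time_to_onset_days)),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("^pct_pres_", "pct_", .x)) |>
    arrange(dplyr::desc(.data$n_cases), .data$drug_id)

  out$imputability <- if (is.null(knowledge)) {
    factor("B1", levels = c("B1", "B2", "B3", "B4"), ordered = TRUE)[
      rep(1, nrow(out))]
  } else {
    do.call(c, lapply(out$drug_name, imputability_for, knowledge = knowledge))
  }
  out
}

#' @rdname summarize_drugs
#' @param drug_id A single retained drug; requesting an excluded or unknown
#'   drug is a lookup error.
#' @export
summarize_drug <- function(excluded, db, event, drug_id,
                           knowledge = NULL,
                           phenotype_map = default_phenotype_map()) {
  if (!drug_id %in% excluded$drug_id[excluded$retained]) {
    abort(sprintf("drug '%s' was not retained by the exclusion procedure",
                  drug_id),
          class = "icscreen_lookup_error")
  }
  out <- summarize_drugs(excluded, db, event, knowledge, phenotype_map)
  out[out$drug_id == drug_id, ]
}

#' Cohort-level descriptive summary
#'
#' Describes a set of cases (by default all cases of the database): age mean,
#' SD and range, sex percentages, time-to-onset median and inter-quartile
#' range (over the cases' analysed drug mentions, available-case), case
#' counts per country and continent, and cases per decade of report year.
#'
#' @param db An `icsr_db`.
#' @param case_ids Optional character vector restricting the cohort (e.g.
#'   the union of retained drugs' event cases). An empty cohort is an error.
#' @return Object of class `cohort_summary`: a list with one-row tibble
#'   `stats` and tibbles `countries`, `continents`, `decades`.
#' @export
cohort_summary <- function(db, case_ids = NULL) {
  stopifnot(inherits(db, "icsr_db"))
  r <- db$reports
  if (!is.null(case_ids)) r <- filter(r, .data$case_id %in% case_ids)
  if (!nrow(r)) {
    abort("empty cohort: no cases selected", class = "icscreen_empty_cohort")
  }
  tto <- db$drugs |>
    filter(.data$case_id %in% r$case_id,
           .data$role %in% c("suspect", "interacting"),
           !is.na(.data$time_to_onset_days)) |>
    dplyr::pull("time_to_onset_days")

  stats_row <- tibble(
    n_cases = nrow(r),
    age_mean = if (any(!is.na(r$age_years)))
      mean(r$age_years, na.rm = TRUE) else NA_real_,
    age_sd = stats::sd(r$age_years, na.rm = TRUE),
    age_min = suppressWarnings(min(r$age_years, na.rm = TRUE)),
    age_max = suppressWarnings(max(r$age_years, na.rm = TRUE)),
    denom_age = sum(!is.na(r$age_years)),
    pct_male = pct(ifelse(r$sex == "unknown", NA, r$sex == "male")),
    pct_female = pct(ifelse(r$sex == "unknown", NA, r$sex == "female")),
    denom_sex = sum(r$sex != "unknown"),
    tto_median = if (length(tto)) stats::median(tto) else NA_real_,
    tto_q1 = if (length(tto)) unname(stats::quantile(tto, 0.25)) else NA_real_,
    tto_q3 = if (length(tto)) unname(stats::quantile(tto, 0.75)) else NA_real_,
    denom_tto = length(tto),
    pct_serious = 100 * mean(lengths(r$outcomes) > 0),
    pct_death = 100 * mean(purrr::map_lgl(r$outcomes, ~ "death" %in% .x))
  )
  countries <- r |>
    count(.data$country, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    left_join(country_continents(), by = "country") |>
    mutate(continent = ifelse(is.na(.data$continent), "other",
                              .data$continent)) |>
    arrange(dplyr::desc(.data$n))
  continents <- countries |>
    group_by(.data$continent) |>
    summarise(n = sum(.data$n), pct = sum(.data$pct), .groups = "drop") |>
    arrange(dplyr::desc(.data$n))
  decades <- r |>
    mutate(decade = sprintf("%d-%d", 10 * (.data$report_year %/% 10),
                            10 * (.data$report_year %/% 10) + 9)) |>
    count(.data$decade, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    arrange(.data$decade)

  structure(list(stats = stats_row, countries = countries,
                 continents = continents, decades = decades),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<cohort_summary> %d cases\n", s$n_cases))
  cat(sprintf("  age: mean %.1f (sd %.1f, range %.0f-%.0f, n=%d)\n",
              s$age_mean, s$age_sd, s$age_min, s$age_max, s$denom_age))
  cat(sprintf("  sex: %.1f%% male / %.1f%% female (n=%d)\n",
              s$pct_male, s$pct_female, s$denom_sex))
  cat(sprintf("  time to onset: median %.0f d (IQR %.0f-%.0f, n=%d)\n",
              s$tto_median, s$tto_q1, s$tto_q3, s$denom_tto))
  cat("  continents:",
      paste(sprintf("%s %.1f%%", x$continents$continent, x$continents$pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the full screening-and-summary pipeline
#'
#' Orchestrates case selection, disproportionality screening, staged
#' exclusions, scoring and summaries, and writes the result set to a
#' directory: `screen.csv` (every screened drug with counts, IC statistics
#' and exclusion reason), `retained.csv` and `excluded.csv` (the partition),
#' `drug_summaries.csv` (per retained drug; percentage columns rounded to
#' one decimal alongside full-precision `*_raw` columns), `cohort.json`
#' (cohort descriptives over the retained drugs' event cases) and
#' `run_log.json` (package version, seed-free content hashes of all inputs).
#' The pipeline draws no random numbers, so a rerun on identical inputs
#' rewrites byte-identical files.
#'
#' @param db An `icsr_db`.
#' @param event An [event_definition()].
#' @param out_dir Output directory (created if needed).
#' @param exclusions An [exclusion_config()].
#' @param knowledge Optional label-knowledge table, see [summarize_drugs()].
#' @param phenotype_map Phenotype map tibble.
#' @param method Credibility-bound method, see [ic_credibility_bound()].
#' @return Invisibly, a list with `screen` (tibble with exclusion reasons),
#'   `summaries` (per-drug tibble), `cohort` (a `cohort_summary`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(db, event, out_dir,
                         exclusions = exclusion_config(),
                         knowledge = NULL,
                         phenotype_map = default_phenotype_map(),
                         method = c("gamma", "approx")) {
  stopifnot(inherits(db, "icsr_db"), inherits(event, "event_definition"))
  method <- match.arg(method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  screen <- screen_drugs(db, event, method = method)
  excl <- apply_exclusions(screen, db, exclusions)
  summaries <- summarize_drugs(excl, db, event, knowledge, phenotype_map)
  retained_ids <- unique(unlist(excl$case_ids[excl$retained]))
  cohort <- cohort_summary(db, case_ids = retained_ids)

  flat <- excl |>
    select(-"case_ids") |>
    mutate(exclusion_reason = as.character(.data$exclusion_reason)) |>
    mutate(exclusion_reason = ifelse(is.na(.data$exclusion_reason), "",
                                     .data$exclusion_reason))
  readr::write_csv(flat, file.path(out_dir, "screen.csv"), na = "")
  readr::write_csv(filter(flat, .data$exclusion_reason == ""),
                   file.path(out_dir, "retained.csv"), na = "")
  readr::write_csv(filter(flat, .data$exclusion_reason != ""),
                   file.path(out_dir, "excluded.csv"), na = "")

  disp <- summaries
  pct_cols <- grep("^(pct_|miss_)", names(disp), value = TRUE)
  for (col in pct_cols) {
    disp[[paste0(col, "_raw")]] <- disp[[col]]
    disp[[col]] <- round(disp[[col]], 1)
  }
  disp$imputability <- as.character(disp$imputability)
  readr::write_csv(disp, file.path(out_dir, "drug_summaries.csv"), na = "")

  jsonlite::write_json(
    list(stats = cohort$stats, countries = cohort$countries,
         continents = cohort$continents, decades = cohort$decades),
    file.path(out_dir, "cohort.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log <- list(
    package = "icscreen",
    version = as.character(utils::packageVersion("icscreen")),
    method = method,
    event = event$name,
    event_pts = event$pts,
    db_hash = rlang::hash(db[c("reports", "drugs", "reactions")]),
    config_hash = rlang::hash(list(event, exclusions, knowledge,
                                   phenotype_map, method)),
    n_total = n_cases(db),
    tally = exclusion_tally(excl)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(screen = excl, summaries = summaries, cohort = cohort,
                 out_dir = out_dir))
}
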