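#' Packaged calibration fixture for the drug-selection pipeline
#'
#' Builds a synthetic spontaneous-report database whose drug catalog is
#' constructed so that the three-stage exclusion procedure reproduces the
#' reference stage tallies: 642 drugs associated with at least one
#' target-event case, of which 555 are excluded as not significant
#' (IC025 <= 0), 11 as single-country (all their event cases share one
#' country), 5 as protopathic (the ammonia-lowering therapies lactulose,
#' rifaximin, sodium phenylbutyrate, benzoic acid and carglumic acid, each
#' planted with a positive signal), leaving 71 drugs retained.
#'
#' The event-case counts are planted deterministically: null drugs receive
#' one or two event cases — counts for which the Gamma-posterior IC025 is
#' negative for every possible expected value — while planted drugs receive
#' enough event cases (and few enough non-event reports) that IC025 > 0 by a
#' comfortable margin. Countries of planted drugs' event cases cycle through
#' a multi-country rota except for the 11 single-country drugs, whose event
#' cases are pinned to one country each. The seed therefore moves only
#' nuisance fields (ages, sexes, times to onset, outcomes, report years,
#' background-case countries); the stage tallies are identical for every
#' seed, and [check_calibration()] verifies them by actually running the
#' screening-and-exclusion pipeline.
#'
#' @param seed Integer seed for the nuisance fields.
#' @param verify Run [check_calibration()] on the result (default `TRUE`).
#' @return List with elements `db` (the `icsr_db`), `event`
#'   (the hyperammonaemia [event_definition()]), `exclusions`
#'   (the default [exclusion_config()]), `ground_truth` (tibble `drug_id`,
#'   `group`, `n_event_cases`) and `expected_tally` (one-row tibble of the
#'   five reference stage counts).
#' @export
calibration_fixture <- function(seed = 2020L, verify = TRUE) {
  fx <- withr::with_seed(seed, build_calibration_fixture(seed))
  if (verify) check_calibration(fx)
  fx
}

build_calibration_fixture <- function(seed) {
  rota <- c("US", "FR", "JP", "DE", "GB", "BR", "IN", "CA")
  sc_countries <- c("JP", "KR", "CN", "IT", "ES", "AU", "SE", "NL", "CH",
                    "PL", "MX")

  retained <- tibble(
    drug_id = sprintf("sig_%03d", 1:71),
    drug_name = sprintf("signal drug %03d", 1:71),
    group = "retained",
    n_event = pmax(5L, as.integer(round(130 * (1:71)^-0.9))),
    n_background = 3L,
    country_mode = "rota"
  )
  single_country <- tibble(
    drug_id = sprintf("sc_%02d", 1:11),
    drug_name = sprintf("single-country drug %02d", 1:11),
    group = "single_country",
    n_event = 8L,
    n_background = 3L,
    country_mode = sc_countries
  )
  protopathic <- tibble(
    drug_id = sprintf("proto_%d", 1:5),
    drug_name = protopathic_hyperammonaemia(),
    group = "protopathic",
    n_event = 12L,
    n_background = 3L,
    country_mode = "rota"
  )
  nulls <- tibble(
    drug_id = sprintf("null_%03d", 1:555),
    drug_name = sprintf("null drug %03d", 1:555),
    group = "null",
    n_event = rep(c(1L, 2L), length.out = 555),
    n_background = 10L + (0:554) %% 30L,
    country_mode = "rota"
  )
  catalog <- bind_rows(retained, single_country, protopathic, nulls)

  # one event case per planted slot, one background case per background slot
  ev <- catalog[rep(seq_len(nrow(catalog)), catalog$n_event), ]
  ev$slot <- stats::ave(seq_len(nrow(ev)), ev$drug_id, FUN = seq_along)
  ev$case_id <- sprintf("E%05d", seq_len(nrow(ev)))
  ev$country <- ifelse(ev$country_mode == "rota",
                       rota[(ev$slot - 1L) %% length(rota) + 1L],
                       ev$country_mode)
  # every 7th mention is interacting rather than suspect: both are analysed
  ev$role <- ifelse(ev$slot %% 7L == 0L, "interacting", "suspect")

  bg <- catalog[rep(seq_len(nrow(catalog)), catalog$n_background), ]
  bg$case_id <- sprintf("B%05d", seq_len(nrow(bg)))
  bg$country <- sample(rota, nrow(bg), replace = TRUE)
  bg$role <- "suspect"

  event_pts <- default_event_pts()
  rx_ev <- tibble(
    case_id = ev$case_id,
    pt = sample(event_pts$pt, nrow(ev), replace = TRUE,
                prob = event_pts$weight)
  )
  # co-reported presentation terms on a third of event cases
  pheno <- default_phenotype_map()
  co <- which(stats::runif(nrow(ev)) < 1 / 3)
  rx_co <- tibble(case_id = ev$case_id[co],
                  pt = sample(pheno$pt, length(co), replace = TRUE))
  bg_pts <- default_background_pts()
  rx_bg <- tibble(case_id = bg$case_id,
                  pt = sample(bg_pts$pt, nrow(bg), replace = TRUE,
                              prob = bg_pts$weight))
  reactions <- bind_rows(rx_ev, rx_co, rx_bg) |>
    distinct(.data$case_id, .data$pt)

  # concomitant co-medication on a quarter of event cases: must never count
  conc_idx <- which(stats::runif(nrow(ev)) < 0.25)
  conc <- tibble(
    case_id = ev$case_id[conc_idx],
    drug_id = sprintf("conc_%02d", 1L + seq_along(conc_idx) %% 20L),
    drug_name = sprintf("concomitant drug %02d", 1L + seq_along(conc_idx) %% 20L),
    role = "concomitant"
  )

  all_cases <- bind_rows(
    tibble(case_id = ev$case_id, country = ev$country, is_event = TRUE),
    tibble(case_id = bg$case_id, country = bg$country, is_event = FALSE)
  )
  n <- nrow(all_cases)

  drugs <- bind_rows(
    tibble(case_id = ev$case_id, drug_id = ev$drug_id,
           drug_name = ev$drug_name, role = ev$role),
    tibble(case_id = bg$case_id, drug_id = bg$drug_id,
           drug_name = bg$drug_name, role = bg$role),
    conc
  ) |>
    mutate(
      time_to_onset_days = as.integer(round(stats::rlnorm(n(), log(13), 1.2))),
      action_taken = sample(icsr_actions, n(), replace = TRUE,
                            prob = c(0.35, 0.10, 0.35, 0.20))
    )
  drugs$time_to_onset_days[stats::runif(nrow(drugs)) < 0.35] <- NA_integer_

  age <- pmin(pmax(stats::rnorm(n, 43, 23), 0), 100)
  age[stats::runif(n) < 0.15] <- NA_real_
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.545, 0.455))
  sex[stats::runif(n) < 0.05] <- "unknown"
  death <- stats::runif(n) < ifelse(all_cases$is_event, 0.12, 0.04)
  hosp <- stats::runif(n) < ifelse(all_cases$is_event, 0.30, 0.10)
  other <- stats::runif(n) < 0.15
  outcomes <- purrr::pmap(list(death, hosp, other), function(d, h, o) {
    icsr_outcomes[c(d, FALSE, h, FALSE, FALSE, o)]
  })
  reports <- tibble(
    case_id = all_cases$case_id, country = all_cases$country,
    report_year = sample(1981:2020, n, replace = TRUE),
    age_years = age, sex = sex, outcomes = outcomes
  )

  db <- icsr_db(reports, drugs, reactions,
                provenance = list(generator = "icscreen::calibration_fixture",
                                  seed = seed))
  list(
    db = db,
    event = hyperammonaemia_event(),
    exclusions = exclusion_config(),
    ground_truth = select(catalog, "drug_id", "group",
                          n_event_cases = "n_event"),
    expected_tally = tibble(screened = 642L, not_significant = 555L,
                            single_country = 11L, protopathic = 5L,
                            retained = 71L)
  )
}

#' Verify the calibration fixture against its reference tallies
#'
#' Runs [screen_drugs()] and [apply_exclusions()] on a fixture and asserts
#' that every selection stage reproduces its reference count, naming the
#' failing stage on mismatch.
#'
#' @param fixture Output of [calibration_fixture()].
#' @return The realised tally (one-row tibble), invisibly.
#' @export
check_calibration <- function(fixture) {
  screen <- screen_drugs(fixture$db, fixture$event)
  excl <- apply_exclusions(screen, fixture$db, fixture$exclusions)
  got <- exclusion_tally(excl)
  want <- fixture$expected_tally
  for (stage in names(want)) {
    if (got[[stage]] != want[[stage]]) {
      abort(sprintf("calibration failure at stage '%s': got %d, expected %d",
                    stage, got[[stage]], want[[stage]]),
            class = "icscreen_calibration_error")
    }
  }
  invisible(got)
}
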