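#' Information component of a drug-event contingency
#'
#' The information component (IC) is the Bayesian disproportionality
#' statistic used for signal detection in spontaneous-report databases:
#' the log2 of the shrunk observed-to-expected reporting ratio
#'
#' \deqn{IC = \log_2 \frac{N_{observed} + 0.5}{N_{drug} N_{effect} / N_{total} + 0.5}}
#'
#' where `n_observed` is the number of cases reporting both the drug and the
#' event, `n_drug` the number of cases reporting the drug (any reaction),
#' `n_effect` the number of cases reporting the event (any drug) and
#' `n_total` the number of cases in the database. The +0.5 shrinkage terms
#' keep the statistic finite for all counts and pull small-count ratios
#' towards 1. All arguments are vectorised.
#'
#' @param n_observed,n_drug,n_effect,n_total Non-negative counts
#'   (`n_total` positive), recycled to a common length.
#' @return IC in bits.
#' @seealso [ic_credibility_bound()] for the credibility interval,
#'   [ic_stats()] for the data-frame interface.
#' @export
#' @examples
#' information_component(1, 100, 100, 10000)   # observed equals expected: 0
#' information_component(0, 1500, 500, 100000) # 0.5 / 8 = 2^-4
information_component <- function(n_observed, n_drug, n_effect, n_total) {
  check_counts(n_observed, n_drug, n_effect, n_total)
  e <- expected_count(n_drug, n_effect, n_total)
  log2((n_observed + 0.5) / (e + 0.5))
}

expected_count <- function(n_drug, n_effect, n_total) {
  n_drug * n_effect / n_total
}

check_counts <- function(n_observed, n_drug, n_effect, n_total) {
  if (any(n_total < 1)) {
    abort("n_total must be >= 1", class = "icscreen_validation_error")
  }
  if (any(n_observed < 0 | n_drug < 0 | n_effect < 0)) {
    abort("counts must be non-negative", class = "icscreen_validation_error")
  }
  if (any(n_observed > pmin(n_drug, n_effect)) ||
      any(n_drug > n_total) || any(n_effect > n_total)) {
    abort("counts violate n_observed <= min(n_drug, n_effect) <= n_total",
          class = "icscreen_validation_error")
  }
  invisible(NULL)
}

#' Credibility bound of the information component
#'
#' Posterior quantiles of the IC under the shrunk observed-to-expected Gamma
#' model: the ratio `(n_observed + 0.5) / (E + 0.5)` is treated as the mean
#' of a Gamma posterior with shape `n_observed + 0.5` and rate `E + 0.5`
#' (with `E = n_drug * n_effect / n_total`), and the bound is the log2 of the
#' requested tail quantile. `tail = 0.025` gives the IC025 used as the
#' signal-detection threshold (IC025 > 0 flags a statistical association);
#' `tail = 0.975` gives IC975.
#'
#' `method = "approx"` instead returns the closed-form approximation
#' historically used for IC intervals,
#' `IC - 3.3 (O+0.5)^{-1/2} - 2 (O+0.5)^{-3/2}` for the lower and
#' `IC + 2.4 (O+0.5)^{-1/2} - 0.5 (O+0.5)^{-3/2}` for the upper bound,
#' offered for sensitivity analysis; tails other than 0.025/0.975 are only
#' available with the exact Gamma method.
#'
#' @inheritParams information_component
#' @param tail Posterior tail probability in (0, 1).
#' @param method `"gamma"` (exact posterior quantile, default) or
#'   `"approx"`.
#' @return Bound in bits, vectorised like the count arguments.
#' @export
ic_credibility_bound <- function(n_observed, n_drug, n_effect, n_total,
                                 tail = 0.025,
                                 method = c("gamma", "approx")) {
  method <- match.arg(method)
  if (length(tail) != 1 || is.na(tail) || tail <= 0 || tail >= 1) {
    abort("tail must be a single probability strictly inside (0, 1)",
          class = "icscreen_domain_error")
  }
  check_counts(n_observed, n_drug, n_effect, n_total)
  e <- expected_count(n_drug, n_effect, n_total)
  if (method == "gamma") {
    log2(stats::qgamma(tail, shape = n_observed + 0.5, rate = e + 0.5))
  } else {
    ic <- log2((n_observed + 0.5) / (e + 0.5))
    o5 <- n_observed + 0.5
    if (tail == 0.025) {
      ic - 3.3 * o5^-0.5 - 2 * o5^-1.5
    } else if (tail == 0.975) {
      ic + 2.4 * o5^-0.5 - 0.5 * o5^-1.5
    } else {
      abort("method = 'approx' only provides the 0.025 and 0.975 tails",
            class = "icscreen_domain_error")
    }
  }
}

#' IC statistics for a table of contingency counts
#'
#' Data-frame-first wrapper: takes any tibble carrying the four count columns
#' (`n_observed`, `n_drug`, `n_effect`, `n_total`) and appends the derived
#' expected count, `ic`, `ic025`, `ic975` and the `significant` flag
#' (`ic025 > 0`).
#'
#' @param counts Data frame with the four count columns.
#' @param method Passed to [ic_credibility_bound()].
#' @return The input tibble with columns `expected`, `ic`, `ic025`, `ic975`,
#'   `significant` appended.
#' @export
ic_stats <- function(counts, method = c("gamma", "approx")) {
  method <- match.arg(method)
  check_cols(counts, c("n_observed", "n_drug", "n_effect", "n_total"),
             "counts")
  as_tibble(counts) |>
    mutate(
      expected = expected_count(.data$n_drug, .data$n_effect, .data$n_total),
      ic = information_component(.data$n_observed, .data$n_drug,
                                 .data$n_effect, .data$n_total),
      ic025 = ic_credibility_bound(.data$n_observed, .data$n_drug,
                                   .data$n_effect, .data$n_total,
                                   tail = 0.025, method = method),
      ic975 = ic_credibility_bound(.data$n_observed, .data$n_drug,
                                   .data$n_effect, .data$n_total,
                                   tail = 0.975, method = method),
      significant = .data$ic025 > 0
    )
}

#' Contingency counts for drug-event pairs
#'
#' Builds the case/non-case contrast at case level (a case mentioning a drug
#' twice counts once): `n_observed` is the number of target-event cases in
#' which the drug has an analysed role (suspect or interacting), `n_drug`
#' the number of cases with the drug in an analysed role regardless of
#' reaction, `n_effect` the number of target-event cases and `n_total` the
#' number of cases in the database. Concomitant mentions never enter either
#' the numerator or `n_drug`, matching the eligibility rule of the analysed
#' roles.
#'
#' @param db An `icsr_db`.
#' @param event An [event_definition()].
#' @param drug_ids Optional character vector restricting the output; a drug
#'   absent from the database yields a row with `n_observed = n_drug = 0`.
#'   Default: all drugs with at least one eligible mention in an event case.
#' @return Tibble with one row per drug: `drug_id`, `drug_name`,
#'   `n_observed`, `n_drug`, `n_effect`, `n_total`.
#' @export
contingency_counts <- function(db, event, drug_ids = NULL) {
  stopifnot(inherits(db, "icsr_db"))
  event_cases <- select_cases(db, event)
  elig <- eligible_drugs(db$drugs)
  names_tbl <- distinct(db$drugs, .data$drug_id, .keep_all = TRUE) |>
    select("drug_id", "drug_name")

  per_drug <- elig |>
    group_by(.data$drug_id) |>
    summarise(
      n_drug = dplyr::n_distinct(.data$case_id),
      n_observed = dplyr::n_distinct(.data$case_id[.data$case_id %in% event_cases]),
      .groups = "drop"
    )
  if (is.null(drug_ids)) {
    per_drug <- filter(per_drug, .data$n_observed > 0)
  } else {
    per_drug <- tibble(drug_id = as.character(drug_ids)) |>
      left_join(per_drug, by = "drug_id") |>
      mutate(across(c("n_drug", "n_observed"),
                    ~ ifelse(is.na(.x), 0L, .x)))
  }
  per_drug |>
    left_join(names_tbl, by = "drug_id") |>
    mutate(drug_name = ifelse(is.na(.data$drug_name), .data$drug_id,
                              .data$drug_name),
           n_effect = length(event_cases),
           n_total = n_cases(db)) |>
    select("drug_id", "drug_name", "n_observed", "n_drug",
           "n_effect", "n_total")
}

#' @rdname contingency_counts
#' @param drug_id Single drug identifier.
#' @export
contingency_for <- function(db, event, drug_id) {
  contingency_counts(db, event, drug_ids = drug_id)
}

#' Screen every drug in a database against a target event
#'
#' Runs the case/non-case disproportionality analysis for each drug with at
#' least one analysed-role (suspect or interacting) mention in a
#' target-event case: contingency counts, IC, Gamma-posterior credibility
#' bounds and the IC025 > 0 significance flag. Rows are ordered by
#' descending `n_observed` with ties broken by `drug_id` so the screen is
#' reproducible.
#'
#' @inheritParams contingency_counts
#' @param method Credibility-bound method, see [ic_credibility_bound()].
#' @return A tibble of class `ic_screen`, one row per drug, with the count
#'   columns, `expected`, `ic`, `ic025`, `ic975`, `significant` and a
#'   list-column `case_ids` holding each drug's event cases.
#' @export
screen_drugs <- function(db, event, method = c("gamma", "approx")) {
  method <- match.arg(method)
  dwe <- drugs_with_event(db, event)
  out <- contingency_counts(db, event) |>
    ic_stats(method = method) |>
    left_join(select(dwe, "drug_id", "case_ids"), by = "drug_id") |>
    arrange(dplyr::desc(.data$n_observed), .data$drug_id)
  class(out) <- c("ic_screen", class(out))
  attr(out, "event") <- event
  out
}
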