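# Small hand-built databases used across the unit tests.

# db with two hyperammonaemia cases and one background case
tiny_db <- function() {
  reports <- tibble::tibble(
    case_id = c("c1", "c2", "c3"),
    country = c("FR", "JP", "FR"),
    report_year = c(2010L, 2015L, 2019L),
    age_years = c(40, 60, NA),
    sex = c("male", "female", "unknown"),
    outcomes = list("death", character(0), c("hospitalisation", "other_important"))
  )
  drugs <- tibble::tibble(
    case_id = c("c1", "c1", "c2", "c3"),
    drug_id = c("dA", "dB", "dA", "dC"),
    drug_name = c("alphadrug", "betadrug", "alphadrug", "gammadrug"),
    role = c("suspect", "concomitant", "interacting", "suspect"),
    time_to_onset_days = c(9L, NA, 30L, NA),
    action_taken = c("withdrawn", "unknown", "continued", "unknown")
  )
  reactions <- tibble::tibble(
    case_id = c("c1", "c1", "c2", "c3"),
    pt = c("Hyperammonaemia", "Coma", "Hyperammonaemic crisis", "Nausea")
  )
  icscreen::icsr_db(reports, drugs, reactions)
}

# minimal generator config for fast property tests
small_config <- function(n_cases = 500, seed = 1L, ...) {
  icscreen::generator_config(
    n_cases = n_cases,
    drug_catalog = icscreen::planted_signal_catalog(n_null = 8, rr = 8),
    p0 = 0.02,
    seed = seed,
    ...
  )
}
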