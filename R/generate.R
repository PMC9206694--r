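#' Configuration for the synthetic report-database generator
#'
#' Describes a spontaneous-report database to simulate: a drug catalog with
#' skewed popularity and per-drug relative reporting rates for one target
#' event, co-prescription clustering by therapeutic class, event and
#' background preferred terms, demographics, seriousness, time to onset and
#' missingness. The generator plants known ground truth so that the whole
#' screening pipeline can be validated without access to a proprietary
#' pharmacovigilance database.
#'
#' @param n_cases Number of cases to generate (>= 1).
#' @param drug_catalog Tibble with one row per drug: `drug_id`,
#'   `class_label`, `popularity_weight` (> 0), `rr_event` (relative
#'   reporting rate for the target event; 1 = null drug), `death_prob`,
#'   `tto_log_mean`, `tto_log_sd` (> 0) and optionally
#'   `single_country_override` (country code forced onto the drug's event
#'   cases, `NA` for none).
#' @param event_pts Tibble `pt`, `weight`: PTs coding the target event.
#' @param background_pts Tibble `pt`, `weight`: PTs for non-event cases.
#' @param p0 Baseline event probability per suspect-drug exposure, in (0,1).
#'   A case exposed to drugs `d` experiences the event with probability
#'   `1 - prod(1 - clamp(p0 * rr_d, 0, 1))`: per-drug hazards combine
#'   independently, which keeps marginal relative reporting rates
#'   approximately multiplicative at small `p0` — the quantity the IC
#'   estimates.
#' @param mean_extra_drugs Mean of the Poisson count of drugs beyond the
#'   first (drug count per case is `1 + Poisson(mean_extra_drugs)`).
#' @param co_class_prob Probability that a multi-drug case draws all its
#'   drugs from a single therapeutic class (co-prescription clustering).
#' @param phenotype_conditional Named numeric vector: probability, given the
#'   event, of co-reporting one PT from each clinical-presentation category
#'   of [default_phenotype_map()].
#' @param missingness Named numeric vector of MCAR missingness
#'   probabilities for `age_years`, `sex`, `time_to_onset_days`,
#'   `action_taken`.
#' @param countries Named numeric vector of country sampling weights.
#' @param seed Integer seed; every random draw derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cases,
                             drug_catalog,
                             event_pts = default_event_pts(),
                             background_pts = default_background_pts(),
                             p0 = 0.005,
                             mean_extra_drugs = 0.3,
                             co_class_prob = 0.15,
                             phenotype_conditional = default_phenotype_conditional(),
                             missingness = c(age_years = 0.15, sex = 0.05,
                                             time_to_onset_days = 0.4,
                                             action_taken = 0.25),
                             countries = default_country_weights(),
                             seed = 1L) {
  drug_catalog <- as_tibble(drug_catalog)
  check_cols(drug_catalog, c("drug_id", "class_label", "popularity_weight",
                             "rr_event", "death_prob", "tto_log_mean",
                             "tto_log_sd"), "drug_catalog")
  if (!"single_country_override" %in% names(drug_catalog)) {
    drug_catalog$single_country_override <- NA_character_
  }
  if (!"drug_name" %in% names(drug_catalog)) {
    drug_catalog$drug_name <- drug_catalog$drug_id
  }
  cfg <- structure(list(
    n_cases = as.integer(n_cases), drug_catalog = drug_catalog,
    event_pts = as_tibble(event_pts), background_pts = as_tibble(background_pts),
    p0 = p0, mean_extra_drugs = mean_extra_drugs,
    co_class_prob = co_class_prob,
    phenotype_conditional = phenotype_conditional,
    missingness = missingness, countries = countries,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p0, cfg$co_class_prob, cfg$phenotype_conditional,
             cfg$missingness, cfg$drug_catalog$death_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "icscreen_config_error")
  }
  if (cfg$p0 <= 0 || cfg$p0 >= 1) {
    abort("p0 must lie strictly inside (0, 1)", class = "icscreen_config_error")
  }
  if (cfg$n_cases < 1) {
    abort("n_cases must be >= 1", class = "icscreen_config_error")
  }
  if (any(cfg$drug_catalog$popularity_weight <= 0) ||
      any(cfg$drug_catalog$tto_log_sd <= 0) ||
      any(c(cfg$event_pts$weight, cfg$background_pts$weight) <= 0) ||
      any(cfg$countries <= 0)) {
    abort("weights and tto_log_sd must be positive",
          class = "icscreen_config_error")
  }
  if (cfg$mean_extra_drugs < 0) {
    abort("mean_extra_drugs must be non-negative",
          class = "icscreen_config_error")
  }
  if (any(cfg$drug_catalog$rr_event <= 0)) {
    abort("rr_event must be positive (1 = null drug)",
          class = "icscreen_config_error")
  }
  invisible(cfg)
}

#' @rdname generator_config
#' @export
default_event_pts <- function() {
  tibble(pt = c("Hyperammonaemia", "Hyperammonaemic encephalopathy",
                "Hyperammonaemic crisis"),
         weight = c(0.80, 0.15, 0.05))
}

#' @rdname generator_config
#' @export
default_background_pts <- function() {
  tibble(
    pt = c("Nausea", "Headache", "Rash", "Diarrhoea", "Dizziness",
           "Pyrexia", "Fatigue", "Vomiting", "Pruritus", "Insomnia",
           "Anaemia", "Cough"),
    weight = c(10, 9, 8, 8, 7, 6, 6, 5, 4, 3, 3, 2)
  )
}

#' @rdname generator_config
#' @export
default_phenotype_conditional <- function() {
  c(coma_altered_consciousness = 0.35, brain_oedema = 0.04,
    seizures = 0.12, neuropsychiatric = 0.15, misc_neurological = 0.10,
    liver_dysfunction = 0.07, kidney_dysfunction = 0.03)
}

#' @rdname generator_config
#' @export
default_country_weights <- function() {
  # continental mix close to a global pharmacovigilance stream:
  # ~40% Americas, ~34% Europe, ~22% Asia, small Oceania/Africa/Middle East
  c(US = 30, CA = 5, BR = 5, FR = 10, DE = 9, GB = 8, IT = 4, ES = 3,
    JP = 12, CN = 5, KR = 3, IN = 2.5, AU = 2, NZ = 0.3, IL = 1, SA = 0.4,
    ZA = 0.3, EG = 0.2)
}

#' Generate a synthetic spontaneous-report database
#'
#' Fixed generative procedure, fully determined by the config seed:
#' \enumerate{
#'   \item drug count per case `k = 1 + Poisson(mean_extra_drugs)`;
#'   \item for multi-drug cases, with probability `co_class_prob` all `k`
#'     drugs come from one therapeutic class (chosen by summed popularity),
#'     otherwise drugs are drawn by popularity weight without replacement;
#'   \item the target event occurs with probability
#'     `1 - prod(1 - clamp(p0 * rr_event_d, 0, 1))` over the case's drugs;
#'   \item event cases receive one event PT by weight plus co-reported
#'     presentation PTs by `phenotype_conditional`; non-event cases receive
#'     1-3 background PTs;
#'   \item the first drug of every case is suspect; further drugs are
#'     suspect/interacting/concomitant with probabilities 0.5/0.1/0.4;
#'   \item demographics, country, report year (uniform 1981-2020), log-normal
#'     time to onset rounded to days, action taken, death by the maximum
#'     `death_prob` over the case's drugs, then MCAR missingness masks.
#' }
#'
#' @param config A [generator_config()].
#' @return List with elements `db` (a validated `icsr_db`) and
#'   `ground_truth` (tibble `drug_id`, `rr_event`, `n_event_cases`: the
#'   realised number of event cases in which the drug has an analysed role).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_database_impl(config))
}

generate_database_impl <- function(cfg) {
  n <- cfg$n_cases
  cat <- cfg$drug_catalog
  nd <- nrow(cat)

  k <- 1L + stats::rpois(n, cfg$mean_extra_drugs)
  if (any(k > nd)) {
    abort(sprintf(
      "unsatisfiable catalog: a case drew %d drugs but the catalog has %d",
      max(k), nd), class = "icscreen_config_error")
  }

  # drug assignment: vectorise the dominant single-drug stream, loop the rest
  w <- cat$popularity_weight
  drug_idx <- vector("list", n)
  single <- k == 1L
  drug_idx[single] <- as.list(sample.int(nd, sum(single), replace = TRUE,
                                         prob = w))
  multi <- which(!single)
  if (length(multi)) {
    coclass <- stats::runif(length(multi)) < cfg$co_class_prob
    classes <- split(seq_len(nd), cat$class_label)
    class_w <- vapply(classes, function(i) sum(w[i]), numeric(1))
    for (j in seq_along(multi)) {
      i <- multi[j]
      if (coclass[j]) {
        cl <- classes[[sample.int(length(classes), 1L, prob = class_w)]]
        kk <- min(k[i], length(cl))
        drug_idx[[i]] <- if (length(cl) == 1L) cl else
          cl[sample.int(length(cl), kk, prob = w[cl])]
      } else {
        drug_idx[[i]] <- sample.int(nd, k[i], prob = w)
      }
    }
  }
  k <- lengths(drug_idx)          # co-class capping may shrink k
  flat_case <- rep.int(seq_len(n), k)
  flat_drug <- unlist(drug_idx)

  # event occurrence: independent per-drug hazards
  hazard <- pmin(pmax(cfg$p0 * cat$rr_event, 0), 1)
  log_keep <- rowsum(log1p(-hazard[flat_drug]), flat_case)[, 1]
  p_event <- -expm1(log_keep)
  is_event <- stats::runif(n) < p_event

  case_id <- sprintf("C%07d", seq_len(n))

  # reactions
  ev_cases <- which(is_event)
  rx_event <- tibble(
    case_id = case_id[ev_cases],
    pt = sample(cfg$event_pts$pt, length(ev_cases), replace = TRUE,
                prob = cfg$event_pts$weight)
  )
  pheno <- default_phenotype_map()
  rx_pheno <- purrr::imap_dfr(cfg$phenotype_conditional, function(p, cat_name) {
    hit <- ev_cases[stats::runif(length(ev_cases)) < p]
    if (!length(hit)) return(NULL)
    pts <- pheno$pt[pheno$category == cat_name]
    tibble(case_id = case_id[hit],
           pt = sample(pts, length(hit), replace = TRUE))
  })
  bg_cases <- which(!is_event)
  m_bg <- sample.int(3L, length(bg_cases), replace = TRUE)
  rx_bg <- tibble(
    case_id = rep(case_id[bg_cases], m_bg),
    pt = sample(cfg$background_pts$pt, sum(m_bg), replace = TRUE,
                prob = cfg$background_pts$weight)
  )
  reactions <- bind_rows(rx_event, rx_pheno, rx_bg) |>
    distinct(.data$case_id, .data$pt)

  # roles: first slot suspect, the rest 0.5 / 0.1 / 0.4
  first_slot <- !duplicated(flat_case)
  role <- sample(icsr_roles, length(flat_case), replace = TRUE,
                 prob = c(0.5, 0.1, 0.4))
  role[first_slot] <- "suspect"

  tto <- as.integer(round(stats::rlnorm(length(flat_drug),
                                        cat$tto_log_mean[flat_drug],
                                        cat$tto_log_sd[flat_drug])))
  # "unknown" is the missing-data token for action_taken: it only arises
  # from the missingness mask below, never as a base draw
  action <- sample(c("withdrawn", "dose_reduced", "continued"),
                   length(flat_drug), replace = TRUE,
                   prob = c(0.45, 0.12, 0.43))

  drugs <- tibble(
    case_id = case_id[flat_case],
    drug_id = cat$drug_id[flat_drug],
    drug_name = cat$drug_name[flat_drug],
    role = role,
    time_to_onset_days = tto,
    action_taken = action
  )

  # demographics and outcomes
  age <- pmin(pmax(stats::rnorm(n, 43, 23), 0), 100)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.545, 0.455))
  country <- sample(names(cfg$countries), n, replace = TRUE,
                    prob = cfg$countries)
  override <- cat$single_country_override[vapply(drug_idx, `[`, 0L, 1L)]
  forced <- is_event & !is.na(override)
  country[forced] <- override[forced]
  year <- sample(1981:2020, n, replace = TRUE)

  death_p <- vapply(drug_idx, function(i) max(cat$death_prob[i]), numeric(1))
  death <- stats::runif(n) < death_p
  hosp <- stats::runif(n) < ifelse(is_event, 0.25, 0.10)
  lt <- is_event & stats::runif(n) < 0.08
  other <- stats::runif(n) < ifelse(is_event, 0.20, 0.05)
  outcomes <- purrr::pmap(list(death, lt, hosp, other), function(d, l, h, o) {
    icsr_outcomes[c(d, l, h, FALSE, FALSE, o)]
  })

  # MCAR missingness masks
  mp <- cfg$missingness
  miss <- function(field) {
    p <- if (field %in% names(mp)) mp[[field]] else 0
    stats::runif(if (field %in% c("age_years", "sex")) n else nrow(drugs)) < p
  }
  age[miss("age_years")] <- NA_real_
  sex[miss("sex")] <- "unknown"
  drugs$time_to_onset_days[miss("time_to_onset_days")] <- NA_integer_
  drugs$action_taken[miss("action_taken")] <- "unknown"

  reports <- tibble(case_id = case_id, country = country, report_year = year,
                    age_years = age, sex = sex, outcomes = outcomes)

  db <- icsr_db(reports, drugs, reactions,
                provenance = list(generator = "icscreen::generate_database",
                                  seed = cfg$seed, n_cases = n))

  event_ids <- case_id[is_event]
  elig_event <- drugs |>
    filter(.data$role %in% c("suspect", "interacting"),
           .data$case_id %in% event_ids) |>
    distinct(.data$case_id, .data$drug_id) |>
    count(.data$drug_id, name = "n_event_cases")
  ground_truth <- cat |>
    select("drug_id", "rr_event") |>
    left_join(elig_event, by = "drug_id") |>
    mutate(n_event_cases = ifelse(is.na(.data$n_event_cases), 0L,
                                  .data$n_event_cases))

  list(db = db, ground_truth = ground_truth)
}

#' Drug catalog for a planted-signal validation study
#'
#' A catalog of `n_null` null drugs (`rr_event = 1`) of equal popularity plus
#' one planted signal drug at relative reporting rate `rr`. The planted drug
#' is given a smaller popularity weight than the nulls so that it stays a
#' small share of all reports: because the comparator of the
#' disproportionality contrast includes the planted drug's own excess cases,
#' a popular signal drug dilutes its own observed-to-expected ratio below
#' the planted rate.
#'
#' @param n_null Number of null drugs.
#' @param rr Planted relative reporting rate of the signal drug.
#' @param planted_weight Popularity weight of the planted drug relative to a
#'   null drug's weight of 1.3.
#' @return Tibble usable as `drug_catalog` in [generator_config()]; the
#'   planted drug has `drug_id` `"drug_signal"`.
#' @export
planted_signal_catalog <- function(n_null = 40, rr = 8,
                                   planted_weight = 0.85) {
  bind_rows(
    tibble(drug_id = sprintf("drug_null_%02d", seq_len(n_null)),
           class_label = rep(c("oncology", "antiepileptic",
                               "immunosuppressant", "psychiatric"),
                             length.out = n_null),
           popularity_weight = 1.3, rr_event = 1, death_prob = 0.05,
           tto_log_mean = log(13), tto_log_sd = 1.2),
    tibble(drug_id = "drug_signal", class_label = "oncology",
           popularity_weight = planted_weight, rr_event = rr,
           death_prob = 0.05, tto_log_mean = log(13), tto_log_sd = 1.2)
  )
}
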