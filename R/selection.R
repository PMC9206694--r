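#' Define the target adverse event as a set of preferred terms
#'
#' A target event is a named, non-empty set of MedDRA preferred terms (PTs),
#' matched case-insensitively after whitespace normalisation. The packaged
#' default, [hyperammonaemia_event()], is the hyperammonaemia definition
#' (the PTs "hyperammonaemia", "hyperammonaemic encephalopathy" and
#' "hyperammonaemic crisis").
#'
#' @param name Event label.
#' @param pts Non-empty character vector of PT strings.
#' @return An object of class `event_definition`.
#' @export
event_definition <- function(name, pts) {
  pts <- unique(as.character(pts))
  if (!length(pts) || any(!nzchar(stringr::str_squish(pts)))) {
    abort("event definition needs a non-empty set of non-blank PTs",
          class = "icscreen_config_error")
  }
  structure(list(name = as.character(name)[1], pts = pts),
            class = "event_definition")
}

#' @export
print.event_definition <- function(x, ...) {
  cat(sprintf("<event_definition> %s: %s\n", x$name,
              paste(x$pts, collapse = "; ")))
  invisible(x)
}

#' @rdname event_definition
#' @export
hyperammonaemia_event <- function() {
  event_definition("hyperammonaemia",
                   c("Hyperammonaemia",
                     "Hyperammonaemic encephalopathy",
                     "Hyperammonaemic crisis"))
}

#' Exclusion configuration for the drug-selection stages
#'
#' After significance screening, drugs whose event cases were all reported
#' from a single country are excluded (their signal rests on one national
#' reporting culture), and drugs used to treat the event or its causes are
#' excluded as protopathic bias (the drug is given *because of* the
#' condition, so the association is reversed). The packaged default
#' protopathic list for hyperammonaemia contains the five ammonia-lowering
#' therapies lactulose, rifaximin, sodium phenylbutyrate, benzoic acid and
#' carglumic acid. Protopathic matching is by exact normalised drug name.
#'
#' @param protopathic_drugs Character vector of drug names (may be empty).
#' @param single_country_rule Apply the single-country exclusion?
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(protopathic_drugs = protopathic_hyperammonaemia(),
                             single_country_rule = TRUE) {
  structure(list(protopathic_drugs = as.character(protopathic_drugs),
                 single_country_rule = isTRUE(single_country_rule)),
            class = "exclusion_config")
}

#' @rdname exclusion_config
#' @export
protopathic_hyperammonaemia <- function() {
  c("lactulose", "rifaximin", "sodium phenylbutyrate",
    "benzoic acid", "carglumic acid")
}

#' Select the cases reporting the target event
#'
#' A case is selected when at least one of its reaction PTs belongs to the
#' event definition; each case is counted once however many event PTs it
#' carries. Matching is case-insensitive after whitespace normalisation.
#'
#' @param db An `icsr_db`.
#' @param event An [event_definition()].
#' @return Character vector of case identifiers (possibly empty), in
#'   database order.
#' @export
select_cases <- function(db, event) {
  stopifnot(inherits(db, "icsr_db"), inherits(event, "event_definition"))
  hits <- db$reactions$case_id[
    normalise_term(db$reactions$pt) %in% normalise_term(event$pts)]
  db$reports$case_id[db$reports$case_id %in% hits]
}

#' Drug mentions eligible for analysis
#'
#' Only drugs labelled suspect or interacting are analysed; concomitant
#' mentions are never eligible. Duplicate (case, drug) mentions collapse to
#' one row (set semantics).
#'
#' @param drugs The drug table of an `icsr_db` (or any tibble with
#'   `case_id`, `drug_id`, `role`), e.g. a single case's rows.
#' @return Tibble with distinct `case_id`, `drug_id` pairs.
#' @export
eligible_drugs <- function(drugs) {
  if (inherits(drugs, "icsr_db")) drugs <- drugs$drugs
  check_cols(drugs, c("case_id", "drug_id", "role"), "drugs")
  drugs |>
    filter(.data$role %in% c("suspect", "interacting")) |>
    distinct(.data$case_id, .data$drug_id)
}

#' Drugs associated with at least one event case
#'
#' @param db An `icsr_db`.
#' @param event An [event_definition()].
#' @return Tibble with one row per drug having an eligible (suspect or
#'   interacting) mention in at least one event case: `drug_id`,
#'   `n_event_cases` and a list-column `case_ids` of its event cases.
#' @export
drugs_with_event <- function(db, event) {
  event_cases <- select_cases(db, event)
  eligible_drugs(db$drugs) |>
    filter(.data$case_id %in% event_cases) |>
    group_by(.data$drug_id) |>
    summarise(n_event_cases = n(), case_ids = list(.data$case_id),
              .groups = "drop")
}

#' Apply the staged drug-exclusion procedure to a screen
#'
#' Three ordered stages, each tagging a drug with the first applicable
#' reason: `not_significant` (IC025 <= 0), `single_country` (all of the
#' drug's *event* cases share one country value — a drug with exactly one
#' event case is single-country by construction), and `protopathic` (drug
#' name on the configured protopathic list). Drugs with no applicable reason
#' are retained. The output partitions the input: every screened drug
#' appears exactly once, with `exclusion_reason` `NA` when retained.
#'
#' @param screen An `ic_screen` from [screen_drugs()].
#' @param db The `icsr_db` the screen was computed from (for countries).
#' @param config An [exclusion_config()].
#' @return The screen tibble with columns `exclusion_reason` (factor with
#'   levels not_significant, single_country, protopathic; `NA` = retained)
#'   and `retained` (logical) appended.
#' @export
apply_exclusions <- function(screen, db, config = exclusion_config()) {
  stopifnot(inherits(screen, "ic_screen"), inherits(db, "icsr_db"),
            inherits(config, "exclusion_config"))
  country_of <- stats::setNames(db$reports$country, db$reports$case_id)
  single_country <- vapply(screen$case_ids, function(ids) {
    dplyr::n_distinct(country_of[ids]) == 1L
  }, logical(1))
  proto <- normalise_term(screen$drug_name) %in%
    normalise_term(config$protopathic_drugs)

  reason <- rep(NA_character_, nrow(screen))
  reason[!screen$significant] <- "not_significant"
  if (config$single_country_rule) {
    reason[is.na(reason) & single_country] <- "single_country"
  }
  reason[is.na(reason) & proto] <- "protopathic"

  out <- screen
  out$exclusion_reason <- factor(
    reason, levels = c("not_significant", "single_country", "protopathic"))
  out$retained <- is.na(reason)
  out
}

#' Tally of the exclusion stages
#'
#' @param excluded Output of [apply_exclusions()].
#' @return One-row tibble: `screened`, `not_significant`, `single_country`,
#'   `protopathic`, `retained`.
#' @export
exclusion_tally <- function(excluded) {
  check_cols(excluded, c("exclusion_reason", "retained"), "excluded screen")
  tab <- table(excluded$exclusion_reason)
  tibble(
    screened = nrow(excluded),
    not_significant = as.integer(tab[["not_significant"]]),
    single_country = as.integer(tab[["single_country"]]),
    protopathic = as.integer(tab[["protopathic"]]),
    retained = sum(excluded$retained)
  )
}
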