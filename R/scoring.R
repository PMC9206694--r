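#' Default clinical-presentation phenotype map
#'
#' Maps each clinical-presentation category to a set of MedDRA-style
#' preferred terms: the five neurological presentation categories
#' (coma/altered consciousness, brain oedema, seizures, neuropsychiatric,
#' miscellaneous neurological) plus liver- and kidney-dysfunction term sets
#' used to flag underlying organ dysfunction. The default sets are disjoint
#' and fully overridable: the classification logic, not this vocabulary, is
#' the reproducible content, so analyses with a licensed MedDRA dictionary
#' should substitute their own table (`category`, `pt`).
#'
#' @return Tibble with columns `category` and `pt`.
#' @export
default_phenotype_map <- function() {
  m <- list(
    coma_altered_consciousness = c(
      "Coma", "Depressed level of consciousness", "Somnolence", "Lethargy",
      "Stupor", "Altered state of consciousness", "Loss of consciousness"),
    brain_oedema = c("Brain oedema", "Cerebral oedema",
                     "Intracranial pressure increased", "Brain herniation"),
    seizures = c("Seizure", "Generalised tonic-clonic seizure",
                 "Status epilepticus", "Convulsion", "Partial seizures"),
    neuropsychiatric = c("Confusional state", "Agitation", "Hallucination",
                         "Delirium", "Psychotic disorder", "Disorientation",
                         "Irritability"),
    misc_neurological = c("Tremor", "Ataxia", "Dysarthria", "Asterixis",
                          "Gait disturbance", "Myoclonus",
                          "Encephalopathy"),
    liver_dysfunction = c("Hepatic failure", "Acute hepatic failure",
                          "Hepatotoxicity", "Liver injury",
                          "Hepatic encephalopathy", "Transaminases increased",
                          "Hepatic cirrhosis", "Liver function test abnormal"),
    kidney_dysfunction = c("Acute kidney injury", "Renal failure",
                           "Renal impairment", "Blood creatinine increased",
                           "Chronic kidney disease")
  )
  tibble(category = rep(names(m), lengths(m)), pt = unlist(m, use.names = FALSE))
}

#' Case informativity score (NI0-NI2)
#'
#' French-method grading of how documented a (case, drug) pair is: NI2 when
#' both the time to onset and the discontinuation of the drug are described,
#' NI1 when exactly one of the two is present, NI0 when neither is.
#' "Discontinuation described" is operationalised as
#' `action_taken == "withdrawn"`; a dose reduction does not qualify.
#'
#' @param drugs The drug table of an `icsr_db` (or an `icsr_db`), or any
#'   tibble with `time_to_onset_days` and `action_taken`.
#' @return The input tibble with an ordered factor column `ni`
#'   (levels NI0 < NI1 < NI2) appended.
#' @export
informativity <- function(drugs) {
  if (inherits(drugs, "icsr_db")) drugs <- drugs$drugs
  check_cols(drugs, c("time_to_onset_days", "action_taken"), "drugs")
  has_tto <- !is.na(drugs$time_to_onset_days)
  has_stop <- !is.na(drugs$action_taken) & drugs$action_taken == "withdrawn"
  as_tibble(drugs) |>
    mutate(ni = factor(paste0("NI", has_tto + has_stop),
                       levels = c("NI0", "NI1", "NI2"), ordered = TRUE))
}

#' @rdname informativity
#' @param case A single case's rows of the drug table.
#' @param drug_id Drug identifier present in `case`.
#' @return `informativity_for()`: the NI level for one (case, drug) pair.
#' @export
informativity_for <- function(case, drug_id) {
  if (inherits(case, "icsr_db")) case <- case$drugs
  rows <- case[case$drug_id == drug_id, ]
  if (!nrow(rows)) {
    abort(sprintf("drug '%s' not present in case", drug_id),
          class = "icscreen_lookup_error")
  }
  max(informativity(rows)$ni)
}

#' Extrinsic imputability (B1-B4) from prior published evidence
#'
#' French-method grading of the prior evidence linking a drug to the event:
#' B4 when the effect is expected (described in the summary of product
#' characteristics, i.e. on-label), else B3 when widely published in
#' reference databases or books, else B2 when published as case reports or
#' in a database, else B1 when not published. Label knowledge is consumed as
#' a user-supplied frozen table, never scraped; a drug absent from the table
#' has all flags false (B1).
#'
#' @param knowledge Tibble with columns `drug_name`, `in_label`,
#'   `widely_published`, `case_reports_published` (logicals).
#' @return The input tibble with an ordered factor column `imputability`
#'   (levels B1 < B2 < B3 < B4) appended.
#' @export
extrinsic_imputability <- function(knowledge) {
  check_cols(knowledge, c("drug_name", "in_label", "widely_published",
                          "case_reports_published"), "knowledge")
  as_tibble(knowledge) |>
    mutate(imputability = factor(
      dplyr::case_when(
        .data$in_label ~ "B4",
        .data$widely_published ~ "B3",
        .data$case_reports_published ~ "B2",
        TRUE ~ "B1"),
      levels = c("B1", "B2", "B3", "B4"), ordered = TRUE))
}

#' @rdname extrinsic_imputability
#' @param drug_name Single drug name (matched after normalisation).
#' @return `imputability_for()`: the B level for one drug.
#' @export
imputability_for <- function(drug_name, knowledge) {
  hit <- normalise_term(knowledge$drug_name) == normalise_term(drug_name)
  if (!any(hit)) return(factor("B1", levels = c("B1", "B2", "B3", "B4"),
                               ordered = TRUE))
  extrinsic_imputability(knowledge[hit, ][1, ])$imputability
}

#' Classify the clinical presentation of cases
#'
#' Assigns each case every presentation category whose PT set intersects the
#' case's co-reported reaction PTs. PTs belonging to the event definition
#' itself are excluded first, so a case reporting only the target-event PTs
#' has an empty presentation. Matching is normalisation-insensitive.
#'
#' @param db An `icsr_db`.
#' @param map Phenotype map tibble (`category`, `pt`); default
#'   [default_phenotype_map()].
#' @param event Optional [event_definition()] whose PTs are excluded from
#'   classification.
#' @return Tibble with one row per (case, category) assignment: `case_id`,
#'   `category`. Cases with no matching PT are absent.
#' @export
classify_presentation <- function(db, map = default_phenotype_map(),
                                  event = NULL) {
  rx <- if (inherits(db, "icsr_db")) db$reactions else as_tibble(db)
  check_cols(rx, c("case_id", "pt"), "reactions")
  check_cols(map, c("category", "pt"), "phenotype map")
  rx <- mutate(rx, pt_norm = normalise_term(.data$pt))
  if (!is.null(event)) {
    rx <- filter(rx, !(.data$pt_norm %in% normalise_term(event$pts)))
  }
  map_norm <- mutate(as_tibble(map), pt_norm = normalise_term(.data$pt))
  rx |>
    inner_join(select(map_norm, "category", "pt_norm"), by = "pt_norm",
               relationship = "many-to-many") |>
    distinct(.data$case_id, .data$category)
}

#' Seriousness of cases
#'
#' A case is serious when it carries at least one of the six regulatory
#' outcome categories (death, life-threatening, hospitalisation, disabling,
#' congenital anomaly, other medically important condition).
#'
#' @param reports The reports table of an `icsr_db` (or an `icsr_db`).
#' @return The input tibble with a logical column `serious` appended.
#' @export
is_serious <- function(reports) {
  if (inherits(reports, "icsr_db")) reports <- reports$reports
  check_cols(reports, "outcomes", "reports")
  mutate(as_tibble(reports), serious = lengths(.data$outcomes) > 0)
}
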