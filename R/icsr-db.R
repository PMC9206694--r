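#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct left_join inner_join anti_join semi_join bind_rows n count across
#' @importFrom tibble tibble as_tibble
NULL

# Fixed vocabularies of the report model. These are closed sets: parsers
# reject anything outside them rather than coercing.
icsr_roles <- c("suspect", "interacting", "concomitant")
icsr_actions <- c("withdrawn", "dose_reduced", "continued", "unknown")
icsr_sexes <- c("male", "female", "unknown")
icsr_outcomes <- c("death", "life_threatening", "hospitalisation",
                   "disabling", "congenital", "other_important")

#' Normalise a preferred term or drug name for matching
#'
#' MedDRA preferred terms and drug names arrive with inconsistent
#' capitalisation and whitespace across sources; all matching in this package
#' is performed on the lower-cased, whitespace-squished form.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalise_term(c("  Hyperammonaemic   Crisis ", "HYPERAMMONAEMIA"))
normalise_term <- function(x) {
  stringr::str_squish(tolower(x))
}

#' Construct a spontaneous-report database
#'
#' An `icsr_db` is a light relational container for individual case safety
#' reports (ICSRs): a reports table (one row per case), a report-drug table
#' (one row per drug mention) and a report-reaction table (one row per
#' reported preferred term). All analysis functions in the package consume
#' this container.
#'
#' @param reports Tibble with columns `case_id`, `country`, `report_year`,
#'   `age_years`, `sex` (one of `"male"`, `"female"`, `"unknown"`) and
#'   `outcomes` (list-column of character vectors drawn from the six
#'   regulatory seriousness categories; may be empty).
#' @param drugs Tibble with columns `case_id`, `drug_id`, `drug_name`,
#'   `role` (`"suspect"`, `"interacting"` or `"concomitant"`),
#'   `time_to_onset_days` (non-negative integer or `NA`) and `action_taken`
#'   (`"withdrawn"`, `"dose_reduced"`, `"continued"` or `"unknown"`).
#' @param reactions Tibble with columns `case_id` and `pt`.
#' @param provenance Optional list of free-form metadata (generator seed and
#'   configuration, or source file paths).
#' @param validate Run full validation (referential integrity, vocabularies,
#'   ranges). Disable only when the tables are known valid by construction.
#' @return An object of class `icsr_db`.
#' @export
icsr_db <- function(reports, drugs, reactions, provenance = list(),
                    validate = TRUE) {
  db <- structure(
    list(
      reports = canonical_reports(as_tibble(reports)),
      drugs = canonical_drugs(as_tibble(drugs)),
      reactions = canonical_reactions(as_tibble(reactions)),
      provenance = provenance
    ),
    class = "icsr_db"
  )
  if (validate) validate_icsr_db(db)
  db
}

canonical_reports <- function(x) {
  need <- c("case_id", "country", "report_year", "age_years", "sex", "outcomes")
  check_cols(x, need, "reports")
  x$case_id <- as.character(x$case_id)
  x$country <- as.character(x$country)
  x$report_year <- as.integer(x$report_year)
  x$age_years <- as.double(x$age_years)
  x$sex <- as.character(x$sex)
  if (!is.list(x$outcomes)) {
    x$outcomes <- lapply(as.character(x$outcomes), split_outcomes)
  }
  x$outcomes <- lapply(x$outcomes, function(o) {
    o <- as.character(o)
    o[nzchar(o)]
  })
  x[need]
}

canonical_drugs <- function(x) {
  need <- c("case_id", "drug_id", "drug_name", "role",
            "time_to_onset_days", "action_taken")
  check_cols(x, need, "drugs")
  x$case_id <- as.character(x$case_id)
  x$drug_id <- as.character(x$drug_id)
  x$drug_name <- as.character(x$drug_name)
  x$role <- as.character(x$role)
  x$time_to_onset_days <- as.integer(x$time_to_onset_days)
  x$action_taken <- as.character(x$action_taken)
  x[need]
}

canonical_reactions <- function(x) {
  need <- c("case_id", "pt")
  check_cols(x, need, "reactions")
  x$case_id <- as.character(x$case_id)
  x$pt <- as.character(x$pt)
  x[need]
}

check_cols <- function(x, need, what) {
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "icscreen_schema_error")
  }
  invisible(x)
}

split_outcomes <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, "|", fixed = TRUE)[[1]]
}

#' Validate a spontaneous-report database
#'
#' Checks referential integrity (every drug and reaction row attached to an
#' existing case), uniqueness of case identifiers, non-empty drug and
#' reaction sets per case, closed vocabularies for roles, actions, sex and
#' outcome categories, and numeric ranges (age in \[0, 130\], time to onset
#' non-negative). Parsing and validation are total: a database either
#' validates or a typed condition (`icscreen_schema_error` /
#' `icscreen_validation_error`) is signalled; rows are never silently
#' dropped.
#'
#' @param db An `icsr_db`.
#' @return `db`, invisibly.
#' @export
validate_icsr_db <- function(db) {
  r <- db$reports; d <- db$drugs; x <- db$reactions

  dup <- r$case_id[duplicated(r$case_id)]
  if (length(dup)) {
    abort(sprintf("duplicate case_id in reports: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "icscreen_validation_error")
  }
  orphan_d <- setdiff(d$case_id, r$case_id)
  if (length(orphan_d)) {
    abort(sprintf("drug rows reference unknown case_id: %s",
                  paste(utils::head(orphan_d, 5), collapse = ", ")),
          class = "icscreen_schema_error")
  }
  orphan_x <- setdiff(x$case_id, r$case_id)
  if (length(orphan_x)) {
    abort(sprintf("reaction rows reference unknown case_id: %s",
                  paste(utils::head(orphan_x, 5), collapse = ", ")),
          class = "icscreen_schema_error")
  }
  no_drug <- setdiff(r$case_id, d$case_id)
  if (length(no_drug)) {
    abort(sprintf("case(s) without any drug row: %s",
                  paste(utils::head(no_drug, 5), collapse = ", ")),
          class = "icscreen_validation_error")
  }
  no_rx <- setdiff(r$case_id, x$case_id)
  if (length(no_rx)) {
    abort(sprintf("case(s) without any reaction row: %s",
                  paste(utils::head(no_rx, 5), collapse = ", ")),
          class = "icscreen_validation_error")
  }
  check_tokens(d$role, icsr_roles, "role")
  check_tokens(d$action_taken, icsr_actions, "action_taken")
  check_tokens(r$sex, icsr_sexes, "sex")
  bad_out <- setdiff(unique(unlist(r$outcomes)), icsr_outcomes)
  if (length(bad_out)) {
    abort(sprintf("invalid outcome token(s): %s",
                  paste(bad_out, collapse = ", ")),
          class = "icscreen_validation_error")
  }
  if (any(!is.na(r$age_years) & (r$age_years < 0 | r$age_years > 130))) {
    abort("age_years outside [0, 130]", class = "icscreen_validation_error")
  }
  if (any(!is.na(d$time_to_onset_days) & d$time_to_onset_days < 0)) {
    abort("negative time_to_onset_days", class = "icscreen_validation_error")
  }
  invisible(db)
}

check_tokens <- function(x, allowed, field) {
  bad <- which(is.na(x) | !(x %in% allowed))
  if (length(bad)) {
    abort(sprintf("invalid %s token %s at row %d (allowed: %s)",
                  field, if (is.na(x[bad[1]])) "NA" else sprintf("'%s'", x[bad[1]]),
                  bad[1], paste(allowed, collapse = ", ")),
          class = "icscreen_validation_error")
  }
  invisible(x)
}

#' @export
print.icsr_db <- function(x, ...) {
  cat(sprintf("<icsr_db> %d cases, %d drug mentions (%d distinct drugs), %d reaction rows\n",
              nrow(x$reports), nrow(x$drugs),
              dplyr::n_distinct(x$drugs$drug_id), nrow(x$reactions)))
  if (length(x$provenance)) {
    cat("provenance:",
        paste(names(x$provenance),
              vapply(x$provenance, function(p) paste(format(p), collapse = " "),
                     character(1)),
              sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Number of cases in a database
#' @param db An `icsr_db`.
#' @return Integer count of cases (the `Ntotal` of the disproportionality
#'   contrast).
#' @export
n_cases <- function(db) nrow(db$reports)

#' Write a spontaneous-report database to disk
#'
#' Two open dialects are supported. `"csv_relational"` writes three files
#' (`reports.csv`, `report_drugs.csv`, `report_reactions.csv`) into a
#' directory; outcome sets are pipe-separated tokens and missing values are
#' empty fields, never sentinel numbers. `"jsonl"` writes one JSON object per
#' case with nested `drugs` and `reactions` arrays; missing scalar fields are
#' absent keys. Both round-trip losslessly through [read_icsr_db()],
#' including missingness.
#'
#' @param db An `icsr_db`.
#' @param path Directory (csv_relational) or file path (jsonl).
#' @param dialect `"csv_relational"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_icsr_db <- function(db, path, dialect = c("csv_relational", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_relational") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    rep <- db$reports
    rep$outcomes <- vapply(rep$outcomes, paste, character(1), collapse = "|")
    readr::write_csv(rep, file.path(path, "reports.csv"), na = "")
    readr::write_csv(db$drugs, file.path(path, "report_drugs.csv"), na = "")
    readr::write_csv(db$reactions, file.path(path, "report_reactions.csv"),
                     na = "")
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    drugs_by <- split(db$drugs[-1L], db$drugs$case_id)
    rx_by <- split(db$reactions$pt, db$reactions$case_id)
    for (i in seq_len(nrow(db$reports))) {
      r <- db$reports[i, ]
      obj <- list(case_id = r$case_id, country = r$country,
                  report_year = r$report_year)
      if (!is.na(r$age_years)) obj$age_years <- r$age_years
      obj$sex <- r$sex
      obj$outcomes <- r$outcomes[[1]]
      dd <- drugs_by[[r$case_id]]
      obj$drugs <- lapply(seq_len(nrow(dd)), function(j) {
        e <- as.list(dd[j, ])
        if (is.na(e$time_to_onset_days)) e$time_to_onset_days <- NULL
        e
      })
      obj$reactions <- rx_by[[r$case_id]]
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  null = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Read a spontaneous-report database from disk
#'
#' Counterpart of [write_icsr_db()]; see that page for the dialect
#' definitions. The result is fully validated: orphan drug or reaction rows
#' raise a schema error naming the offending `case_id`, and invalid role,
#' action, sex or outcome tokens raise a validation error naming the row.
#'
#' @inheritParams write_icsr_db
#' @return A validated `icsr_db` whose provenance records the source paths.
#' @export
read_icsr_db <- function(path, dialect = c("csv_relational", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv_relational") {
    fr <- file.path(path, "reports.csv")
    fd <- file.path(path, "report_drugs.csv")
    fx <- file.path(path, "report_reactions.csv")
    for (f in c(fr, fd, fx)) {
      if (!file.exists(f)) {
        abort(sprintf("missing file: %s", f), class = "icscreen_io_error")
      }
    }
    rep <- readr::read_csv(fr, col_types = readr::cols(
      case_id = "c", country = "c", report_year = "i",
      age_years = "d", sex = "c", outcomes = "c"), na = "")
    rep$outcomes <- lapply(ifelse(is.na(rep$outcomes), "", rep$outcomes),
                           split_outcomes)
    drg <- readr::read_csv(fd, col_types = readr::cols(
      case_id = "c", drug_id = "c", drug_name = "c", role = "c",
      time_to_onset_days = "i", action_taken = "c"), na = "")
    rx <- readr::read_csv(fx, col_types = readr::cols(case_id = "c", pt = "c"),
                          na = "")
    icsr_db(rep, drg, rx,
            provenance = list(source = normalizePath(path), dialect = dialect))
  } else {
    if (!file.exists(path)) {
      abort(sprintf("missing file: %s", path), class = "icscreen_io_error")
    }
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    rep <- tibble(
      case_id = vapply(objs, function(o) as.character(o$case_id), ""),
      country = vapply(objs, function(o) as.character(o$country), ""),
      report_year = vapply(objs, function(o) as.integer(o$report_year), 1L),
      age_years = vapply(objs, function(o)
        if (is.null(o$age_years)) NA_real_ else as.double(o$age_years), 0),
      sex = vapply(objs, function(o) as.character(o$sex), ""),
      outcomes = lapply(objs, function(o) as.character(o$outcomes %||% character(0)))
    )
    drg <- purrr::map_dfr(objs, function(o) {
      d <- as_tibble(o$drugs)
      d$case_id <- as.character(o$case_id)
      if (!"time_to_onset_days" %in% names(d)) d$time_to_onset_days <- NA_integer_
      d$time_to_onset_days <- as.integer(d$time_to_onset_days)
      d
    })
    rx <- purrr::map_dfr(objs, function(o) {
      tibble(case_id = as.character(o$case_id), pt = as.character(o$reactions))
    })
    icsr_db(rep, drg, rx,
            provenance = list(source = normalizePath(path), dialect = dialect))
  }
}

#' Test two databases for equality
#'
#' Field-by-field comparison treating outcome and reaction collections as
#' sets (order-insensitive) and everything else positionally.
#'
#' @param a,b `icsr_db` objects.
#' @return Logical scalar.
#' @export
icsr_db_equal <- function(a, b) {
  norm <- function(db) {
    r <- db$reports[order(db$reports$case_id), ]
    r$outcomes <- lapply(r$outcomes, sort)
    d <- db$drugs[do.call(order, db$drugs), ]
    x <- db$reactions[do.call(order, db$reactions), ]
    list(r = as.data.frame(r), d = as.data.frame(d), x = as.data.frame(x))
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}
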