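#' @importFrom ggplot2 ggplot aes autoplot geom_point geom_hline geom_col
#'   scale_x_log10 labs facet_wrap coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot a disproportionality screen
#'
#' Scatter of the IC025 signal bound against the number of co-reported
#' cases (log scale), the standard view of a signal screen: drugs above the
#' zero line are statistically associated with the event. When the screen
#' has been through [apply_exclusions()], points are coloured by exclusion
#' reason (retained drugs in their own colour).
#'
#' @param object An `ic_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ic_screen
#' @export
autoplot.ic_screen <- function(object, ...) {
  d <- tidy(object)
  d$status <- if ("exclusion_reason" %in% names(d)) {
    ifelse(is.na(d$exclusion_reason) | d$exclusion_reason == "",
           "retained", as.character(d$exclusion_reason))
  } else {
    ifelse(d$significant, "significant", "not significant")
  }
  ggplot(d, aes(x = .data$n_observed, y = .data$ic025,
                colour = .data$status)) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_point(alpha = 0.8) +
    scale_x_log10() +
    labs(x = "cases co-reporting drug and event (log scale)",
         y = expression(IC[0.25] ~ "(bits)"),
         colour = NULL,
         title = "Disproportionality screen")
}

#' Plot per-drug clinical presentation profiles
#'
#' Horizontal bars of the presentation-category percentages for the most
#' frequently implicated drugs.
#'
#' @param summaries Output of [summarize_drugs()].
#' @param top Number of drugs (by case count) to show.
#' @return A ggplot object.
#' @export
plot_presentation_profile <- function(summaries, top = 15) {
  cats <- c("pct_coma_altered_consciousness", "pct_brain_oedema",
            "pct_seizures", "pct_neuropsychiatric", "pct_misc_neurological")
  cats <- intersect(cats, names(summaries))
  d <- summaries |>
    dplyr::slice_max(.data$n_cases, n = top, with_ties = FALSE) |>
    select("drug_name", "n_cases", dplyr::all_of(cats)) |>
    tidyr::pivot_longer(dplyr::all_of(cats), names_to = "category",
                        values_to = "pct") |>
    mutate(category = sub("^pct_", "", .data$category),
           drug_name = stats::reorder(.data$drug_name, .data$n_cases))
  ggplot(d, aes(x = .data$drug_name, y = .data$pct)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    facet_wrap(~category, nrow = 1) +
    labs(x = NULL, y = "% of the drug's event cases",
         title = "Clinical presentation profile")
}
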