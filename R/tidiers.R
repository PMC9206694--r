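#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a disproportionality screen
#'
#' Returns the screen as a plain tibble (one row per drug, list-column of
#' event cases dropped), with the exclusion reason when the screen has been
#' through [apply_exclusions()].
#'
#' @param x An `ic_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ic_screen
#' @export
tidy.ic_screen <- function(x, ...) {
  out <- as_tibble(x)
  out$case_ids <- NULL
  out
}

#' Glance at a disproportionality screen
#'
#' @param x An `ic_screen`.
#' @param ... Unused.
#' @return One-row tibble: database size (`n_total`), number of
#'   target-event cases (`n_effect`), number of drugs screened and number
#'   significant (IC025 > 0); plus the number retained when exclusions have
#'   been applied.
#' @method glance ic_screen
#' @export
glance.ic_screen <- function(x, ...) {
  out <- tibble(
    n_total = if (nrow(x)) x$n_total[1] else 0L,
    n_effect = if (nrow(x)) x$n_effect[1] else 0L,
    n_drugs = nrow(x),
    n_significant = sum(x$significant)
  )
  if ("retained" %in% names(x)) out$n_retained <- sum(x$retained)
  out
}
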