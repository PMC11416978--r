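#' Tidy a predictive-value result
#'
#' @param x A `hladq_pv` object from [predictive_values()].
#' @param ... Unused.
#' @return A two-column tibble (`term`, `estimate`) in long form.
#' @method tidy hladq_pv
#' @export
tidy.hladq_pv <- function(x, ...) {
  tibble::tibble(
    term = c(
      "prevalence", "sensitivity", "carrier_freq_population",
      "carrier_freq_controls", "npv", "ppv"
    ),
    estimate = c(
      x$prevalence, x$sensitivity, x$carrier_freq_population,
      x$carrier_freq_controls, x$npv, x$ppv
    )
  )
}

#' One-row summary of a predictive-value result
#'
#' @inheritParams tidy.hladq_pv
#' @return A one-row tibble with `npv`, `ppv` and the inputs.
#' @method glance hladq_pv
#' @export
glance.hladq_pv <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Tidy an EPT cohort summary
#'
#' @param x A `hladq_ept_summary` from [aggregate_cohort()].
#' @param ... Unused.
#' @return The per-method summary as a plain tibble.
#' @method tidy hladq_ept_summary
#' @export
tidy.hladq_ept_summary <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row overall summary of an EPT cohort
#'
#' @inheritParams tidy.hladq_ept_summary
#' @return A one-row tibble: total labs (method-participations), labs with
#'   at least one error and the overall error percentage.
#' @method glance hladq_ept_summary
#' @export
glance.hladq_ept_summary <- function(x, ...) {
  tibble::tibble(
    methods_n = nrow(x),
    labs_n = sum(x$labs_n),
    labs_with_error_n = sum(x$labs_with_error_n),
    error_rate = round_half_up(
      100 * sum(x$labs_with_error_n) / sum(x$labs_n), 1
    )
  )
}
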