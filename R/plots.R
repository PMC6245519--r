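#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.sim_ledger <- function(x, among_aid = TRUE, ...) {
  ledger_rates(x, among_aid = among_aid)
}

#' @export
glance.sim_ledger <- function(x, ...) {
  by <- x$by_year
  tibble(
    scenario = x$scenario_kind, mode = x$mode, n = x$n0,
    horizon_years = x$config$policy_horizon_years,
    person_years = sum(by$alive),
    deaths = sum(by$deaths),
    ascvd_events = sum(by$ascvd_events),
    alive_end = by$alive[nrow(by)] - by$deaths[nrow(by)]
  )
}

#' Plot outcome incidence rates from a ledger
#'
#' @param object A `sim_ledger`.
#' @param among_aid Restrict to aid recipients.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_ledger <- function(object, among_aid = TRUE, ...) {
  rates <- ledger_rates(object, among_aid = among_aid)
  ggplot2::ggplot(rates, ggplot2::aes(
    x = stats::reorder(.data$outcome, .data$rate), y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Incidence per 1,000 person-years",
      title = sprintf("Scenario '%s'", object$scenario_kind)
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of scenario contrasts
#'
#' @param object An `aid_comparison` from [run_comparison_suite()].
#' @param table Which table to plot (`"outcomes"`, `"biomarkers"`,
#'   `"consumption"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aid_comparison <- function(object, table = "outcomes", ...) {
  df <- filter(as_tibble(object), .data$table == !!table)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate, y = .data$quantity, colour = .data$scenario))
  if (all(c("conf_low", "conf_high") %in% names(df))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5))
  }
  p +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Change vs traditional parcel", y = NULL, colour = "Scenario",
      title = sprintf("Scenario contrasts: %s", table)
    ) +
    ggplot2::theme_minimal()
}

#' Plot household intake distributions by arm
#'
#' @param consumption Output of [generate_household_consumption()] (one or
#'   more arms row-bound together).
#' @return A ggplot of per-group kcal distributions.
#' @export
plot_household_intake <- function(consumption) {
  long <- tidyr::pivot_longer(consumption, dplyr::all_of(food_groups()),
                              names_to = "group", values_to = "kcal")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kcal, fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "kcal/person/day", y = NULL, fill = "Aid arm") +
    ggplot2::theme_minimal()
}
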