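#' Stacked electron-yield plot per condition
#'
#' Electron yields of each product as stacked bars per condition, the
#' balancing view of where the consumed substrate electrons went; bars above
#' 100% indicate extra electron sources.
#'
#' @param experiment a `ferm_experiment` from [analyze_experiment()].
#' @return a ggplot.
#' @export
plot_yields <- function(experiment) {
  yields <- purrr::map_dfr(experiment$results, function(r) {
    mutate(r$yields, condition_label = r$spec$condition_label)
  }) %>%
    group_by(.data$condition_label, .data$compound) %>%
    summarise(yield_pct = mean(.data$yield_pct), .groups = "drop")
  ggplot2::ggplot(yields, ggplot2::aes(
    x = .data$condition_label, y = .data$yield_pct, fill = .data$compound
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "electron yield [%]", fill = "product") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Consumption/formation rate plot
#'
#' Replicate-mean electron-mole space-time rates per compound and condition
#' with the negative-consumption sign convention; error bars are replicate
#' standard deviations.
#'
#' @param experiment a `ferm_experiment`.
#' @param compounds compounds to show (default: all).
#' @return a ggplot.
#' @export
plot_rates <- function(experiment, compounds = NULL) {
  summ <- summarize_experiment(experiment)
  if (!is.null(compounds)) {
    summ <- filter(summ, .data$compound %in% compounds)
  }
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$condition_label, y = .data$q_emol_mean, fill = .data$compound
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q_emol_mean - .data$q_emol_sd,
                   ymax = .data$q_emol_mean + .data$q_emol_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "rate [e-mM/d] (negative = consumption)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Control-normalised turnover plot
#'
#' Cumulative electron turnover of each condition relative to the
#' zero-acetate control of its pH/temperature stratum; sign changes against
#' the control mark metabolic switches between production and consumption.
#'
#' @param experiment a `ferm_experiment`.
#' @param ... passed to [normalize_experiment()].
#' @return a ggplot.
#' @export
plot_normalized <- function(experiment, ...) {
  norm <- normalize_experiment(experiment, ...)
  ggplot2::ggplot(norm, ggplot2::aes(
    x = factor(.data$acetate_gL), y = .data$ratio, colour = .data$compound,
    group = .data$compound
  )) +
    ggplot2::geom_hline(yintercept = c(-1, 0, 1), linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(pH ~ temp_C,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "supplemented acetate [g/L]",
                  y = "cumulative e-mol / |control|", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ferm_balance <- function(object, ...) {
  flows <- object$flows
  ggplot2::ggplot(flows, ggplot2::aes(
    x = stats::reorder(.data$compound, .data$q_emol), y = .data$q_emol,
    fill = .data$role
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = object$spec$condition_label,
      x = NULL, y = "rate [e-mM/d] (negative = consumption)", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ferm_experiment <- function(object, ...) {
  plot_rates(object, ...)
}

#' Result tables and figures for an experiment
#'
#' Bundles the per-condition rate summary, the per-bottle yields and
#' recoveries, the control-normalised table and the three standard figures.
#' All tables are plain tibbles and round-trippable through CSV.
#'
#' @param experiment a `ferm_experiment`.
#' @return list with `rates`, `bottles`, `normalized` tibbles and a `plots`
#'   list of ggplots.
#' @export
report_experiment <- function(experiment) {
  list(
    rates = summarize_experiment(experiment),
    bottles = experiment$bottles,
    normalized = normalize_experiment(experiment),
    plots = list(
      yields = plot_yields(experiment),
      rates = plot_rates(experiment),
      normalized = plot_normalized(experiment)
    )
  )
}
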