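#' Plot mean maximum TSS against prevalence
#'
#' One panel per discrimination scenario, one line per sample size, with the
#' theoretical optimum TSS as a dashed reference. At small N the lines bend
#' upward at extreme prevalence (the U shape); they flatten onto the reference
#' as N grows.
#'
#' @param object A `tss_experiment` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tss_experiment <- function(object, ...) {
  optima <- theoretical_optima(unique(object$scenario))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$prevalence, y = .data$mean_max_tss,
                               colour = factor(.data$n_total),
                               group = .data$n_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = optima,
                        ggplot2::aes(yintercept = .data$tss_star),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(x = "prevalence", y = "mean maximum TSS",
                  colour = "sample size N") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the conditional densities and expected TSS of a scenario
#'
#' `plot_scenario_densities()` draws the presence and absence prediction
#' densities f1 and f0; their crossing is the theoretically optimal cutoff.
#' `plot_expected_tss()` draws E(TSS) = F0(xc) - F1(xc) across cutoffs for one
#' or more scenarios, marking each maximum.
#'
#' @param scenario A scenario name or [model_scenario()] object.
#' @param scenarios Character vector of scenario names.
#' @param n_points Curve resolution.
#' @return A ggplot object.
#' @export
plot_scenario_densities <- function(scenario, n_points = 401) {
  scenario <- model_scenario(scenario)
  x <- seq(0, 1, length.out = n_points)
  dens <- c(scenario_density(scenario, x, "presence"),
            scenario_density(scenario, x, "absence"))
  df <- tibble(
    x = rep(x, 2),
    density = dens,
    condition = rep(c("presence (f1)", "absence (f0)"), each = n_points)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = scenario$name, x = "predicted probability",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scenario_densities
#' @export
plot_expected_tss <- function(scenarios = model_scenarios()$name,
                              n_points = 401) {
  x <- seq(0, 1, length.out = n_points)
  df <- purrr::map_dfr(scenarios, function(nm) {
    tibble(scenario = nm, cutoff = x, expected_tss = expected_tss(nm, x))
  })
  optima <- theoretical_optima(scenarios)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$expected_tss,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = optima,
                        ggplot2::aes(x = .data$cutoff_star,
                                     y = .data$tss_star)) +
    ggplot2::labs(x = "cutoff", y = "expected TSS") +
    ggplot2::theme_minimal()
}
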