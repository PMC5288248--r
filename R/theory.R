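#' Expected TSS at a fixed cutoff
#'
#' For continuous predictions the expected sensitivity and specificity at a
#' cutoff xc are 1 - F1(xc) and F0(xc), where F1 and F0 are the conditional
#' CDFs of predicted probabilities given presence and absence. Hence
#' E(TSS) = F0(xc) - F1(xc).
#'
#' @param scenario A scenario name or [model_scenario()] object.
#' @param cutoff Cutoff value(s) in \[0, 1\]; vectorized.
#' @return Numeric vector of expected TSS values.
#' @examples
#' expected_tss("linear", 0.5)
#' @export
expected_tss <- function(scenario, cutoff) {
  if (anyNA(cutoff) || any(cutoff < 0 | cutoff > 1)) {
    abort("`cutoff` must lie in [0, 1].", class = "tssbias_error_input")
  }
  scenario_cdf(scenario, cutoff, "absence") -
    scenario_cdf(scenario, cutoff, "presence")
}

#' Theoretical optimum cutoff and TSS
#'
#' E(TSS) = F0(xc) - F1(xc) is maximal where its derivative vanishes, i.e.
#' where the conditional densities cross: f0(xc) = f1(xc). The crossing is
#' located by bracketed root-finding on f0 - f1 over (0, 1); for the shipped
#' mirror-symmetric scenarios the root is 0.5 analytically, but the solver
#' path is kept for generality.
#'
#' @param scenario A scenario name or [model_scenario()] object.
#' @param tol Root-finding tolerance on the cutoff.
#' @return A one-row tibble with columns `scenario`, `cutoff_star`,
#'   `tss_star`.
#' @examples
#' theoretical_optimum("quadratic")  # cutoff 0.5, TSS 0.75
#' @export
theoretical_optimum <- function(scenario, tol = 1e-9) {
  scenario <- model_scenario(scenario)
  gap <- function(x) {
    scenario_density(scenario, x, "absence") -
      scenario_density(scenario, x, "presence")
  }
  lo <- 1e-6
  hi <- 1 - 1e-6
  if (sign(gap(lo)) == sign(gap(hi))) {
    abort("No density crossing inside (0, 1) for this scenario.",
          class = "tssbias_error_degenerate")
  }
  root <- uniroot(gap, c(lo, hi), tol = tol)$root
  tibble(
    scenario = scenario$name,
    cutoff_star = root,
    tss_star = expected_tss(scenario, root)
  )
}

#' @rdname theoretical_optimum
#' @param scenarios Character vector of scenario names.
#' @return `theoretical_optima()` returns one row per scenario.
#' @export
theoretical_optima <- function(scenarios = model_scenarios()$name,
                               tol = 1e-9) {
  purrr::map_dfr(scenarios, theoretical_optimum, tol = tol)
}

#' Bias of the mean maximum TSS against the theoretical optimum
#'
#' Because the cutoff is chosen from the data, the mean of TSS maxima is a
#' positively biased estimate of the theoretical TSS. This joins a simulation
#' result to the theoretical optima and reports the bias per cell, carrying
#' the Monte Carlo standard error forward so downstream checks can be stated
#' in SE units.
#'
#' @param result A `tss_experiment` tibble from [run_experiment()].
#' @return A tibble with the experiment columns plus `tss_star`, `bias`
#'   (= mean_max_tss - tss_star) and `se_max_tss`.
#' @export
bias_table <- function(result) {
  if (!is.data.frame(result) ||
      !all(c("scenario", "n_total", "prevalence", "mean_max_tss")
           %in% names(result))) {
    abort("`result` must be a tss_experiment-style table.",
          class = "tssbias_error_input")
  }
  known <- model_scenarios()$name
  bad <- setdiff(unique(result$scenario), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown scenario name(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "tssbias_error_input")
  }
  optima <- theoretical_optima(intersect(known, unique(result$scenario)))
  result |>
    dplyr::left_join(optima[, c("scenario", "tss_star")], by = "scenario") |>
    dplyr::mutate(bias = .data$mean_max_tss - .data$tss_star) |>
    as_tibble()
}
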