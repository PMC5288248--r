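#' Discrimination-quality scenarios
#'
#' The four model-quality scenarios used throughout the simulation study.
#' Predicted probabilities for presences are drawn from a beta density f1 with
#' parameters (alpha1, beta1), and for absences from f0 with (alpha0, beta0).
#' The parameter sets are mirror images (f0(x) = f1(1 - x)), and the steepness
#' of f1 encodes discrimination power:
#'
#' | name          | f1           | interpretation                 |
#' |---------------|--------------|--------------------------------|
#' | `quadratic`   | beta(3, 1)   | good discrimination            |
#' | `linear`      | beta(2, 1)   | medium discrimination          |
#' | `square_root` | beta(1.5, 1) | weak discrimination            |
#' | `p16`         | beta(17/16, 1) | extremely weak discrimination |
#'
#' @return `model_scenarios()` returns a tibble with one row per scenario and
#'   columns `name`, `alpha1`, `beta1`, `alpha0`, `beta0`.
#' @seealso [sample_labeled_predictions()], [theoretical_optimum()]
#' @export
model_scenarios <- function() {
  tibble(
    name   = c("quadratic", "linear", "square_root", "p16"),
    alpha1 = c(3, 2, 1.5, 17 / 16),
    beta1  = c(1, 1, 1, 1),
    alpha0 = c(1, 1, 1, 1),
    beta0  = c(3, 2, 1.5, 17 / 16)
  )
}

#' @rdname model_scenarios
#' @param name One of `"quadratic"`, `"linear"`, `"square_root"`, `"p16"`, or
#'   an existing `model_scenario` object (returned unchanged).
#' @return `model_scenario()` returns an object of class `model_scenario`:
#'   a list with the scenario name and its four beta parameters.
#' @examples
#' model_scenario("linear")
#' @export
model_scenario <- function(name) {
  if (inherits(name, "model_scenario")) return(name)
  tab <- model_scenarios()
  if (!is.character(name) || length(name) != 1L || !name %in% tab$name) {
    abort(sprintf("Unknown scenario; expected one of %s.",
                  paste0('"', tab$name, '"', collapse = ", ")),
          class = "tssbias_error_input")
  }
  row <- tab[tab$name == name, ]
  structure(as.list(row), class = "model_scenario")
}

#' @export
print.model_scenario <- function(x, ...) {
  cat(sprintf(
    "Model scenario \"%s\": f1 = beta(%.4g, %.4g), f0 = beta(%.4g, %.4g)\n",
    x$name, x$alpha1, x$beta1, x$alpha0, x$beta0))
  invisible(x)
}

scenario_params <- function(scenario, cond = c("presence", "absence")) {
  scenario <- model_scenario(scenario)
  cond <- match.arg(cond)
  if (cond == "presence") c(scenario$alpha1, scenario$beta1)
  else c(scenario$alpha0, scenario$beta0)
}

#' Conditional densities, distribution functions and quantiles
#'
#' The beta density f (and CDF F, quantile Q) of predicted probabilities
#' conditional on the true class: `cond = "presence"` uses the scenario's
#' (alpha1, beta1), `cond = "absence"` its (alpha0, beta0). Values outside
#' \[0, 1\] have zero density.
#'
#' @param scenario A scenario name or [model_scenario()] object.
#' @param x Probabilities at which to evaluate (density/CDF).
#' @param u Quantile levels in \[0, 1\].
#' @param cond `"presence"` or `"absence"`.
#' @return Numeric vector.
#' @examples
#' scenario_density("linear", 0.5, "presence")  # 2 * 0.5
#' scenario_cdf("quadratic", 0.5, "absence")    # 1 - (1 - 0.5)^3
#' @export
scenario_density <- function(scenario, x, cond = c("presence", "absence")) {
  pars <- scenario_params(scenario, cond)
  out <- numeric(length(x))
  inside <- x >= 0 & x <= 1
  out[inside] <- dbeta(x[inside], pars[1], pars[2])
  out
}

#' @rdname scenario_density
#' @export
scenario_cdf <- function(scenario, x, cond = c("presence", "absence")) {
  pars <- scenario_params(scenario, cond)
  pbeta(x, pars[1], pars[2])
}

#' @rdname scenario_density
#' @export
scenario_quantile <- function(scenario, u, cond = c("presence", "absence")) {
  if (anyNA(u) || any(u < 0 | u > 1)) {
    abort("`u` must lie in [0, 1].", class = "tssbias_error_input")
  }
  pars <- scenario_params(scenario, cond)
  beta_quantile(u, pars[1], pars[2])
}

# inverse CDF with closed forms when one shape parameter is 1 (all shipped
# scenarios), so sampling is reproducible from the uniform stream alone
beta_quantile <- function(u, alpha, beta) {
  if (beta == 1) {
    u^(1 / alpha)
  } else if (alpha == 1) {
    1 - (1 - u)^(1 / beta)
  } else {
    qbeta(u, alpha, beta)
  }
}

#' Number of presences allocated at a target prevalence
#'
#' P = round(prevalence * n_total), clamped to \[1, n_total - 1\] so that both
#' classes always exist. On the study grid (prevalence 0.05..0.95 with N in
#' 100/1000/10000) the product is integral and clamping never triggers.
#'
#' @param n_total Total number of observations (>= 2).
#' @param prevalence Target prevalence in (0, 1).
#' @return Integer count of presences.
#' @examples
#' allocate_presences(100, 0.05)
#' @export
allocate_presences <- function(n_total, prevalence) {
  if (length(n_total) != 1L || is.na(n_total) || n_total < 2) {
    abort("`n_total` must be a single count >= 2.",
          class = "tssbias_error_input")
  }
  check_prev_vec(prevalence)
  p <- round(prevalence * n_total)
  as.integer(min(max(p, 1), n_total - 1))
}

#' Simulate one labeled prediction set
#'
#' Draws a dataset of binary truth labels and continuous predicted
#' probabilities: `allocate_presences(n_total, prevalence)` observations get
#' label 1 with probabilities i.i.d. from the scenario's presence density f1,
#' the rest get label 0 with probabilities from f0. Sampling is by inversion
#' of the conditional CDFs, so a fixed seed reproduces the dataset exactly.
#'
#' @param scenario A scenario name or [model_scenario()] object.
#' @param n_total Total number of observations (>= 2).
#' @param prevalence Target prevalence in (0, 1).
#' @param seed Optional integer; when supplied the draw is reproducible.
#' @return A tibble with columns `label` (integer 0/1) and `prob`, carrying
#'   the scenario name, `n_total`, `prevalence` and `seed` as attributes.
#' @examples
#' d <- sample_labeled_predictions("quadratic", 100, 0.5, seed = 1)
#' table(d$label)
#' @export
sample_labeled_predictions <- function(scenario, n_total, prevalence,
                                       seed = NULL) {
  scenario <- model_scenario(scenario)
  n_pres <- allocate_presences(n_total, prevalence)
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_scenario_probs(scenario, n_pres, n_total - n_pres)
  out <- tibble(
    label = c(rep(1L, n_pres), rep(0L, n_total - n_pres)),
    prob  = c(draws$presence, draws$absence)
  )
  attr(out, "scenario") <- scenario$name
  attr(out, "n_total") <- as.integer(n_total)
  attr(out, "prevalence") <- prevalence
  attr(out, "seed") <- seed
  out
}

# vector-level sampler shared with the experiment loop (no tibble overhead)
draw_scenario_probs <- function(scenario, n_pres, n_abs) {
  list(
    presence = beta_quantile(runif(n_pres), scenario$alpha1, scenario$beta1),
    absence  = beta_quantile(runif(n_abs), scenario$alpha0, scenario$beta0)
  )
}
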