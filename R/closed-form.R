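#' Observation-error scenarios for binary predictions
#'
#' Describes one mechanism by which observed presence/absence can deviate from
#' habitat suitability even when the model itself is perfect:
#'
#' * `"two_error"` — the model errs at fixed false-negative rate `e1` and
#'   false-positive rate `e2`; observations coincide with suitability.
#' * `"missed_presence"` — the species occupies every suitable site but a
#'   fraction `e` of presences goes undetected.
#' * `"fallacious_absence"` — a fraction of suitable sites is unoccupied
#'   (e.g. metapopulation vacancy); algebraically identical to missed
#'   presences.
#' * `"fallacious_presence_prop_presences"` — a proportion of presences is
#'   fallacious (sink populations), equivalent to `two_error` with `e2 = 0`.
#' * `"fallacious_presence_prop_unsuitable"` — fallacious presences arise in
#'   proportion to the number of unsuitable sites.
#'
#' @param kind One of the five mechanism names above.
#' @param prevalence Prevalence of observed presences, strictly inside (0, 1).
#' @param e Single error rate in \[0, 1) (all kinds except `two_error`).
#' @param e1,e2 False-negative and false-positive rates in \[0, 1)
#'   (`two_error` only).
#' @return An object of class `error_scenario`.
#' @seealso [scenario_confusion()], [tss_two_error()], [tss_missed_presence()]
#' @export
error_scenario <- function(kind = c("two_error", "missed_presence",
                                    "fallacious_absence",
                                    "fallacious_presence_prop_presences",
                                    "fallacious_presence_prop_unsuitable"),
                           prevalence, e = NULL, e1 = NULL, e2 = NULL) {
  kind <- match.arg(kind)
  check_rate <- function(x, name, lo_open = FALSE, hi_closed = FALSE) {
    lo_ok <- if (lo_open) x > 0 else x >= 0
    hi_ok <- if (hi_closed) x <= 1 else x < 1
    if (length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
      abort(sprintf("`%s` must be a single rate in %s.", name,
                    if (lo_open) "(0, 1)" else "[0, 1)"),
            class = "tssbias_error_input")
    }
  }
  check_rate(prevalence, "prevalence", lo_open = TRUE)
  if (kind == "two_error") {
    e1 <- e1 %||% 0
    e2 <- e2 %||% 0
    check_rate(e1, "e1")
    check_rate(e2, "e2")
    e <- NULL
  } else {
    if (is.null(e)) {
      abort("`e` is required for this scenario kind.",
            class = "tssbias_error_input")
    }
    check_rate(e, "e")
    e1 <- e2 <- NULL
  }
  if (kind %in% c("missed_presence", "fallacious_absence") &&
      prevalence > 1 - e) {
    abort("Requires prevalence <= 1 - e, otherwise S = P/(1-e) exceeds N.",
          class = "tssbias_error_input")
  }
  if (kind == "fallacious_presence_prop_unsuitable" && prevalence <= e) {
    abort("Requires prevalence > e, otherwise TP would be negative.",
          class = "tssbias_error_input")
  }
  structure(list(kind = kind, prevalence = prevalence, e = e, e1 = e1, e2 = e2),
            class = "error_scenario")
}

#' Expected confusion matrix under an observation-error scenario
#'
#' Fills the 2x2 expected-value table for a given total sample size, with
#' P = prevalence * N presences. Cells are algebraic (real-valued), never
#' rounded. The cells per mechanism, with S the number of positive
#' predictions:
#'
#' * `two_error`: TP = (1-e1)P, FN = e1*P, FP = e2(N-P), TN = (1-e2)(N-P).
#' * `missed_presence` / `fallacious_absence`: S = P/(1-e); TP = P, FN = 0,
#'   FP = eS, TN = N - S.
#' * `fallacious_presence_prop_presences`: `two_error` with e1 = e, e2 = 0.
#' * `fallacious_presence_prop_unsuitable`: S solves the self-consistency
#'   identity TP = P - e(N - S) = S, giving S = (P - eN)/(1 - e); TP = S,
#'   FN = e(N - S), FP = 0, TN = N - P.
#'
#' @param scenario An [error_scenario()].
#' @param n_total Total number of observations N (>= 1).
#' @return A real-mode [confusion_matrix()].
#' @examples
#' sc <- error_scenario("missed_presence", prevalence = 0.5, e = 0.2)
#' scenario_confusion(sc, n_total = 1000)
#' @export
scenario_confusion <- function(scenario, n_total) {
  stopifnot(inherits(scenario, "error_scenario"))
  if (length(n_total) != 1L || is.na(n_total) || n_total < 1) {
    abort("`n_total` must be a single count >= 1.",
          class = "tssbias_error_input")
  }
  n <- n_total
  p <- scenario$prevalence * n
  cells <- switch(
    scenario$kind,
    two_error = {
      list(tp = (1 - scenario$e1) * p, fn = scenario$e1 * p,
           fp = scenario$e2 * (n - p), tn = (1 - scenario$e2) * (n - p))
    },
    missed_presence = ,
    fallacious_absence = {
      s <- p / (1 - scenario$e)
      list(tp = p, fn = 0, fp = scenario$e * s, tn = n - s)
    },
    fallacious_presence_prop_presences = {
      list(tp = (1 - scenario$e) * p, fn = scenario$e * p,
           fp = 0, tn = n - p)
    },
    fallacious_presence_prop_unsuitable = {
      s <- (p - scenario$e * n) / (1 - scenario$e)
      list(tp = s, fn = scenario$e * (n - s), fp = 0, tn = n - p)
    }
  )
  confusion_matrix(tp = cells$tp, fp = cells$fp, fn = cells$fn, tn = cells$tn,
                   mode = "real")
}

#' Closed-form TSS when both error rates are fixed
#'
#' With a fixed false-negative rate `e1` and false-positive rate `e2`,
#' TSS = 1 - e1 - e2: prevalence cancels entirely, so binary-prediction TSS is
#' prevalence independent in this (idealized) case.
#'
#' @param e1,e2 Error rates in \[0, 1); vectorized with recycling.
#' @return Numeric vector of TSS scores.
#' @examples
#' tss_two_error(0.2, 0.2)
#' @export
tss_two_error <- function(e1, e2) {
  check_rates_vec(e1, "e1")
  check_rates_vec(e2, "e2")
  1 - e1 - e2
}

#' Closed-form TSS under missed presences
#'
#' A constant fraction `e` of true presences goes undetected while the model
#' itself is perfect. Then TPR = 1 and
#' TSS = (1 - e - pi) / ((1 - pi)(1 - e)), which depends on prevalence pi even
#' though the detection error rate is prevalence free: rarer species are
#' penalized less, common species more.
#'
#' @param e Rate of missed presences in \[0, 1); vectorized with recycling.
#' @param prevalence Prevalence in (0, 1), with prevalence <= 1 - e.
#' @return Numeric vector of TSS scores.
#' @examples
#' tss_missed_presence(e = 0.2, prevalence = 0.5)
#' @export
tss_missed_presence <- function(e, prevalence) {
  check_rates_vec(e, "e")
  check_prev_vec(prevalence)
  if (any(prevalence > 1 - e)) {
    abort("Requires prevalence <= 1 - e (so that S = P/(1-e) <= N).",
          class = "tssbias_error_input")
  }
  (1 - e - prevalence) / ((1 - prevalence) * (1 - e))
}

#' Closed-form TSS under fallacious absences
#'
#' Suitable-but-unoccupied sites recorded as absences, at a rate proportional
#' to the number of suitable sites. Mathematically identical to
#' [tss_missed_presence()].
#'
#' @inheritParams tss_missed_presence
#' @return Numeric vector of TSS scores.
#' @export
tss_fallacious_absence <- function(e, prevalence) {
  tss_missed_presence(e, prevalence)
}

#' Closed-form TSS under fallacious presences proportional to unsuitable sites
#'
#' The species occurs at unsuitable sites (e.g. sinks) in numbers proportional
#' to the count of unsuitable sites. Two variants are exposed because the
#' published formula disagrees with the table it is derived from:
#'
#' * `"table_consistent"` (default): the number of positive predictions S is
#'   obtained by solving the table's own identity TP = P - e(N - S) = S, which
#'   gives S = (P - eN)/(1 - e) and TSS = (pi - e) / (pi (1 - e)). This is the
#'   variant whose cells balance the row and column margins, and the one
#'   [scenario_confusion()] reproduces.
#' * `"printed"`: the shortcut as printed, S = (P - eN)/(1 + e), yielding
#'   TSS = (pi - e) / (pi (1 + e)).
#'
#' @param e Rate of fallacious presences in \[0, 1); vectorized.
#' @param prevalence Prevalence in (0, 1), strictly greater than `e`.
#' @param variant `"table_consistent"` or `"printed"`.
#' @return Numeric vector of TSS scores.
#' @examples
#' tss_fallacious_presence(e = 0.1, prevalence = 0.5)
#' tss_fallacious_presence(e = 0.1, prevalence = 0.5, variant = "printed")
#' @export
tss_fallacious_presence <- function(e, prevalence,
                                    variant = c("table_consistent", "printed")) {
  variant <- match.arg(variant)
  check_rates_vec(e, "e")
  check_prev_vec(prevalence)
  if (any(prevalence <= e)) {
    abort("Requires prevalence > e, otherwise TP would be negative.",
          class = "tssbias_error_input")
  }
  denom <- if (variant == "printed") 1 + e else 1 - e
  (prevalence - e) / (prevalence * denom)
}

#' Tabulate closed-form TSS over an (error rate, prevalence) grid
#'
#' Convenience wrapper crossing scenario kinds with error rates and prevalence
#' values; rows whose (e, prevalence) combination is outside a kind's valid
#' domain are dropped. For `two_error` the single rate is applied to both
#' error types (e1 = e2 = e). For `fallacious_presence_prop_unsuitable` both
#' formula variants are reported side by side.
#'
#' @param kinds Character vector of [error_scenario()] kinds.
#' @param e Numeric vector of error rates in \[0, 1).
#' @param prevalence Numeric vector of prevalences in (0, 1).
#' @return A tibble with columns `kind`, `e`, `prevalence`, `variant`, `tss`.
#' @examples
#' closed_form_table(e = c(0.1, 0.2), prevalence = c(0.25, 0.5, 0.75))
#' @export
closed_form_table <- function(kinds = c("two_error", "missed_presence",
                                        "fallacious_absence",
                                        "fallacious_presence_prop_presences",
                                        "fallacious_presence_prop_unsuitable"),
                              e, prevalence) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  grid <- tidyr::crossing(kind = kinds, e = e, prevalence = prevalence)
  rows <- purrr::pmap(grid, function(kind, e, prevalence) {
    val <- switch(
      kind,
      two_error = tss_two_error(e, e),
      missed_presence = if (prevalence <= 1 - e)
        tss_missed_presence(e, prevalence) else NA_real_,
      fallacious_absence = if (prevalence <= 1 - e)
        tss_fallacious_absence(e, prevalence) else NA_real_,
      fallacious_presence_prop_presences = tss_two_error(e, 0),
      fallacious_presence_prop_unsuitable = if (prevalence > e) c(
        table_consistent = tss_fallacious_presence(e, prevalence),
        printed = tss_fallacious_presence(e, prevalence, variant = "printed")
      ) else NA_real_
    )
    if (length(val) == 2L) {
      tibble(kind = kind, e = e, prevalence = prevalence,
             variant = names(val), tss = unname(val))
    } else {
      tibble(kind = kind, e = e, prevalence = prevalence,
             variant = "closed_form", tss = val)
    }
  })
  dplyr::filter(dplyr::bind_rows(rows), !is.na(.data$tss))
}

check_rates_vec <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x >= 1)) {
    abort(sprintf("`%s` must lie in [0, 1).", name),
          class = "tssbias_error_input")
  }
}

check_prev_vec <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0 | x >= 1)) {
    abort("`prevalence` must lie strictly inside (0, 1).",
          class = "tssbias_error_input")
  }
}
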