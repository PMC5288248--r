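#' Cutoff grid for threshold-based metrics
#'
#' The default grid is the 19 values 0.05, 0.10, ..., 0.95, evenly spaced
#' along the probability spectrum; values must be strictly increasing and
#' strictly inside (0, 1).
#'
#' @param values Numeric vector of cutoffs.
#' @return The validated cutoff vector.
#' @export
cutoff_grid <- function(values = seq(0.05, 0.95, by = 0.05)) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(values <= 0 | values >= 1) || is.unsorted(values, strictly = TRUE)) {
    abort("Cutoffs must be strictly increasing values inside (0, 1).",
          class = "tssbias_error_input")
  }
  values
}

#' TSS across a grid of cutoffs
#'
#' Binarizes the predicted probabilities at each cutoff (presence iff
#' prob > cutoff) and computes TSS from the resulting confusion matrix. Since
#' TPR and TNR condition on the observed labels, the curve stays defined even
#' at cutoffs where one predicted class vanishes.
#'
#' @param data A data frame with columns `label` (0/1 truth) and `prob`
#'   (predicted probability), e.g. from [sample_labeled_predictions()].
#' @param cutoffs Cutoff vector, default [cutoff_grid()].
#' @return A tibble with columns `cutoff` and `tss`.
#' @examples
#' d <- tibble::tibble(label = c(1, 1, 0, 0), prob = c(0.9, 0.8, 0.2, 0.1))
#' tss_curve(d)
#' @export
tss_curve <- function(data, cutoffs = cutoff_grid()) {
  parts <- split_classes(data)
  cutoffs <- cutoff_grid(cutoffs)
  tibble(
    cutoff = cutoffs,
    tss = vapply(cutoffs,
                 function(ct) mean(parts$p1 > ct) + mean(parts$p0 <= ct) - 1,
                 numeric(1))
  )
}

#' Maximum TSS over a cutoff grid
#'
#' The data-driven cutoff selection in widespread use: evaluate TSS at every
#' grid cutoff and keep the largest. Ties are broken toward the smallest
#' cutoff so the result is deterministic.
#'
#' @inheritParams tss_curve
#' @return A one-row tibble with columns `max_tss` and `cutoff` (the argmax).
#' @examples
#' d <- tibble::tibble(label = c(1, 1, 0, 0), prob = c(0.9, 0.8, 0.2, 0.1))
#' max_tss(d)
#' @export
max_tss <- function(data, cutoffs = cutoff_grid()) {
  curve <- tss_curve(data, cutoffs)
  i <- which.max(curve$tss)
  tibble(max_tss = curve$tss[i], cutoff = curve$cutoff[i])
}

split_classes <- function(data) {
  if (!is.data.frame(data) || !all(c("label", "prob") %in% names(data))) {
    abort("`data` must be a data frame with columns `label` and `prob`.",
          class = "tssbias_error_input")
  }
  if (!all(data$label %in% c(0, 1))) {
    abort("`label` entries must be 0 or 1.", class = "tssbias_error_input")
  }
  p1 <- data$prob[data$label == 1]
  p0 <- data$prob[data$label == 0]
  if (length(p1) == 0L || length(p0) == 0L) {
    abort("Both classes must be present in the labels.",
          class = "tssbias_error_degenerate")
  }
  list(p1 = p1, p0 = p0)
}

# (max tss, argmax cutoff) from the class-wise probability vectors;
# hot loop of run_experiment
max_tss_fast <- function(p1, p0, cutoffs) {
  vals <- vapply(cutoffs,
                 function(ct) mean(p1 > ct) + mean(p0 <= ct) - 1,
                 numeric(1))
  i <- which.max(vals)
  c(vals[i], cutoffs[i])
}

# deterministic per-replicate substream seeds below 2^31, so each replicate
# is individually reproducible from the root seed
substream_seed <- function(seed, cell, rep) {
  base <- (as.double(seed) %% 2147483647) * 48271 + cell * 100003 + rep
  as.integer(base %% 2147483629)
}

#' Monte Carlo experiment: mean maximum TSS per factorial cell
#'
#' For every combination of discrimination scenario, total sample size and
#' prevalence, repeatedly simulates a labeled prediction set
#' ([sample_labeled_predictions()]), takes the maximum TSS over the cutoff
#' grid, and aggregates the maxima. Defaults reproduce the full study design:
#' four scenarios, sizes 100/1000/10000, prevalence 0.05 to 0.95 in steps of
#' 0.05, 19 cutoffs, 1000 replicates per cell. Each replicate runs on its own
#' seed substream derived from `seed`, so any cell is reproducible in
#' isolation.
#'
#' @param scenarios Character vector of scenario names (see
#'   [model_scenarios()]).
#' @param sample_sizes Integer vector of total sample sizes N.
#' @param prevalence Numeric vector of prevalences in (0, 1).
#' @param n_reps Replicates per cell.
#' @param cutoffs Cutoff vector, default [cutoff_grid()].
#' @param seed Root seed (integer).
#' @param verbose Print per-cell progress to stderr.
#' @return A tibble of class `tss_experiment` with one row per cell:
#'   `scenario`, `n_total`, `prevalence`, `n_presence`, `mean_max_tss`,
#'   `sd_max_tss`, `se_max_tss` (Monte Carlo standard error of the mean),
#'   `mean_cutoff`, `n_reps`. The root seed is carried as an attribute.
#' @examples
#' res <- run_experiment(scenarios = "linear", sample_sizes = 100,
#'                       prevalence = c(0.1, 0.5, 0.9), n_reps = 20, seed = 1)
#' res
#' @export
run_experiment <- function(scenarios = model_scenarios()$name,
                           sample_sizes = c(100, 1000, 10000),
                           prevalence = seq(0.05, 0.95, by = 0.05),
                           n_reps = 1000,
                           cutoffs = cutoff_grid(),
                           seed = 20170112,
                           verbose = FALSE) {
  scenarios <- vapply(scenarios, function(s) model_scenario(s)$name,
                      character(1), USE.NAMES = FALSE)
  check_prev_vec(prevalence)
  cutoffs <- cutoff_grid(cutoffs)
  if (length(n_reps) != 1L || n_reps < 1) {
    abort("`n_reps` must be a single count >= 1.",
          class = "tssbias_error_input")
  }
  cells <- tidyr::crossing(
    scenario = factor(scenarios, levels = scenarios),
    n_total = sort(unique(as.integer(sample_sizes))),
    prevalence = sort(unique(prevalence))
  )
  cells$scenario <- as.character(cells$scenario)

  rows <- purrr::imap(
    purrr::transpose(cells),
    function(cell, i) {
      sc <- model_scenario(cell$scenario)
      n_pres <- allocate_presences(cell$n_total, cell$prevalence)
      n_abs <- cell$n_total - n_pres
      maxima <- numeric(n_reps)
      argmax <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        set.seed(substream_seed(seed, i, r))
        draws <- draw_scenario_probs(sc, n_pres, n_abs)
        mt <- max_tss_fast(draws$presence, draws$absence, cutoffs)
        maxima[r] <- mt[1]
        argmax[r] <- mt[2]
      }
      if (verbose) {
        message(sprintf("cell %d/%d: %s N=%d pi=%.2f mean max TSS=%.4f",
                        i, nrow(cells), cell$scenario, cell$n_total,
                        cell$prevalence, mean(maxima)))
      }
      tibble(
        scenario = cell$scenario, n_total = cell$n_total,
        prevalence = cell$prevalence, n_presence = n_pres,
        mean_max_tss = mean(maxima),
        sd_max_tss = sd(maxima),
        se_max_tss = sd(maxima) / sqrt(n_reps),
        mean_cutoff = mean(argmax),
        n_reps = as.integer(n_reps)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("tss_experiment", class(out))
  out
}

#' @export
glance.tss_experiment <- function(x, ...) {
  tibble(
    n_scenarios = dplyr::n_distinct(x$scenario),
    n_sizes = dplyr::n_distinct(x$n_total),
    n_prevalences = dplyr::n_distinct(x$prevalence),
    n_cells = nrow(x),
    n_reps = max(x$n_reps),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Confusion matrix from fixed sensitivity and specificity
#'
#' Constructs the table implied by holding TPR and TNR constant at a given
#' prevalence and sample size — the design used to argue that TSS is
#' prevalence independent. In `"real"` mode the cells are exact products
#' (tp = tpr * P, tn = tnr * (N - P)) and TSS is exactly tpr + tnr - 1
#' regardless of prevalence. In `"integer"` mode each cell is rounded
#' (round-half-to-even) before FN/FP are taken as complements, reproducing the
#' low-level jitter that realized integer tables show around the theoretical
#' value.
#'
#' @param tpr,tnr Target sensitivity and specificity in \[0, 1\].
#' @param prevalence Prevalence in (0, 1); P = round(prevalence * N).
#' @param n_total Total sample size.
#' @param mode `"real"` or `"integer"`.
#' @return A [confusion_matrix()] in the requested mode.
#' @examples
#' tss(fixed_rate_confusion(0.8, 0.8, prevalence = 0.5, n_total = 100))
#' @export
fixed_rate_confusion <- function(tpr, tnr, prevalence, n_total,
                                 mode = c("real", "integer")) {
  mode <- match.arg(mode)
  if (anyNA(c(tpr, tnr)) || any(c(tpr, tnr) < 0 | c(tpr, tnr) > 1)) {
    abort("`tpr` and `tnr` must lie in [0, 1].", class = "tssbias_error_input")
  }
  n_pres <- allocate_presences(n_total, prevalence)
  n_abs <- n_total - n_pres
  if (mode == "real") {
    confusion_matrix(tp = tpr * n_pres, fn = (1 - tpr) * n_pres,
                     tn = tnr * n_abs, fp = (1 - tnr) * n_abs,
                     mode = "real")
  } else {
    tp <- round(tpr * n_pres)
    tn <- round(tnr * n_abs)
    confusion_matrix(tp = tp, fn = n_pres - tp, tn = tn, fp = n_abs - tn,
                     mode = "integer")
  }
}

#' Fixed-rate TSS across a prevalence grid
#'
#' Replicates the constant-TPR/TNR design over a prevalence grid: with
#' real-valued cells TSS equals tpr + tnr - 1 at every prevalence, and with
#' integer cells it deviates only by rounding (bounded by
#' 0.5 * (1/P + 1/(N-P))).
#'
#' @inheritParams fixed_rate_confusion
#' @param prevalence_grid Numeric vector of prevalences.
#' @return A tibble with columns `prevalence`, `tss_real`, `tss_integer`.
#' @examples
#' allouche_replication(0.8, 0.8, n_total = 100)
#' @export
allouche_replication <- function(tpr, tnr,
                                 prevalence_grid = seq(0.05, 0.95, by = 0.05),
                                 n_total = 100) {
  purrr::map_dfr(prevalence_grid, function(pi) {
    tibble(
      prevalence = pi,
      tss_real = tss(fixed_rate_confusion(tpr, tnr, pi, n_total,
                                          mode = "real"))$tss,
      tss_integer = tss(fixed_rate_confusion(tpr, tnr, pi, n_total,
                                             mode = "integer"))$tss
    )
  })
}
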