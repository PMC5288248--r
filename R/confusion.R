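#' Construct a confusion matrix
#'
#' Builds the 2x2 table of matches and mismatches between binary observations
#' and binary predictions that underlies all threshold-based discrimination
#' metrics. Cells may be realized integer counts (`mode = "integer"`) or
#' real-valued expected counts (`mode = "real"`), as produced by the algebraic
#' observation-error scenarios in [scenario_confusion()].
#'
#' @param tp,fp,fn,tn Non-negative cell counts: true positives, false
#'   positives, false negatives, true negatives.
#' @param mode `"integer"` for realized samples (cells must be whole numbers)
#'   or `"real"` for expected-value tables.
#' @return An object of class `confusion_matrix`.
#' @seealso [confusion_from_binary()], [tss()], [kappa_score()]
#' @examples
#' cm <- confusion_matrix(tp = 40, fp = 10, fn = 10, tn = 40)
#' tss(cm)
#' @export
confusion_matrix <- function(tp, fp, fn, tn, mode = c("integer", "real")) {
  mode <- match.arg(mode)
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!is.numeric(cells) || length(cells) != 4L || anyNA(cells)) {
    abort("All four cells must be single non-missing numbers.",
          class = "tssbias_error_input")
  }
  if (any(cells < 0)) {
    abort("Confusion matrix cells must be non-negative.",
          class = "tssbias_error_input")
  }
  if (mode == "integer" && any(abs(cells - round(cells)) > 1e-8)) {
    abort("Integer-mode confusion matrices require whole-number cells.",
          class = "tssbias_error_input")
  }
  if (mode == "integer") cells <- round(cells)
  structure(
    list(tp = cells[["tp"]], fp = cells[["fp"]],
         fn = cells[["fn"]], tn = cells[["tn"]], mode = mode),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (", x$mode, " mode)\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(observed = c("1", "0"),
                              predicted = c("1", "0")))
  print(m)
  invisible(x)
}

# margins used throughout: P (positives observed), S (positives predicted), N
cm_p <- function(cm) cm$tp + cm$fn
cm_s <- function(cm) cm$tp + cm$fp
cm_n <- function(cm) cm$tp + cm$fp + cm$fn + cm$tn

#' Prevalence of a confusion matrix
#'
#' Fraction of presence observations among all observations, P/N.
#'
#' @param cm A [confusion_matrix()].
#' @return A number in \[0, 1\].
#' @export
prevalence <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cm_p(cm) / cm_n(cm)
}

#' Tally binary observations against binary predictions
#'
#' @param obs,pred Equal-length vectors of 0/1 labels; `obs` are the field
#'   observations (1 = presence), `pred` the model's binary predictions.
#' @return An integer-mode [confusion_matrix()] whose cells partition the
#'   observations.
#' @examples
#' confusion_from_binary(obs = c(1, 1, 0, 0), pred = c(1, 0, 1, 0))
#' @export
confusion_from_binary <- function(obs, pred) {
  if (length(obs) != length(pred)) {
    abort("`obs` and `pred` must have the same length.",
          class = "tssbias_error_input")
  }
  if (length(obs) == 0L) {
    abort("`obs` and `pred` must contain at least one observation.",
          class = "tssbias_error_input")
  }
  if (!all(obs %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    abort("`obs` and `pred` entries must be 0 or 1.",
          class = "tssbias_error_input")
  }
  confusion_matrix(
    tp = sum(obs == 1 & pred == 1),
    fp = sum(obs == 0 & pred == 1),
    fn = sum(obs == 1 & pred == 0),
    tn = sum(obs == 0 & pred == 0),
    mode = "integer"
  )
}

#' Convert predicted probabilities to binary calls at a cutoff
#'
#' Presence is called when the predicted probability strictly exceeds the
#' cutoff; ties at the cutoff are absences, matching the conditional
#' probability formulation TPR = P(x > xc | present), TNR = P(x <= xc | absent).
#'
#' @param probs Vector of predicted probabilities in \[0, 1\].
#' @param cutoff A single probability in \[0, 1\].
#' @return Integer vector of 0/1 calls, same length as `probs`.
#' @examples
#' binarize(c(0.9, 0.5, 0.2), cutoff = 0.5)
#' @export
binarize <- function(probs, cutoff) {
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    abort("`probs` must lie in [0, 1].", class = "tssbias_error_input")
  }
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0 || cutoff > 1) {
    abort("`cutoff` must be a single probability in [0, 1].",
          class = "tssbias_error_input")
  }
  as.integer(probs > cutoff)
}

#' True skill statistic of a confusion matrix
#'
#' TSS = TPR + TNR - 1 with TPR = TP/(TP+FN) (sensitivity) and
#' TNR = TN/(TN+FP) (specificity). TSS is also known as the Youden index and
#' the Peirce/Kuipers skill score. Both observed classes must be present;
#' a table with P = 0 or N - P = 0 has an undefined rate and raises an error
#' rather than silently returning a sentinel.
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble with columns `tpr`, `tnr`, `tss`.
#' @examples
#' tss(confusion_matrix(tp = 40, fp = 10, fn = 10, tn = 40))
#' @export
tss <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm_p(cm)
  a <- cm$tn + cm$fp
  if (p <= 0 || a <= 0) {
    abort(
      "TSS is undefined when a class is absent from the observations (P = 0 or N - P = 0).",
      class = "tssbias_error_degenerate"
    )
  }
  tpr <- cm$tp / p
  tnr <- cm$tn / a
  tibble(tpr = tpr, tnr = tnr, tss = tpr + tnr - 1)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement, (po - pe) / (1 - pe), where po is the observed
#' agreement (TP+TN)/N and pe the agreement expected from the margins. Included
#' as the classical comparison baseline: kappa is known to be prevalence
#' dependent even when both error rates are fixed.
#'
#' @param cm A [confusion_matrix()].
#' @return A single score in \[-1, 1\]; 1 for perfect agreement.
#' @examples
#' kappa_score(confusion_matrix(tp = 40, fp = 10, fn = 10, tn = 40))
#' @export
kappa_score <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_n(cm)
  p <- cm_p(cm)
  s <- cm_s(cm)
  if (p <= 0 || p >= n) {
    abort(
      "kappa is undefined when a class is absent from the observations.",
      class = "tssbias_error_degenerate"
    )
  }
  po <- (cm$tp + cm$tn) / n
  pe <- (p * s + (n - p) * (n - s)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    abort("kappa is undefined: chance agreement equals 1.",
          class = "tssbias_error_degenerate")
  }
  (po - pe) / (1 - pe)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(
    observed  = c(1L, 1L, 0L, 0L),
    predicted = c(1L, 0L, 1L, 0L),
    cell      = c("tp", "fn", "fp", "tn"),
    count     = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(
    n = cm_n(x), p = cm_p(x), s = cm_s(x),
    prevalence = prevalence(x), mode = x$mode
  )
}
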