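#' Read and write labeled prediction sets as delimited text
#'
#' Datasets are stored as comma-separated text with columns `label` and
#' `prob`; `#`-prefixed comment lines at the top record the generating
#' scenario, sample size, prevalence and seed when known, so any written file
#' can be regenerated.
#'
#' @param data A data frame with columns `label` and `prob`, e.g. from
#'   [sample_labeled_predictions()].
#' @param path File path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns a tibble with integer `label` and double
#'   `prob`, with any recorded metadata restored as attributes.
#' @export
write_predictions <- function(data, path) {
  if (!is.data.frame(data) || !all(c("label", "prob") %in% names(data))) {
    abort("`data` must have columns `label` and `prob`.",
          class = "tssbias_error_input")
  }
  meta <- c(
    scenario = attr(data, "scenario"),
    n_total = attr(data, "n_total"),
    prevalence = attr(data, "prevalence"),
    seed = attr(data, "seed")
  )
  header <- sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
  lines <- c(header, "label,prob",
             sprintf("%d,%s", as.integer(data$label),
                     formatC(data$prob, digits = 17, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "tssbias_error_input")
  }
  meta_lines <- grep("^#", readLines(path, n = 10), value = TRUE)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           label = readr::col_integer(),
                           prob = readr::col_double()))
  if (!all(c("label", "prob") %in% names(out))) {
    abort("Expected columns `label` and `prob`.",
          class = "tssbias_error_input")
  }
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^# *([a-z_]+): *(.+)$", ln))[[1]]
    if (length(m) == 3L && m[3] != "NULL") {
      val <- suppressWarnings(as.numeric(m[3]))
      attr(out, m[2]) <- if (is.na(val)) m[3] else val
    }
  }
  out
}

#' Write packaged example datasets
#'
#' Generates the small fixture set used in examples and tests: one labeled
#' prediction file per discrimination scenario (N = 100, prevalence 0.5) and a
#' table of fixed-rate worked-example confusion matrices (sensitivity and
#' specificity held at 0.8/0.8 and 0.7/0.9, both of which give TSS = 0.6).
#' Rerunning with the same seed reproduces the files byte for byte.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Integer root seed.
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(out_dir, seed = 20170112) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(nrow(model_scenarios()))) {
    nm <- model_scenarios()$name[i]
    d <- sample_labeled_predictions(nm, n_total = 100, prevalence = 0.5,
                                    seed = seed + i)
    p <- file.path(out_dir, sprintf("predictions_%s.csv", nm))
    write_predictions(d, p)
    paths <- c(paths, p)
  }
  worked <- purrr::map_dfr(
    list(c(0.8, 0.8), c(0.7, 0.9)),
    function(rates) {
      cm <- fixed_rate_confusion(rates[1], rates[2], prevalence = 0.5,
                                 n_total = 100, mode = "integer")
      tibble(tpr = rates[1], tnr = rates[2],
             tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    }
  )
  wp <- file.path(out_dir, "fixed_rate_worked_examples.csv")
  readr::write_csv(worked, wp)
  invisible(c(paths, wp))
}
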