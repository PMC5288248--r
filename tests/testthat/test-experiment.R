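test_that("tss_curve matches hand enumeration on separable data", {
  d <- tibble::tibble(label = c(1, 1, 0, 0), prob = c(0.9, 0.8, 0.2, 0.1))
  curve <- tss_curve(d)
  expect_equal(nrow(curve), 19)
  # perfect separation for cutoffs in [0.2, 0.8): all absences at/below,
  # all presences above
  ones <- curve$cutoff >= 0.2 & curve$cutoff < 0.8
  expect_true(all(curve$tss[ones] == 1))
  expect_true(all(curve$tss[!ones] < 1))
  expect_equal(curve$tss[curve$cutoff == 0.8], 0.5)  # 0.8 > 0.8 is FALSE
})

test_that("uninformative and perfectly separated predictions give flat curves", {
  flat <- tibble::tibble(label = c(1, 0, 1, 0), prob = rep(0.4, 4))
  expect_true(all(tss_curve(flat)$tss == 0))
  sep <- tibble::tibble(label = c(1, 1, 0, 0), prob = c(1, 1, 0, 0))
  expect_true(all(tss_curve(sep)$tss == 1))
})

test_that("max_tss takes the curve maximum, ties to the smallest cutoff", {
  d <- tibble::tibble(label = c(1, 1, 0, 0), prob = c(0.9, 0.8, 0.2, 0.1))
  mt <- max_tss(d)
  expect_equal(mt$max_tss, 1)
  expect_equal(mt$cutoff, 0.2)
  flat <- tibble::tibble(label = c(1, 0), prob = c(0.3, 0.3))
  expect_equal(max_tss(flat), tibble::tibble(max_tss = 0, cutoff = 0.05))
})

test_that("tss_curve and max_tss agree with the brute-force oracle", {
  set.seed(31)
  grid <- cutoff_grid()
  for (i in 1:25) {
    d <- sample_labeled_predictions(
      sample(model_scenarios()$name, 1), n_total = sample(c(20, 50, 200), 1),
      prevalence = runif(1, 0.1, 0.9))
    expect_equal(tss_curve(d, grid)$tss, oracle_tss_curve(d$label, d$prob, grid))
    mt <- max_tss(d, grid)
    om <- oracle_max_tss(d$label, d$prob, grid)
    expect_equal(mt$max_tss, unname(om["max"]))
    expect_equal(mt$cutoff, unname(om["cutoff"]))
  }
})

test_that("single-class data is rejected with a degenerate-draw error", {
  d <- tibble::tibble(label = c(1, 1), prob = c(0.2, 0.9))
  expect_error(tss_curve(d), class = "tssbias_error_degenerate")
  expect_error(max_tss(d), class = "tssbias_error_degenerate")
  expect_error(tss_curve(tibble::tibble(label = c(1, 2), prob = c(0.1, 0.2))),
               class = "tssbias_error_input")
})

test_that("run_experiment is reproducible cell by cell", {
  a <- run_experiment(scenarios = "linear", sample_sizes = 100,
                      prevalence = c(0.2, 0.5), n_reps = 5, seed = 3)
  b <- run_experiment(scenarios = "linear", sample_sizes = 100,
                      prevalence = c(0.2, 0.5), n_reps = 5, seed = 3)
  expect_equal(as.data.frame(a), as.data.frame(b))
  expect_named(
    a, c("scenario", "n_total", "prevalence", "n_presence", "mean_max_tss",
         "sd_max_tss", "se_max_tss", "mean_cutoff", "n_reps"))
  gl <- glance(a)
  expect_equal(gl$n_cells, 2)
  expect_equal(gl$seed, 3)
})

test_that("mean maximum TSS is consistent at large N and biased at small N", {
  big <- run_experiment(scenarios = "quadratic", sample_sizes = 10000,
                        prevalence = 0.5, n_reps = 200, seed = 17)
  expect_equal(big$mean_max_tss, 0.75, tolerance = 0.01 / 0.75)

  sizes <- run_experiment(scenarios = "square_root",
                          sample_sizes = c(100, 1000, 10000),
                          prevalence = 0.5, n_reps = 200, seed = 17)
  means <- sizes$mean_max_tss[order(sizes$n_total)]
  expect_true(all(diff(means) < 0))  # bias decays with sample size
})

test_that("fixed-rate construction reproduces constant TSS and integer jitter", {
  expect_equal(tss(fixed_rate_confusion(0.8, 0.8, 0.5, 100))$tss, 0.6)
  expect_equal(tss(fixed_rate_confusion(0.7, 0.9, 0.5, 100))$tss, 0.6)

  # pi = 0.07, N = 100: P = 7, tp = round(5.6) = 6, tn = round(74.4) = 74
  cm <- fixed_rate_confusion(0.8, 0.8, 0.07, 100, mode = "integer")
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(6, 1, 74, 19))
  expect_equal(tss(cm)$tss, 6 / 7 + 74 / 93 - 1)
  expect_error(fixed_rate_confusion(1.2, 0.8, 0.5, 100),
               class = "tssbias_error_input")
})

test_that("fixed-rate TSS across prevalence is flat in real mode", {
  rep <- allouche_replication(0.8, 0.8)
  expect_equal(nrow(rep), 19)
  expect_true(all(abs(rep$tss_real - 0.6) < 1e-12))

  perfect <- allouche_replication(1, 1, n_total = 100)
  expect_true(all(perfect$tss_real == 1))
  expect_true(all(perfect$tss_integer == 1))

  # integer-cell deviation shrinks like the rounding bound at large N
  big <- allouche_replication(0.8, 0.8, n_total = 10000)
  expect_lt(max(abs(big$tss_integer - 0.6)), 0.01)
})
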