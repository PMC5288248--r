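test_that("scenario_confusion fills the expected tables", {
  # perfect model, perfect observation: diagonal
  cm <- scenario_confusion(error_scenario("two_error", prevalence = 0.5,
                                          e1 = 0, e2 = 0), 100)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(50, 0, 0, 50))
  expect_identical(cm$mode, "real")

  # missed presences, e = 0.2, pi = 0.5, N = 1000: S = 500/0.8 = 625
  cm <- scenario_confusion(error_scenario("missed_presence", prevalence = 0.5,
                                          e = 0.2), 1000)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(500, 0, 125, 375))
  expect_equal(cm$tp + cm$fp, 625)   # S margin
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 1000)

  # fallacious presences prop. to unsuitable sites: S = (500 - 100)/0.9
  cm <- scenario_confusion(
    error_scenario("fallacious_presence_prop_unsuitable", prevalence = 0.5,
                   e = 0.1), 1000)
  s <- (500 - 100) / 0.9
  expect_equal(cm$tp, s)
  expect_equal(cm$fn, 0.1 * (1000 - s))
  expect_equal(cm$fp, 0)
  expect_equal(cm$tn, 500)
  expect_equal(cm$tp + cm$fn, 500)   # row margin P balances
})

test_that("two-error TSS is 1 - e1 - e2 and matches its table at any prevalence", {
  expect_equal(tss_two_error(0, 0), 1)
  expect_equal(tss_two_error(0.2, 0.2), 0.6)
  for (pi in c(0.1, 0.5, 0.9)) {
    cm <- scenario_confusion(error_scenario("two_error", prevalence = pi,
                                            e1 = 0.1, e2 = 0.3), 1000)
    expect_equal(tss(cm)$tss, 0.6, tolerance = 1e-12)
  }
})

test_that("missed-presence TSS matches its table and decreases with prevalence", {
  expect_equal(tss_missed_presence(0, 0.3), 1)
  cm <- scenario_confusion(error_scenario("missed_presence", prevalence = 0.5,
                                          e = 0.2), 1000)
  expect_equal(tss(cm)$tnr, 375 / 500)
  expect_equal(tss_missed_presence(0.2, 0.5), 0.75)
  expect_equal(tss_missed_presence(0.2, 0.5), tss(cm)$tss, tolerance = 1e-12)

  # prevalence dependence despite a prevalence-free error rate
  expect_lt(tss_missed_presence(0.1, 0.8), tss_missed_presence(0.1, 0.2))
  pis <- seq(0.05, 0.85, by = 0.05)
  vals <- tss_missed_presence(0.1, pis)
  expect_true(all(diff(vals) < 0))
  es <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(tss_missed_presence(es, 0.5)) < 0))
})

test_that("fallacious absences are mathematically the missed-presence case", {
  expect_equal(tss_fallacious_absence(0, 0.3), 1)
  expect_equal(tss_fallacious_absence(0.2, 0.5), 0.75)
  grid <- expand.grid(e = seq(0.02, 0.2, length.out = 10),
                      pi = seq(0.05, 0.75, length.out = 10))
  expect_equal(tss_fallacious_absence(grid$e, grid$pi),
               tss_missed_presence(grid$e, grid$pi))
})

test_that("the two fallacious-presence variants disagree as documented", {
  expect_equal(tss_fallacious_presence(0, 0.4), 1)
  expect_equal(tss_fallacious_presence(0, 0.4, variant = "printed"), 1)
  expect_equal(tss_fallacious_presence(0.1, 0.5, variant = "printed"),
               0.4 / 0.55)
  # table-consistent variant: TPR = S/P with S = (P - eN)/(1 - e)
  expect_equal(tss_fallacious_presence(0.1, 0.5), 0.4 / 0.45)
  cm <- scenario_confusion(
    error_scenario("fallacious_presence_prop_unsuitable", prevalence = 0.5,
                   e = 0.1), 1000)
  expect_equal(tss(cm)$tpr, (400 / 0.9) / 500)
  expect_equal(tss_fallacious_presence(0.1, 0.5), tss(cm)$tss,
               tolerance = 1e-12)
})

test_that("every closed form agrees with its expected table on an (e, pi, N) grid", {
  es <- seq(0.02, 0.2, length.out = 10)
  pis <- seq(0.25, 0.75, length.out = 10)
  ns <- c(100, 1000, 10000)
  for (e in es) for (pi in pis) for (n in ns) {
    expect_equal(
      tss(scenario_confusion(error_scenario("two_error", prevalence = pi,
                                            e1 = e, e2 = e / 2), n))$tss,
      tss_two_error(e, e / 2), tolerance = 1e-12)
    expect_equal(
      tss(scenario_confusion(error_scenario("missed_presence", prevalence = pi,
                                            e = e), n))$tss,
      tss_missed_presence(e, pi), tolerance = 1e-12)
    expect_equal(
      tss(scenario_confusion(error_scenario("fallacious_absence",
                                            prevalence = pi, e = e), n))$tss,
      tss_fallacious_absence(e, pi), tolerance = 1e-12)
    expect_equal(
      tss(scenario_confusion(error_scenario("fallacious_presence_prop_presences",
                                            prevalence = pi, e = e), n))$tss,
      tss_two_error(e, 0), tolerance = 1e-12)
    expect_equal(
      tss(scenario_confusion(error_scenario("fallacious_presence_prop_unsuitable",
                                            prevalence = pi, e = e), n))$tss,
      tss_fallacious_presence(e, pi), tolerance = 1e-12)
  }
})

test_that("scenario TSS stays in [-1, 1] on the valid domain", {
  grid <- expand.grid(e = seq(0, 0.45, by = 0.05),
                      pi = seq(0.5, 0.95, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    e <- grid$e[i]; pi <- grid$pi[i]
    vals <- c(tss_two_error(e, e),
              if (pi <= 1 - e) tss_missed_presence(e, pi),
              if (pi > e) tss_fallacious_presence(e, pi),
              if (pi > e) tss_fallacious_presence(e, pi, variant = "printed"))
    expect_true(all(vals >= -1 & vals <= 1))
  }
})

test_that("domain violations are rejected", {
  expect_error(error_scenario("fallacious_presence_prop_unsuitable",
                              prevalence = 0.1, e = 0.2),
               class = "tssbias_error_input")
  expect_error(error_scenario("missed_presence", prevalence = 0.9, e = 0.2),
               class = "tssbias_error_input")
  expect_error(tss_missed_presence(0.2, 0.9), class = "tssbias_error_input")
  expect_error(tss_fallacious_presence(0.2, 0.1),
               class = "tssbias_error_input")
  expect_error(tss_two_error(1, 0), class = "tssbias_error_input")
  expect_error(error_scenario("two_error", prevalence = 0),
               class = "tssbias_error_input")
})

test_that("closed_form_table crosses kinds with the grid and drops invalid cells", {
  tab <- closed_form_table(e = c(0.1, 0.3), prevalence = c(0.2, 0.5, 0.8))
  expect_true(all(!is.na(tab$tss)))
  # fallacious_presence_prop_unsuitable reports both variants side by side
  fp <- dplyr::filter(tab, kind == "fallacious_presence_prop_unsuitable",
                      e == 0.1, prevalence == 0.5)
  expect_setequal(fp$variant, c("table_consistent", "printed"))
  expect_gt(fp$tss[fp$variant == "table_consistent"],
            fp$tss[fp$variant == "printed"])
  # two_error rows are constant across prevalence
  te <- dplyr::filter(tab, kind == "two_error", e == 0.1)
  expect_equal(diff(range(te$tss)), 0)
})
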