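---
title: "Why maximum TSS depends on prevalence: models, scenarios, and the Monte Carlo design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why maximum TSS depends on prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tssbias)
library(dplyr)
```

## The statistic and the question

Species distribution models are routinely ranked by the true skill statistic,

$$\mathrm{TSS} = \mathrm{TPR} + \mathrm{TNR} - 1,$$

where TPR (sensitivity) is TP/(TP+FN) and TNR (specificity) is TN/(TN+FP)
from the 2×2 confusion matrix of observed versus predicted presence/absence.
TSS is the Youden index of the epidemiological literature and the
Peirce/Kuipers skill score of forecast verification. Its appeal in ecology
rests on the claim that, unlike Cohen's kappa, it does not react to
prevalence $\pi = P/N$ — the fraction of presence observations — so models of
rare and common species can be compared on equal footing.

This package dissects that claim along two axes:

1. **Binary predictions, closed form.** When both observations and
   predictions are binary, TSS can be written down algebraically under
   explicit assumptions about where observation error comes from. Whether
   $\pi$ survives in the formula decides prevalence dependence.
2. **Continuous predictions, Monte Carlo.** In practice predictions are
   probabilities, binarized at a grid of cutoffs, and the *maximum* TSS over
   the grid is reported. The cutoff is then chosen from the data, and a
   maximum of noisy quantities is biased upward. The simulation study
   quantifies how that bias varies with prevalence, sample size, and model
   quality.

## Closed-form scenarios

If the model errs with fixed false-negative rate $e_1$ and false-positive
rate $e_2$ and observations are error-free, the expected confusion matrix
gives $\mathrm{TSS} = 1 - e_1 - e_2$: prevalence cancels, so binary TSS is
prevalence independent in this idealized setting. The classical
constant-rate design that argued for prevalence independence is reproduced by
`fixed_rate_confusion()` / `allouche_replication()`: holding TPR and TNR at
0.8/0.8 (or 0.7/0.9) forces TSS = 0.6 at every prevalence by construction,
which demonstrates nothing about prevalence dependence in general — the
low-level jitter seen in realized tables is only the constraint that cell
counts must be integers (`mode = "integer"` rounds each cell half-to-even and
takes FN/FP as complements).

Prevalence dependence appears as soon as the observed pattern is allowed to
deviate from habitat suitability while the model remains perfect:

* **Missed presences** (detection failure at rate $e$):
  $\mathrm{TSS} = \dfrac{1-e-\pi}{(1-\pi)(1-e)}$ — decreasing in $\pi$.
* **Fallacious absences** (suitable but unoccupied sites, e.g.
  metapopulation vacancies): algebraically identical to missed presences.
* **Fallacious presences** (occupied unsuitable sites, e.g. sinks): if
  proportional to the number of *presences* this reduces to the two-error
  case with $e_2 = 0$ (prevalence independent); if proportional to the
  number of *unsuitable sites* it is prevalence dependent.

For the last case the published shortcut for the number of positive
predictions, $S = (P - eN)/(1+e)$, does not balance the margins of the very
table it is derived from: the table's identity $TP = P - e(N-S) = S$ solves
to $S = (P - eN)/(1-e)$. Both are exposed —
`tss_fallacious_presence(variant = "table_consistent")` (the default, and the
form consistent with the expected table that `scenario_confusion()` builds)
and `variant = "printed"` — and `closed_form_table()` reports them side by
side rather than silently picking one.

Every closed form is tested against an independent oracle: build the
expected confusion matrix cell by cell with `scenario_confusion()`, run it
through the generic `tss()`, and require agreement to $10^{-12}$ over an
$(e, \pi, N)$ grid.

```{r}
closed_form_table(e = 0.1, prevalence = c(0.2, 0.5, 0.8)) |>
  filter(kind %in% c("two_error", "missed_presence",
                     "fallacious_presence_prop_unsuitable"))
```

## The generative model for continuous predictions

The simulator emulates a model of tunable discrimination quality: predicted
probabilities for presences are drawn from a beta density $f_1$ and for
absences from $f_0$, with mirror-image parameters so that
$f_0(x) = f_1(1-x)$:

| scenario      | $f_1$             | discrimination       |
|---------------|-------------------|----------------------|
| `quadratic`   | beta(3, 1)        | good                 |
| `linear`      | beta(2, 1)        | medium               |
| `square_root` | beta(1.5, 1)      | weak                 |
| `p16`         | beta(17/16, 1)    | extremely weak       |

(The mirror identity is the defensible reading of the design: the literal
statement "$f_0(x) = 1 - f_1(x)$" cannot hold for densities, and the
parameter table itself implies the mirror form. The test suite verifies
$f_0(x) = f_1(1-x)$ numerically for all four scenarios.)

Labels are allocated deterministically, $P = \mathrm{round}(\pi N)$ clamped
to keep both classes; on the study grid ($\pi \in \{0.05, \dots, 0.95\}$,
$N \in \{100, 1000, 10000\}$) the product is integral and clamping never
fires. Sampling uses inversion of the conditional CDFs with the closed-form
branch $Q(u) = u^{1/\alpha}$ (or its mirror) available whenever one beta
parameter is 1 — true for all four scenarios — so draws are exactly
reproducible from the uniform stream and independent of any library's beta
sampler internals. `qbeta()` is the fallback for general parameters.

What the generator does *not* emulate: spatial structure, covariates,
calibration error, or any coupling between sites. Passing tests therefore
speak to the behavior of the *statistic* under known conditional
distributions, not to any particular SDM fitted to field data.

## Theory: the expected TSS and its optimum

At cutoff $x_c$ (presence is called when the predicted probability strictly
exceeds $x_c$; ties are absences, matching
$\mathrm{TPR} = P(x > x_c \mid \text{present})$),

$$E(\mathrm{TSS}) = F_0(x_c) - F_1(x_c),$$

which is maximal where the densities cross, $f_0(x_c) = f_1(x_c)$.
`theoretical_optimum()` locates the crossing by bracketed root-finding
(`uniroot`, tolerance $10^{-9}$ on the cutoff); for the shipped
mirror-symmetric scenarios the crossing is at 0.5 analytically, but the
solver path is kept and tested so non-symmetric scenarios would work too.
The optima order the scenarios by discrimination power:

```{r}
theoretical_optima()
```

Crucially, $E(\mathrm{TSS})$ contains no $\pi$: with an a priori cutoff,
TSS on continuous predictions is prevalence independent. The dependence
enters only through estimating the cutoff from data.

## The Monte Carlo experiment

`run_experiment()` crosses scenario × sample size × prevalence, simulates
`n_reps` datasets per cell, takes each dataset's maximum TSS over the
19-point cutoff grid 0.05, 0.10, …, 0.95, and reports the mean, SD, and
Monte Carlo standard error of the maxima plus the mean argmax cutoff. The
defaults are the full study design: four scenarios, $N \in \{100, 1000,
10000\}$, prevalence 0.05–0.95 in steps of 0.05, 1000 replicates. Design
choices that the procedure itself leaves open:

* **Tie-break at the argmax:** smallest cutoff. Only the maximum value is
  used downstream, so any deterministic rule gives identical science; a rule
  is still required for bit-reproducibility of `mean_cutoff`.
* **Seeding:** each replicate runs on its own substream seed derived from
  the root seed, cell index, and replicate index (kept below $2^{31}$), so
  any single cell can be re-run in isolation and reproduced exactly.
* **Degenerate draws:** impossible by construction — allocation clamping
  guarantees both classes in every dataset, and TPR/TNR condition on
  observed labels, so the TSS curve is defined even at cutoffs where a
  *predicted* class vanishes. Undefined rates elsewhere (single-class user
  data) raise classed errors rather than sentinel values.

```{r, eval = FALSE}
res <- run_experiment()        # full design, ~4 minutes on one CPU
autoplot(res)
```

A reduced run shows the headline phenomenon — the U shape — in seconds:

```{r}
res <- run_experiment(sample_sizes = 100, prevalence = seq(0.05, 0.95, 0.1),
                      n_reps = 200, seed = 20170112)
res |>
  group_by(scenario) |>
  summarise(spread = max(mean_max_tss) - min(mean_max_tss),
            at_edges = mean(mean_max_tss[prevalence %in% c(0.05, 0.95)]),
            at_mid = mean_max_tss[prevalence == 0.55])
```

At $N = 100$ the mean maximum TSS is inflated at extreme prevalence relative
to balanced prevalence for every scenario, the inflation grows as model
quality falls, and `bias_table()` (which joins each cell to its theoretical
optimum and carries the Monte Carlo SE forward) shows the bias decaying with
sample size. The intuition: the empirical conditional CDF of the *minority*
class is built from few points and is noisy; maximizing over cutoffs
harvests that noise, and the harvest is largest when one class is rare, the
sample small, or the true TSS curve flat.

## Numerical and scale choices

* Expected-value confusion matrices keep real-valued cells (the algebra is
  exact; rounding would break the $10^{-12}$ oracle equivalence); a mode
  flag separates them from realized integer tables, which validate
  integrality.
* The closed-form/oracle agreement tolerance is $10^{-12}$, i.e. pure
  floating-point noise on quantities of magnitude 1.
* Monte Carlo checks in the test suite are stated in units of the replicate
  Monte Carlo standard error wherever the quantity is stochastic, with
  frozen seeds so the suite is deterministic.
* Test and example problem sizes are scaled to what the checks need, not to
  the full design: the U-shape, headline-spread, and quality-ordering
  checks use the complete $N = 100$ grid at the study's 1000 replicates
  (~15 s); large-sample consistency uses $N = 10000$, $\pi = 0.5$, 200
  replicates; distribution-fit checks use $10^5$–$10^6$ draws.

## Known limitations

* One residual effect is worth stating plainly, because the test suite
  measures it: even at $N = 10000$ the mean maximum TSS retains a small
  *systematic* positive bias for very flat TSS curves (about $+0.005$ for
  the `p16` scenario at $\pi = 0.5$, versus a Monte Carlo SE of the mean
  near $0.0005$ at 200 replicates). It is invisible at the 0.01 resolution
  at which the decay of bias is usually read, but it does not vanish into
  the Monte Carlo noise of the mean: it is the expectation of a maximum of
  many nearly-equal noisy points. "Large samples eliminate the bias" is
  therefore true at practical resolution, not exactly.
* Only the maximum-TSS cutoff rule is studied; equality criteria
  (TPR = TNR) and ROC-based selection are out of scope, as are AUC,
  F-scores, and calibration measures.
* The error scenarios are examined one at a time; mixed mechanisms are not
  modeled.
* Scenarios beyond the four beta families are accepted by the machinery
  (the solver path is generic) but are untested territory.
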