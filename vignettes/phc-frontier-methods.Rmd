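---
title: "Frontier efficiency and productivity analysis for primary healthcare panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontier efficiency and productivity analysis for primary healthcare panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phcfrontier)
```

## The problem

Province-level primary healthcare systems transform inputs — institutions,
beds, healthcare workers — into services: outpatient visits and hospital
admissions. Not every admission is desirable at the system level: when an
aggregate input–output analysis shows a province producing admissions far in
excess of what its efficient peers achieve with comparable resources, part of
that volume is read as *potentially unreasonable hospitalization*, a
by-product to be contracted rather than expanded. This package implements a
complete analysis chain for such panels:

1. a slacks-based directional-distance frontier model (SBM-DDF) under
   variable returns to scale, with and without undesirable outputs;
2. a two-stage decomposition that splits observed admissions into
   potentially reasonable and unreasonable components and scores the
   *severity* of unreasonable hospitalization per province;
3. the Global Malmquist–Luenberger (GML) productivity index with its
   efficiency-change (GEC) and technology-change (GTC) decomposition;
4. regional aggregation and summary tables;
5. a demand-forecast evaluation harness (sequential split, lag features,
   MAE/MAPE/MSE/RMSE, direct multi-step projection);
6. a synthetic panel generator with known true efficiencies, so every stage
   is testable end to end without any external download.

## The frontier model

For an evaluated unit with inputs $x_0 \in \mathbb{R}^N_+$, desirable
outputs $y_0 \in \mathbb{R}^M_+$ and undesirable outputs
$b_0 \in \mathbb{R}^I_+$, and a direction $g = (g_x, g_y, g_b) > 0$, the
inefficiency score is the optimum of the linear program

$$
S = \max_{w, s}\; \frac12\left[\frac1N \sum_{n} \frac{s^x_n}{g^x_n}
 + \frac{1}{M+I}\Big(\sum_m \frac{s^y_m}{g^y_m}
 + \sum_i \frac{s^b_i}{g^b_i}\Big)\right]
$$

subject to
$\sum_j w_j x_j + s^x = x_0$, $\sum_j w_j y_j - s^y = y_0$,
$\sum_j w_j b_j + s^b = b_0$, $\sum_j w_j = 1$, all variables
non-negative. The reference sums run over the *scope*'s observation pool:
the **global** frontier pools every (province, year) observation and makes
distances intertemporally comparable; a **contemporaneous** frontier uses a
single year. The convexity row $\sum w = 1$ imposes variable returns to
scale. Efficiency is reported as $\rho = 1 - S$; a frontier unit has
$S = 0$, $\rho = 1$.

Three conventions deserve comment, because the printed sources for this
model family are not always internally consistent:

* **Slack orientation.** Input and undesirable-output slacks are additive
  (excess to shed); the desirable-output slack is subtractive (shortfall to
  close). This is the only sign pattern under which all three slack vectors
  are simultaneously non-negative at a feasible point, and it matches the
  reading of $(s^x, s^y, s^b)$ as redundancy / shortfall / excess.
* **Output weight.** The desirable and undesirable output terms share the
  weight $1/(M+I)$, the standard form of this measure (the two coincide at
  $M = 1, I = 1$, the headline configuration, where $M + I = M + 1$).
* **Efficiency mapping.** Only the inefficiency $S$ is defined by the
  program; the mapping $\rho = 1 - S$ is adopted because with the
  self-direction the slack ratios are shares of the unit's own levels. On
  pathological data $S$ can exceed 1; $\rho$ is then reported negative with
  a warning, never clipped silently.

**Direction.** The default direction is the evaluated unit's own
observation, $g = (x_0, y_0, b_0)$, which makes every slack ratio
dimensionless and the score invariant to units of measurement. Any
strictly positive direction can be supplied per run. For derived panels in
which frontier units have an exactly zero undesirable value (see the
decomposition below) the default direction is undefined; callers must
either supply a direction or use
`default_direction(..., on_zero = "mean")`, which substitutes the
panel-wide mean of the affected variable — a neutral, data-driven scale for
a movement the unit cannot express itself.

**Uniqueness.** The optimal score $S$ is unique, but the optimal weights
and slacks need not be (DEA programs are routinely degenerate). Only $S$
and $\rho$ are contract-guaranteed; slacks and reference sets are reported
as returned by the solver and documented as potentially non-unique.

**The solver.** The model is solved by a dense two-phase primal simplex
written for this package (`R/lp.R`): the constraint systems here have at
most a handful of rows (one per variable plus the convexity row) but
hundreds of columns, and the VRS row makes vertices degenerate, so the
pivot rule is Dantzig's with an automatic switch to Bland's anti-cycling
rule if iterations stall. Before solving, every variable is rescaled by the
evaluated unit's direction component, so all coefficients are $O(1)$
regardless of raw data magnitudes. Feasibility of the returned solution is
re-checked to $10^{-7}$; score comparisons in tests use $10^{-9}$ to
$10^{-8}$. The solver is validated against an independent oracle: after
eliminating the slacks, the program is linear in the intensity weights over
a polytope, and for instances with at most four observations every vertex
can be enumerated exhaustively; the test suite checks 200+ randomized
instances against this oracle.

## The two-stage hospitalization decomposition

Stage one computes a benchmark score $\rho_1$ with admissions treated as an
ordinary desirable output and no undesirable output; stage two computes
$\rho_2$ with admissions moved to the undesirable set. The per-province
severity of unreasonable hospitalization is

$$
\text{severity} = 100 \cdot
\frac{\bar\rho_1 - \bar\rho_2}{\bar\rho_1} \%
$$

computed from 13-year means per province (per-year severities are
available but are not the headline). A positive difference means that
accounting for hospitalization volume lowers measured efficiency; a
negative one (seen in Beijing and Shanghai in the published tables) means
inpatient care contributes positively.

Two modelling choices were genuinely open and are resolved as follows:

* **Which outputs enter $\rho_1$.** The benchmark includes admissions as a
  desirable output (not visits only), consistent with the indicator system
  in which admissions are an output in both stages; a visits-only variant
  is a one-line configuration change (`set_admission_role` is isolated).
* **The split rule.** The sources state the decomposition idea — identify
  macro-level efficiency losses through low single-output efficiency — but
  not a formula. The implemented rule solves the model with admissions as
  the *sole* desirable output, yielding $\rho_{single}$, and reads the
  inefficiency share as the unreasonable fraction:
  `reasonable = rho_single * observed`,
  `unreasonable = (1 - rho_single) * observed`. This is the simplest rule
  consistent with the stated idea, conserves admissions exactly, and is
  isolated behind `decompose_admissions()` so a slack-projection-based
  split could be swapped in. Where $\rho_{single}$ falls outside $[0, 1]$
  on pathological data it is truncated for the split (with a warning) so
  both components stay non-negative.

`build_main_panel()` then assembles the headline panel — desirable outputs
{visits, reasonable admissions}, undesirable {unreasonable admissions} —
which feeds the static summary and the GML stage.

## The GML index

For each province and adjacent year pair,

$$
GML_t^{t+1} = \frac{1 + S^G(x_t, y_t, b_t)}{1 + S^G(x_{t+1}, y_{t+1}, b_{t+1})},
\qquad
GEC_t^{t+1} = \frac{1 + S^t(x_t, y_t, b_t)}{1 + S^{t+1}(x_{t+1}, y_{t+1}, b_{t+1})},
\qquad
GTC = GML / GEC,
$$

with $S^G$ the global-frontier distance and $S^t$ the own-year
contemporaneous distance. Values above 1 signal improvement, below 1
decline. Two notes:

* GEC uses own-period contemporaneous distances. This is the standard
  global-index decomposition and the only reading under which
  $GML = GEC \times GTC$ holds together with the four-term
  technology-change expression; a printed formula that repeats the global
  distances in GEC would collapse GEC into GML itself.
* Cross-period evaluations (a unit measured against another year's
  frontier), which can be infeasible under variable returns to scale,
  never need to be solved: GTC is computed as the ratio $GML/GEC$.

Because the global frontier is common to all periods the index is circular,
$GML(t \to t+2) = GML(t \to t+1) \cdot GML(t+1 \to t+2)$; the tests verify
this from independently recomputed distances.

## Reporting conventions

Province and period means are unweighted (each province counts once), which
is what reproduces the published table averages from their printed
per-province values; population-weighted means would be a different
statistic. Computation is at full precision throughout; rounding is half-up
(`round_half_up()`) and happens only at render time. Two decimals are used
for scores and severity percentages; four decimals are available where
sub-percent index differences matter. `render_summary()` checks that the
grand mean agrees row-wise and column-wise to $10^{-12}$ before rounding.

The package ships the published province-level summary tables (scores,
mean-efficiency pairs, GML indices, 2010–2022) as plain-CSV fixtures via
`reference_table()`. The raw province-year panel behind them is not
machine-readable, so those tables act as report-layer inputs: the package
reproduces their derived statistics (row means, grand means, severity
ratios, column averages) exactly at the printed precision, while the solver
itself is validated on synthetic data and against the enumeration oracle.
The regional map is the National Bureau of Statistics three-region
classification (11 east / 8 central / 11 west provinces; Tibet, Hong Kong,
Macao and Taiwan lie outside the sample) and ships as a replaceable data
file, not hard-coded logic.

## The synthetic generator

`generate_panel()` draws a panel around a known concave variable-returns
frontier. Inputs are drawn positive (three inputs at province-like scales
by default); an aggregate input $z = a'x$ feeds concave increasing
production rules $f_m(z) = c_m z^{\gamma_m}$, $0 < \gamma_m < 1$, defining
efficient output levels. Observed desirable outputs are $u \cdot f(z)$ with
a true efficiency multiplier $u \in (0, 1]$, at least one unit per period
having $u = 1$. Because any convex combination of points on a concave
surface lies weakly below it, every $u = 1$ unit lies on the pooled VRS
frontier, so noiseless recovery is exact by construction — this is the
pipeline's primary validation surface given that the study's raw panel is
unavailable. The undesirable output follows
$b = b_0 + b_{scale}(1/u - 1)\,e^{\sigma\varepsilon}$: it grows with
inefficiency, and the small positive baseline $b_0$ keeps the bad strictly
positive even for fully efficient units so the self-direction stays
defined. A `progress` factor scales the frontier geometrically across
periods for technology-change experiments.

Default dimensions mirror the study design: 30 provinces, 13 years, 3
inputs, 2 desirable outputs, 1 undesirable output, noiseless. What the
generator does *not* emulate: the yearbook's distributional shape
(no attempt to match its descriptive statistics), serial correlation in
inputs, measurement error structure, or COVID-era shocks. Passing tests on
synthetic panels therefore demonstrate correctness of the *method* under
known truth, not empirical conclusions about China's primary healthcare
system.

Rank-recovery checks use `input_profile = "common"` (all units share one
input profile) on 1-input/1-output panels: there the score is the closed
form $S = (1-u)/(2u)$, strictly decreasing in $u$, so Kendall's $\tau$
between estimated and true efficiency must be exactly 1. With
heterogeneous inputs the non-radial score also reflects input-reduction
potential, and cross-unit rank agreement with $u$ alone is no longer a
theorem — which is why the recovery condition is pinned to the common-input
design.

## The forecast harness

The harness is deliberately model-agnostic: its contribution surface is the
protocol — a strictly sequential split (the last $n$ years form the test
tail; with 33 years and $n = 4$, training runs 1990–2018 and testing
2019–2022), single-time-step lag features built only from past values, the
four error metrics, and a *direct* multi-step strategy (one model per
horizon step, each predicting from the last observed value, never from its
own predictions; the recursive strategy is available for comparison).
Regressors are pluggable fit/predict contracts; a persistence baseline and
an OLS contract keep the harness fully testable with no machine-learning
dependency, and wrappers for random forest, support-vector regression and
the lasso attach when those packages are installed. A single integer seed
is threaded to any stochastic regressor and recorded in the output.
Published headline forecast numbers (the random-forest test metrics and the
2029 projection) depend on the yearbook series, which is not printed, and
are therefore out of scope; the harness is validated on synthetic series
and hand-computable metric cases.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full 30 × 13 design for
the GML identities (780 linear programs), 200 randomized oracle
comparisons, and smaller panels (2–10 units, 1–3 periods) for worked
examples and property checks — sizes at which the dense simplex solves each
program in milliseconds and the whole suite completes in seconds on one
core. Larger pools scale linearly in solve count and roughly linearly in
pool size per solve.

## Known limitations

* The severity construct is strictly the model-defined efficiency notion;
  no clinical adjudication of admission appropriateness is implied.
* Slacks and reference sets are non-unique under alternate optima.
* Missing data are rejected, not imputed.
* No data standardization is applied before solving: the score is invariant
  to rescaling any variable together with its direction component (verified
  by a property test), so z-scoring or unit changes cannot alter $S$.
* The shipped reference tables are printed at two decimals; statistics
  derived from them are reproduced at that precision, and third-decimal
  discrepancies in prose values (e.g. a 0.807 vs 0.809 mean) are below the
  resolution of the printed data.
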