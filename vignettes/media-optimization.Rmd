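---
title: "Modelling and optimizing pear micropropagation media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing pear micropropagation media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearmedia)
```

## The problem

In vitro proliferation of pear rootstocks (here Pyrodwarf and OHF, two
*Pyrus communis* dwarfing rootstocks) depends strongly on the mineral and
hormone composition of the culture medium. The experiments behind this
package varied six components — KNO~3~, NH~4~NO~3~, the "mesos" salt group
(CaCl~2~, KH~2~PO~4~, MgSO~4~), the micronutrient group, and the hormones
BAP and IBA — over a six-factor, three-level Box–Behnken design (BBD) of 48
media, plus three control media (MS, WPM, QL). Five responses were scored
per medium: proliferation rate (PR, shoots per explant), shoot length (SL,
cm), shoot-tip necrosis (STN, %), vitrification (Vitri, %), and a 1–5
quality index (QI).

Three model families map media composition to response: symbolic regression
by gene expression programming (GEP), a Gaussian radial-basis-function
network (RBFNN), and multiple linear regression (MLR). Fitted surfaces are
then searched by a real-coded genetic algorithm (GA) for compositions that
maximize PR, SL and QI or minimize STN and Vitri.

## The designed experiment

`bbd_generate(k)` builds the edge-run BBD: each block of factors is varied
over all $\pm 1$ combinations while the others sit at their mid level. For
six factors the classical blocking varies factors three at a time over six
blocks, giving exactly 48 runs, which is the design actually used — it
contains no centre runs, so `n_center` defaults to 0 (an edge-only BBD;
note that without centre runs the six quadratic effects are not jointly
estimable, which is why `fit_mlr(quadratic = TRUE)` refuses the packaged
design). The literal 48-run table ships as a fixture
(`load_paper_design()`) and analyses default to it so that results are
anchored to the experiment as printed; printed levels are rounded (IBA mid
0.125 prints as 0.13), so actual-to-coded matching uses a 0.01 tolerance.

```{r design}
head(load_paper_design(), 3)
```

## Data, and what the synthetic generator does

The packaged datasets (`load_dataset()`) are the published *per-medium
means* for the 51 media of each rootstock. The modelling protocol, however,
operates on replicate-level records: at least ten replicate jars per
medium, 510 observations, split 70/30 into 357 training and 153 test
records. The replicate-level raw data were never published, so
`generate_replicates()` emulates them: a ground-truth surface (by default
the published equations via `spec_from_published()`) plus Gaussian noise,
clipped to each response's admissible range (STN/Vitri to [0, 100], QI to
[1, 5], PR/SL to non-negative), with PR rounded to quarter-shoot resolution
to mimic count averaging (skipped at zero noise so the noiseless generator
is exactly the clipped ground truth). Replicate noise SDs are not
derivable from the published tables; the default is 10% of each response's
observed range, overridable per response.

What passing tests on synthetic data show: that the estimators and the
pipeline behave correctly when their assumptions hold (smooth bounded
surfaces, independent Gaussian replicate noise). What they do not show:
that real replicate variation is Gaussian or homoscedastic, nor anything
about biological validity of the fitted surfaces beyond the printed means.

## The published equations, and two hard transcription problems

The ten published GEP equations are hard-coded (`published_model()`), each
the sum of three gene sub-expressions (three genes linked by addition),
with constants at full printed precision. Two genuinely open choices had to
be resolved against the data:

**Factor-symbol mapping.** The published footnote glosses the equation
symbols as A = NH~4~NO~3~, B = KNO~3~. Scored against the published
per-medium means, that mapping gives correlations far below the published
fit statistics, while the swapped mapping A = KNO~3~, B = NH~4~NO~3~ — the
column order of every data table — reproduces the published $r^2$ closely
for six of the ten equations. The package therefore uses the data-table
order throughout and reads the published optimization table's first two
columns the same way (the two readings are numerically equivalent for the
optimization rows when applied consistently).

```{r mapping-evidence}
d <- load_dataset("Pyrodwarf")[1:48, ]
pred <- predict_published("Pyrodwarf", "STN", d)      # A = KNO3 mapping
compute_metrics(d$STN, pred)$r_squared                 # published: 0.954
swapped <- d
swapped[c("KNO3", "NH4NO3")] <- d[c("NH4NO3", "KNO3")]
compute_metrics(d$STN, predict_published("Pyrodwarf", "STN", swapped))$r_squared
```

**Protected-operator convention.** The printed equations contain square
roots, logarithms and inverses whose arguments go negative or cross zero
inside the factor box (e.g. the Pyrodwarf PR equation contains
$\sqrt{(E - 2.1016)/2}$ with BAP as low as 0.5, feeding
$1/\ln(\cdot)$). Every evaluation is therefore protected; two total
conventions are implemented (see `?function_table`):

* `"abs"` — $\sqrt{|x|}$, even roots of $|x|$, sign-preserving odd roots,
  $\ln\max(|x|, \varepsilon)$, denominators clamped to magnitude
  $\varepsilon = 10^{-9}$, $e^x$ clamped at $|x| \le 50$.
* `"complex"` — principal complex branches for even roots and logarithms,
  real signed odd roots, the same $\varepsilon$ clamps, real part taken
  once at the end.

The two agree wherever intermediate values stay non-negative — which is
everywhere for eight of the ten equations at their published optimal
compositions. They differ for the Pyrodwarf PR equation: `"abs"`
reproduces that equation's fit to the observed means ($r^2 \approx 0.90$)
but evaluates to 14.16 at the published optimal composition (printed:
13.00) and has a pole of $1/\ln(\cdot)$ inside the box; `"complex"`
evaluates to 12.59 there (−3.1%, consistent with the 2-decimal rounding of
the printed composition, to which the value is very sensitive) and bounds
the pole. The package's reading: the model-fitting software evaluated
$\sqrt{|x|}$ while the optimization stage ran in complex arithmetic.
Consequently `"abs"` is the package default (and the convention used for
goodness-of-fit work), while reproduction of the published optimization
table uses `"complex"`; both are explicit arguments everywhere.

```{r conventions}
x_opt <- factor_vector(1.56, 1.19, 1.75, 3.28, 2.08, 0.13)
predict_published("Pyrodwarf", "PR", x_opt, convention = "abs")
predict_published("Pyrodwarf", "PR", x_opt, convention = "complex")
```

**What does not reproduce.** The OHF PR equation as typeset evaluates to
3.62 at its published optimum (printed: 9.42) and is uncorrelated with its
own training data ($r^2 < 0.01$) under every convention and mapping tried;
structurally its BAP dependence is monotone while the observed PR peaks at
mid BAP, so no re-reading of signs or precedence can rescue it — the
typeset equation is evidently corrupted. The OHF QI equation and the
data-fit (not the optima) of both SL equations show similar, milder
problems. The affected checks in the acceptance suite are left failing
with this analysis rather than being loosened. Likewise, the published
Pyrodwarf PR optimum (13.00) is *not* the global maximum of the printed
equation: the GA here reliably finds ≈ 25.3 ("complex") at the
$1/\ln$ ridge near BAP ≈ 2.10, and the supremum under "abs" is
$\varepsilon^{-1}$-scale at the pole. The honest best-found value is
reported as computed.

## The GEP engine

`evolve()` implements symbolic regression with fixed-length multigenic
genomes. Defaults follow the published run settings: 50 chromosomes, head
length $h = 8$, 3 genes linked by addition, per-symbol mutation 0.044,
inversion 0.1, one-point/two-point/gene recombination 0.1/0.3/0.1, gene
transposition 0.1, RRSE fitness. Structural guarantees: the tail holds
terminals only and has length $h(a_{\max} - 1) + 1$, so every genome
decodes to a valid tree (`karva_decode()`, breadth-first open reading
frame; verified against an independent level-order decoder).

Choices the published settings leave open, and how they were resolved:

* **Selection.** Roulette-wheel sampling with elitism is retained, but the
  wheel spins over squared-rank weights (`selection_weights()`) rather than
  a direct transform of RRSE: transforms like $1000/(1 + \mathrm{RRSE})$
  become nearly flat once the population improves, and the measured
  selection intensity is then too weak against the disruptive operator
  rates (the population stays in mutation–selection balance at high
  error). Rank-based wheels are a standard remedy and keep the sampling
  mechanism itself unchanged.
* **Extra transposition operators.** Insertion-sequence (IS) and
  root-IS transposition, the classical head-rearrangement operators of
  this method family, are included at rate 0.1 (the published parameter
  table does not list them; the accompanying text mentions a "rotation"
  operator without parameters). They measurably improve structural search.
* **Restarts.** The generation budget is not published ("run until no
  significant improvement"). `evolve()` runs up to `generations` in total
  and reinitializes the population whenever the current population's best
  RRSE stalls for `stop_window` (default 75) generations; the best
  chromosome ever seen is archived and returned, so the reported best is
  monotone.
* **Constants.** The published equations contain numeric constants, so the
  terminal set includes an ephemeral-constant slot drawn uniformly from
  [−10, 10], redrawn on mutation. The published constant mechanism is
  undocumented; this is a deviation surface.
* **Elitism count** 1; ties break first-encountered under a fixed
  iteration order.

On the noiseless recovery benchmark — target $(A+B)(C-D)$ on the 48-run
design, function set $\{+, -, \times\}$, population 100, budget 1500
generations — the engine reaches RRSE < 0.01 in at least 8 of 10 seeds
(the acceptance suite runs exactly this).

## RBFNN and MLR baselines

`train_rbf()` standardizes inputs, places Gaussian centers by k-means,
sets each width to the distance to the nearest other center, and trains
output weights and bias by full-batch gradient descent on MSE (centers and
widths stay fixed, matching the published description; the garbled printed
kernel formula is implemented as the standard
$\exp(-\lVert x - c\rVert^2 / 2\sigma^2)$). Hidden-unit count, learning
rate and epochs are not published; `select_rbf()` picks the unit count by
held-out RMSE. Reproducing a noiseless replicate-level surface to
$r^2 > 0.9$ needs roughly one unit per medium and ~2 × 10⁴ epochs, which
is what the corresponding test uses.

`fit_mlr()` is main-effects ordinary least squares via `stats::lm` (the
published linear model has no interaction or quadratic terms; a quadratic
expansion is available but off by default), with an explicit rank check
that names collinear columns. Tests verify the fit against the normal
equations directly.

## Model comparison

`compute_metrics()` reports RMSE, MARE, MBE and the correlation between
observation and prediction. Two printed-formula quirks: the published
"R²" formula is an unsquared Pearson correlation, so both `r` and
`r_squared` are reported; and MARE is undefined at zero observations
(STN/Vitri contain legitimate zeros), so those terms are excluded and
counted in `n_excluded_mare`. `compare_models()` ranks by RMSE with
`r_squared` as tie-break.

## GA optimization

`optimize_media()` is a real-coded GA over the factor box (one gene per
factor): rank-weighted roulette selection (plain fitness-proportional
selection misbehaves under sign changes and minimization, so ranks are
used for both senses), uniform crossover at rate 0.9, per-gene Gaussian
mutation at rate 0.1 with SD 10% of each factor's range, clipping to
bounds, elitism 2, and 10 independent restarts — these defaults were
chosen for reliable convergence on smooth 6-D objectives (the concave
quadratic benchmark recovers its argmax to 1% of range per coordinate) and
are all configurable. The returned optimum is re-evaluated at the returned
composition, so the reported value is exactly reproducible. The BAP upper
bound is 3.0 mg/l, following the design tables (one summary table prints
2.5, but the design itself and the published optimization setup use 3.0).

`optimize_all()` runs the five responses with their senses
(PR/SL/QI maximized, STN/Vitri minimized). One published inconsistency is
carried as metadata: the results text attributes the QI optima to RBFNN
models while the optimization table's caption says GEP; the package
optimizes the published GEP QI equations and flags this in the table
attribute `note`.

## Numerical choices, in one place

$\varepsilon = 10^{-9}$ for denominator/log clamps; $e^x$ argument clamp
±50; level-matching tolerance 0.01 between printed and exact design
levels; GEP fitness tolerance for "solved" 10⁻⁹; stagnation tolerance
10⁻⁶ over 75 generations; split sizes are `round(n × fraction)`; all
randomness flows through explicit integer seeds, and every seeded helper
restores the caller's RNG state.

## Problem sizes used by the test suite

Tests run at the scale of the original experiment where that is cheap (48
and 51-row tables, 510-record synthetic sets) and at reduced scale where
it is not: GEP property tests use populations of 40–100 and budgets of
60–1500 generations; the RBF surface test uses one 20 000-epoch fit; the
GA benchmarks use populations of 30–100 for 25–200 generations. These
sizes were chosen so each property is demonstrated with comfortable
margin.

## Known limitations

* Four of the ten published equations cannot be fully reconciled with the
  published data or optima (see above); their transcriptions are faithful
  to the typesetting and the discrepancies are surfaced, not patched.
* The engine does not attempt to reproduce the original software's random
  streams or internal operator implementations, only the method.
* Synthetic replicates are Gaussian and independent; real jar-level data
  are counts, percentages and ordinal scores with likely heteroscedastic,
  correlated errors.
* The GA optimizes one response at a time; joint (multi-objective)
  optimization of, say, PR and QI is out of scope.
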