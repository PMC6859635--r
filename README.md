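# pearmedia

Response-surface modelling and evolutionary optimization of in vitro
proliferation media for the pear rootstocks **Pyrodwarf** and **OHF**.

Designing a tissue-culture medium means choosing the levels of several
interacting mineral and hormone components at once. The experiments this
package re-analyzes varied six components — KNO₃, NH₄NO₃, the mesos salt
group (CaCl₂ + KH₂PO₄ + MgSO₄), the micronutrient group, BAP and IBA —
over a six-factor, three-level Box–Behnken design of 48 media (plus MS,
WPM and QL controls) and scored five growth responses per medium:
proliferation rate (PR, shoots per explant), shoot length (SL, cm),
shoot-tip necrosis (STN, %), vitrification (Vitri, %), and a 1–5 quality
index (QI). The package is for plant-biotech researchers who want to fit
and compare surrogate models of such designed experiments and search them
for optimal media.

## What it implements

* **Box–Behnken designs** — `bbd_generate(k)` (edge-run set; 48 runs for
  k = 6), coded↔actual conversion, and the literal 48-run design as a
  packaged fixture.
* **Gene expression programming (GEP)** — `evolve()`: symbolic regression
  with fixed-length multigenic Karva genomes. A gene of head length *h*
  has a terminals-only tail of length *h*(a<sub>max</sub> − 1) + 1 and
  decodes breadth-first into an expression tree; a chromosome's phenotype
  is the addition-linked fold of its gene trees, and fitness is the root
  relative squared error RRSE = √(Σ(P−O)² / Σ(O−Ō)²). Selection is
  roulette-wheel with elitism; variation uses per-symbol mutation,
  inversion, one/two-point and gene recombination and three transposition
  operators.
* **The ten published GEP media equations** — `published_model()` /
  `predict_published()`: faithful transcriptions, each the sum of three
  gene terms, evaluated under protected-operator rules (two documented
  conventions; see the methods vignette).
* **RBF network and MLR baselines** — `train_rbf()` (Gaussian units,
  k-means centers, gradient-descent output weights) and `fit_mlr()`
  (main-effects OLS).
* **Model comparison** — `compute_metrics()`: RMSE, MARE (zero
  observations excluded and counted), MBE = mean(O−P), and the Pearson
  correlation r with r².
* **GA media optimization** — `optimize_media()` / `optimize_all()`:
  real-coded, bound-constrained genetic algorithm (uniform crossover,
  Gaussian mutation clipped to the factor box, elitism, restarts) that
  maximizes PR/SL/QI and minimizes STN/Vitri.
* **Synthetic replicate generator** — `generate_replicates()` /
  `spec_from_published()`: replicate-level observations (51 media × 10
  jars = 510 records) from a known surface plus clipped Gaussian noise,
  so the whole pipeline is testable end to end.
* **Pipeline** — `run_pipeline()` orchestrates load → split (70/30) →
  fit → evaluate → optimize and writes CSV/JSON artifacts; a thin CLI
  lives in `inst/cli/pearmedia.R`.

## Worked example

Score a published equation against the packaged data, evaluate it at a
published optimal composition, and re-find an optimum by GA:

```r
library(pearmedia)

d <- load_dataset("Pyrodwarf")
pred <- predict_published("Pyrodwarf", "STN", d[1:48, ])
compute_metrics(d$STN[1:48], pred)
#> RMSE 2.3142  MARE 0.1136  MBE -0.8534  r2 0.9679  (n = 48, 6 zero-observation term(s) excluded from MARE)

x <- factor_vector(1.83, 0.51, 1.74, 2.60, 0.59, 0.16)  # published SL optimum
predict_published("Pyrodwarf", "SL", x, convention = "complex")
#> [1] 5.019018   # printed optimum: 5.00

tree <- published_model("Pyrodwarf", "QI")
res <- optimize_media(function(df) evaluate_tree(tree, df, convention = "complex"),
                      ga_config(population_size = 60, generations = 80,
                                restarts = 3, sense = "maximize", seed = 1),
                      vectorized = TRUE)
res
#> <optimization_result> maximized value: 4.98861
#>   KNO3 NH4NO3  mesos minors    BAP    IBA
#>  0.885  0.500  2.500  4.000  0.500  0.050
```

The GA lands on the same composition as the published QI optimum (printed:
4.99 at 0.89, 0.50, 2.50, 4.00, 0.50, 0.05): low nitrogen, high mesos and
micronutrients, minimal hormones give the highest-quality Pyrodwarf
plantlets. The fit above reproduces the published STN accuracy
(r² ≈ 0.97) once the equations' factor symbols are read in data-table
order — one of several transcription issues the vignette documents.

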