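test_that("a one-dimensional quadratic optimum is located", {
  cfg <- ga_config(population_size = 40, generations = 60, restarts = 2,
                   sense = "maximize", seed = 1)
  res <- optimize_media(function(x) -(x[["KNO3"]] - 1)^2, cfg)
  expect_lt(abs(res$best_x[["KNO3"]] - 1), 0.02)
  expect_lt(abs(res$best_value), 1e-3)
})

test_that("a six-dimensional concave quadratic argmax is recovered", {
  b <- factor_bounds()
  center <- (b$lo + b$hi) / 2
  obj <- function(df) -rowSums(sweep(as.matrix(df), 2, center)^2)
  ok <- vapply(1:10, function(seed) {
    cfg <- ga_config(population_size = 60, generations = 80, restarts = 1,
                     sense = "maximize", seed = seed)
    res <- optimize_media(obj, cfg, vectorized = TRUE)
    all(abs(res$best_x - center) <= 0.01 * (b$hi - b$lo))
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("maximization and minimization are dual", {
  tree <- published_model("OHF", "Vitri")
  f <- function(df) evaluate_tree(tree, df)
  for (seed in 1:5) {
    up <- optimize_media(f, ga_config(population_size = 30, generations = 30,
                                      restarts = 1, sense = "maximize",
                                      seed = seed), vectorized = TRUE)
    dn <- optimize_media(function(df) -f(df),
                         ga_config(population_size = 30, generations = 30,
                                   restarts = 1, sense = "minimize",
                                   seed = seed), vectorized = TRUE)
    expect_equal(up$best_x, dn$best_x)
    expect_equal(up$best_value, -dn$best_value)
  }
})

test_that("every evaluated candidate stays inside the bounds box", {
  b <- factor_bounds()
  seen_bad <- FALSE
  obj <- function(df) {
    m <- as.matrix(df)
    out_of_box <- any(sweep(m, 2, b$lo, "<")) | any(sweep(m, 2, b$hi, ">"))
    seen_bad <<- seen_bad || out_of_box
    rowSums(m)
  }
  cfg <- ga_config(population_size = 50, generations = 50, restarts = 2,
                   mutation_rate = 0.9, mutation_scale = 1, seed = 2)
  invisible(optimize_media(obj, cfg, vectorized = TRUE))
  expect_false(seen_bad)
})

test_that("the per-restart trace is monotone in the optimization sense", {
  tree <- published_model("Pyrodwarf", "QI")
  f <- function(df) evaluate_tree(tree, df)
  res <- optimize_media(f, ga_config(population_size = 40, generations = 40,
                                     restarts = 3, sense = "maximize",
                                     seed = 6), vectorized = TRUE)
  for (rs in unique(res$trace$restart)) {
    tr <- res$trace$best[res$trace$restart == rs]
    expect_true(all(diff(tr) >= 0))
  }
  expect_error(optimize_media(function(df) rep(NA_real_, nrow(df)),
                              ga_config(restarts = 1, generations = 2),
                              vectorized = TRUE), "non-finite")
})

test_that("optimize_all covers the five responses with correct senses", {
  cfg <- ga_config(population_size = 30, generations = 25, restarts = 1,
                   seed = 3)
  tab <- optimize_all("OHF", cfg)
  expect_equal(tab$response, response_names())
  expect_equal(tab$sense[tab$response %in% c("STN", "Vitri")],
               rep("minimize", 2))
  expect_equal(tab$sense[tab$response %in% c("PR", "SL", "QI")],
               rep("maximize", 3))
  expect_true(all(c(factor_names(), "optimum") %in% names(tab)))
  # reported optima are re-evaluations of the reported compositions
  results <- attr(tab, "results")
  for (rp in response_names()) {
    r <- results[[rp]]
    expect_equal(r$best_value,
                 predict_published("OHF", rp, r$best_x,
                                   convention = "complex"))
  }
})
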