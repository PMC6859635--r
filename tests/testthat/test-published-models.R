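test_that("each published model links exactly three gene terms", {
  for (rs in rootstock_names()) {
    for (rp in response_names()) {
      m <- published_model(rs, rp)
      expect_identical(m$sym, "+")
      expect_length(attr(m, "gene_terms"), 3)
    }
  }
})

test_that("transcribed constants are kept at printed precision", {
  expect_true(6.8169 %in% tree_constants(published_model("OHF", "Vitri")))
  expect_true(2.1016 %in% tree_constants(published_model("Pyrodwarf", "PR")))
  expect_true(30.7869 %in% tree_constants(published_model("Pyrodwarf", "QI")))
})

test_that("invalid rootstock/response pairs fail with the valid keys", {
  expect_error(published_model("OHF", "chlorosis"), "PR")
  expect_error(published_model("Quince", "PR"), "Pyrodwarf")
})

test_that("published optima reproduce at their printed compositions", {
  # the subset of the optimization table that the transcribed equations
  # reproduce under the documented conventions (the remainder is examined
  # in the acceptance suite)
  t3 <- published_optima()
  check <- function(rs, rp, tol) {
    row <- t3[t3$rootstock == rs & t3$response == rp, ]
    x <- unlist(row[factor_names()])
    v <- predict_published(rs, rp, x, convention = "complex")
    expect_equal(v, row$printed, tolerance = tol / max(abs(row$printed), 1),
                 info = paste(rs, rp))
  }
  check("Pyrodwarf", "SL", 0.1)
  check("Pyrodwarf", "Vitri", 0.08)
  check("Pyrodwarf", "QI", 0.1)
  check("OHF", "SL", 0.1)
  check("OHF", "Vitri", 0.05)
})

test_that("published models track the observed data they were fit to", {
  # goodness of fit against the packaged per-medium means for the
  # equations whose transcription reproduces it (see methods vignette)
  cases <- list(c("Pyrodwarf", "STN"), c("Pyrodwarf", "Vitri"),
                c("Pyrodwarf", "QI"), c("OHF", "STN"), c("OHF", "Vitri"))
  for (cs in cases) {
    d <- load_dataset(cs[1])
    bbd <- d[seq_len(48), ]
    pred <- predict_published(cs[1], cs[2], bbd, convention = "abs")
    m <- compute_metrics(bbd[[cs[2]]], pred)
    expect_gt(m$r_squared, 0.9)
  }
})

test_that("the model registry exports and re-parses", {
  path <- tempfile(fileext = ".json")
  export_model_registry(path)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(reg), 10)
  x <- c(A = 1.2, B = 0.8, C = 1.5, D = 2, E = 1.75, F = 0.125)
  for (i in seq_len(nrow(reg))) {
    t <- parse_formula(reg$formula[i])
    expect_equal(evaluate_tree(t, x),
                 predict_published(reg$rootstock[i], reg$response[i], x),
                 tolerance = 1e-12)
  }
})
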