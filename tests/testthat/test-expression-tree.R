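test_that("basic tree arithmetic matches hand computation", {
  t <- parse_formula("((A + B) * (C - D))")
  x <- c(A = 1, B = 2, C = 5, D = 3, E = 1, F = 0.1)
  expect_identical(evaluate_tree(t, x), 6)
})

test_that("protected operators are total with the documented conventions", {
  x <- c(A = -4, B = 0, C = 0.5, D = 1, E = 1, F = 1)
  expect_equal(evaluate_tree(parse_formula("sqrt(A)"), x), 2)
  expect_true(is.finite(evaluate_tree(parse_formula("inv(B)"), x)))
  expect_true(is.finite(evaluate_tree(parse_formula("ln(B)"), x)))
  expect_true(is.finite(evaluate_tree(parse_formula("(A / B)"), x)))
  expect_equal(evaluate_tree(parse_formula("exp(A)"), x), exp(-4))
  # exp clamps its argument rather than overflowing
  big <- c(A = 1e6, B = 1, C = 1, D = 1, E = 1, F = 1)
  expect_true(is.finite(evaluate_tree(parse_formula("exp(A)"), big)))
  expect_equal(evaluate_tree(parse_formula("cbrt(A)"), x),
               -abs(-4)^(1 / 3))
})

test_that("complex convention returns the real part of principal branches", {
  x <- c(A = -4, B = 1, C = 1, D = 1, E = 1, F = 1)
  # principal sqrt of -4 is 2i, real part 0
  expect_equal(evaluate_tree(parse_formula("sqrt(A)"), x,
                             convention = "complex"), 0)
  # odd roots stay real and signed under both conventions
  expect_equal(evaluate_tree(parse_formula("cbrt(A)"), x,
                             convention = "complex"), -abs(-4)^(1 / 3))
  # conventions agree when all arguments stay non-negative
  set.seed(1)
  xf <- random_factor_frame(50)
  t <- parse_formula("(sqrt((A + B)) + ln((C * D)))")
  expect_equal(evaluate_tree(t, xf, convention = "abs"),
               evaluate_tree(t, xf, convention = "complex"))
})

test_that("unknown symbols and arity mismatches are rejected by name", {
  expect_error(tree_leaf("Z"), "Z")
  expect_error(tree_node("nope", tree_leaf("A")), "nope")
  expect_error(tree_node("sqrt", tree_leaf("A"), tree_leaf("B")), "sqrt")
  bad <- structure(list(sym = "+", children = list(tree_leaf("A"))),
                   class = "gep_tree")
  expect_error(validate_tree(bad), "arity")
  x <- c(A = 1, B = 1, C = 1, D = 1, E = 1, F = 1)
  bad2 <- structure(list(sym = "zap", children = list()),
                    class = "gep_tree")
  expect_error(evaluate_tree(bad2, x), "zap")
})

test_that("formula rendering round-trips through the parser", {
  x <- c(A = 1.3, B = 0.7, C = 2.1, D = 3.3, E = 1.1, F = 0.11)
  expect_identical(to_formula_string(tree_leaf("A")), "A")
  expect_identical(gsub(" ", "", to_formula_string(
    tree_node("avg2", tree_leaf("A"), tree_leaf("B")))), "((A+B)/2)")
  set.seed(42)
  for (i in 1:200) {
    t1 <- random_test_tree(3)
    t2 <- parse_formula(to_formula_string(t1))
    expect_equal(evaluate_tree(t2, x), evaluate_tree(t1, x),
                 tolerance = 1e-12)
  }
})

test_that("evaluation is deterministic and vectorized", {
  t <- published_model("Pyrodwarf", "Vitri")
  set.seed(7)
  xf <- random_factor_frame(25)
  v1 <- evaluate_tree(t, xf)
  v2 <- evaluate_tree(t, xf)
  expect_identical(v1, v2)
  expect_length(v1, 25)
  single <- vapply(seq_len(25), function(i) {
    evaluate_tree(t, unlist(xf[i, ]))
  }, numeric(1))
  expect_equal(v1, single)
})

test_that("evaluate_tree agrees with an independent evaluation oracle", {
  set.seed(11)
  for (i in 1:1000) {
    t <- random_test_tree(3)
    x <- unlist(random_factor_frame(1)[1, ])
    got <- evaluate_tree(t, x)
    want <- oracle_eval(t, x)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("every published model is finite across the whole design box", {
  set.seed(123)
  xf <- random_factor_frame(10000)
  for (rs in rootstock_names()) {
    for (rp in response_names()) {
      for (conv in c("abs", "complex")) {
        v <- predict_published(rs, rp, xf, convention = conv)
        expect_true(all(is.finite(v)),
                    info = paste(rs, rp, conv))
      }
    }
  }
})
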