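test_that("datasets load with printed values and record counts", {
  ohf <- load_dataset("OHF")
  pyr <- load_dataset("Pyrodwarf")
  expect_equal(nrow(ohf), 51)
  expect_equal(nrow(pyr), 51)
  expect_equal(unname(unlist(ohf[1, c("PR", "SL", "STN", "Vitri", "QI")])),
               c(2.00, 4.51, 0, 0, 5.00))
  r46 <- pyr[pyr$medium_id == "46", ]
  expect_equal(unname(unlist(r46[c("PR", "SL", "STN", "Vitri", "QI")])),
               c(12.08, 2.25, 12.00, 17.80, 3.48))
  ms <- pyr[pyr$medium_id == "MS", ]
  expect_equal(ms$PR, 3.53)
  expect_equal(ms$SL, 3.99)
  expect_error(load_dataset("Quince"), "rootstock")
})

test_that("responses respect their stated ranges", {
  for (rs in rootstock_names()) {
    d <- load_dataset(rs)
    expect_true(all(d$PR >= 0))
    expect_true(all(d$SL >= 0))
    expect_true(all(d$STN >= 0 & d$STN <= 100))
    expect_true(all(d$Vitri >= 0 & d$Vitri <= 100))
    expect_true(all(d$QI >= 1 & d$QI <= 5))
  }
})

test_that("every record's factor levels come from the design or controls", {
  des <- load_paper_design()
  key <- function(df) do.call(paste, c(df[factor_names()], sep = "|"))
  design_keys <- key(des)
  control <- paste(c(1, 1, 1, 1, 2.5, 0.2), collapse = "|")
  for (rs in rootstock_names()) {
    d <- load_dataset(rs)
    expect_true(all(key(d) %in% c(design_keys, control)))
  }
})

test_that("fixture corruption is detected", {
  path <- system.file("extdata", "ohf_media_means.csv", package = "pearmedia")
  tmp <- file.path(tempdir(), "ohf_media_means.csv")
  writeLines(c(readLines(path), "junk"), tmp)
  expect_error(pearmedia:::check_fixture_digest(tmp), "integrity")
})

test_that("train/test split sizes, disjointness and determinism hold", {
  recs <- data.frame(id = 1:510, y = rnorm(510))
  sp <- split_train_test(recs, 0.7, seed = 5)
  expect_equal(nrow(sp$train), 357)
  expect_equal(nrow(sp$test), 153)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), recs$id)
  sp2 <- split_train_test(recs, 0.7, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(recs, 0.7, seed = 6)
  expect_false(identical(sp$train$id, sp3$train$id))
  small <- split_train_test(data.frame(y = 1:10), 0.7, seed = 1)
  expect_equal(nrow(small$train), 7)
  expect_error(split_train_test(recs, 1.2, seed = 1), "train_fraction")
  expect_error(split_train_test(recs[0, , drop = FALSE], 0.5, 1),
               "non-empty")
})

test_that("splitting does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(split_train_test(data.frame(y = 1:20), 0.5, seed = 3))
  b <- runif(1)
  expect_identical(a, b)
})
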