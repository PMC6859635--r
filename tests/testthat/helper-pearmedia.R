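# Shared fixtures and independent oracles for the test suite.

# 48-run design in actual units, with factor-name columns
bbd_actual_design <- function() {
  d <- as.data.frame(code_to_actual(bbd_generate(6)))
  names(d) <- factor_names()
  d
}

# The published optimization table: printed optimum and the factor levels
# of each row, in design-table column order (KNO3 first).
published_optima <- function() {
  rows <- list(
    list("Pyrodwarf", "PR",   13.00, c(1.56, 1.19, 1.75, 3.28, 2.08, 0.13)),
    list("Pyrodwarf", "SL",    5.00, c(1.83, 0.51, 1.74, 2.60, 0.59, 0.16)),
    list("Pyrodwarf", "STN",   0.00, c(0.93, 0.50, 2.30, 0.64, 0.51, 0.07)),
    list("Pyrodwarf", "Vitri", 4.00, c(0.50, 0.50, 2.50, 2.76, 0.50, 0.05)),
    list("Pyrodwarf", "QI",    4.99, c(0.89, 0.50, 2.50, 4.00, 0.50, 0.05)),
    list("OHF", "PR",    9.42, c(2.00, 1.19, 0.62, 2.13, 1.59, 0.17)),
    list("OHF", "SL",    4.99, c(0.90, 1.35, 2.04, 3.45, 1.81, 0.10)),
    list("OHF", "STN",   0.02, c(1.08, 0.51, 1.58, 2.36, 1.93, 0.15)),
    list("OHF", "Vitri", 0.02, c(0.50, 1.27, 1.49, 1.52, 1.32, 0.14)),
    list("OHF", "QI",    4.84, c(0.99, 0.53, 1.86, 2.12, 2.59, 0.18))
  )
  do.call(rbind, lapply(rows, function(r) {
    cbind(data.frame(rootstock = r[[1]], response = r[[2]],
                     printed = r[[3]], stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(as.list(r[[4]])), factor_names()))
  }))
}

random_factor_frame <- function(n) {
  b <- factor_bounds()
  out <- as.data.frame(lapply(seq_len(nrow(b)), function(j) {
    stats::runif(n, b$lo[j], b$hi[j])
  }))
  names(out) <- LETTERS[1:6]
  out
}

# random expression tree over a restricted symbol set
random_test_tree <- function(depth = 3,
                             funcs = c("+", "-", "*", "/", "sqrt", "cbrt",
                                       "exp", "ln", "inv", "sq", "tanh",
                                       "avg2"),
                             p_const = 0.3) {
  tab <- function_table()
  if (depth == 0 || stats::runif(1) < 0.25) {
    if (stats::runif(1) < p_const) {
      return(tree_const(round(stats::runif(1, -5, 5), 4)))
    }
    return(tree_leaf(sample(LETTERS[1:6], 1)))
  }
  sym <- sample(funcs, 1)
  kids <- replicate(tab[[sym]]$arity,
                    random_test_tree(depth - 1, funcs, p_const),
                    simplify = FALSE)
  do.call(tree_node, c(list(sym), kids))
}

# Independent evaluation oracle: render the tree to its formula string and
# let R's own evaluator compute it, with the protected rules defined here
# from scratch (a code path disjoint from evaluate_tree's recursion).
oracle_eval <- function(tree, x) {
  eps <- 1e-9
  guard <- function(b) {
    s <- ifelse(b == 0, 1, sign(b))
    ifelse(abs(b) < eps, s * eps, b)
  }
  env <- list2env(as.list(x))
  env$sqrt <- function(v) abs(v)^0.5
  env$cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
  env$root4 <- function(v) abs(v)^0.25
  env$root6 <- function(v) abs(v)^(1 / 6)
  env$root9 <- function(v) sign(v) * abs(v)^(1 / 9)
  env$ln <- function(v) log(pmax(abs(v), eps))
  env$inv <- function(v) 1 / guard(v)
  env$exp <- function(v) base::exp(pmin(pmax(v, -50), 50))
  env$sq <- function(v) v * v
  env$cube <- function(v) v * v * v
  env$avg2 <- function(a, b) (a + b) / 2
  env$`/` <- function(a, b) base::`/`(a, guard(b))
  eval(str2lang(to_formula_string(tree)), envir = env)
}

# Independent Karva decoder: builds the tree level by level (the width of
# level k+1 is the arity sum of level k), then assembles recursively --
# a different algorithm from the package's positional decoder.
oracle_decode <- function(gene) {
  tab <- function_table()
  syms <- gene$symbols
  ar <- vapply(syms, function(s) {
    if (is.null(tab[[s]])) 0L else as.integer(tab[[s]]$arity)
  }, integer(1))
  levels <- list(1L)
  repeat {
    cur <- levels[[length(levels)]]
    width <- sum(ar[cur])
    if (width == 0) break
    start <- max(cur) + 1L
    levels[[length(levels) + 1L]] <- seq(start, start + width - 1L)
  }
  build <- function(lvl, slot) {
    i <- levels[[lvl]][slot]
    s <- syms[i]
    if (identical(s, "?")) return(tree_const(gene$consts[i]))
    if (ar[i] == 0) return(tree_leaf(s))
    # child slots: arities of earlier nodes on this level come first
    before <- sum(ar[levels[[lvl]][seq_len(slot - 1)]])
    kids <- lapply(seq_len(ar[i]), function(k) build(lvl + 1, before + k))
    do.call(tree_node, c(list(s), kids))
  }
  build(1, 1)
}

random_test_gene <- function(config) {
  h <- config$head_length
  t <- h * (config_max_arity_test(config) - 1) + 1
  terms <- c(config$terminal_set, if (config$use_constants) "?")
  list(symbols = c(sample(c(config$function_set, terms), h, replace = TRUE),
                   sample(terms, t, replace = TRUE)),
       consts = round(stats::runif(h + t, -10, 10), 4))
}

config_max_arity_test <- function(config) {
  tab <- function_table()
  max(vapply(config$function_set, function(s) tab[[s]]$arity, numeric(1)))
}
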