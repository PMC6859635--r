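#' Genetic-algorithm media optimization
#'
#' A real-coded, bound-constrained, single-objective genetic algorithm:
#' each chromosome is a candidate media composition (one gene per factor),
#' selection is fitness-proportional over rank-based weights, crossover is
#' uniform (each gene from either parent with probability 1/2), mutation is
#' per-gene Gaussian scaled to a fraction of the factor's range and clipped
#' to the bounds, and the best chromosomes pass unchanged. Independent
#' restarts guard against premature convergence; the best-of-restarts is
#' re-evaluated at return.
#'
#' @name ga-optimizer
NULL

#' GA configuration
#'
#' @param population_size Chromosomes per generation.
#' @param generations Generations per restart.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_scale Mutation SD as a fraction of each factor's range.
#' @param elitism Chromosomes copied unchanged (>= 1).
#' @param sense `"maximize"` or `"minimize"`.
#' @param bounds Data frame with columns `factor`, `lo`, `hi` (default
#'   [factor_bounds()]).
#' @param restarts Independent restarts.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      mutation_scale = 0.1, elitism = 2,
                      sense = c("maximize", "minimize"),
                      bounds = factor_bounds(), restarts = 10, seed = 1) {
  sense <- match.arg(sense)
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (elitism < 1) stop("elitism must be >= 1", call. = FALSE)
  if (!all(bounds$lo < bounds$hi)) {
    stop("bounds must satisfy lo < hi", call. = FALSE)
  }
  structure(list(population_size = population_size,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale, elitism = elitism,
                 sense = sense, bounds = bounds, restarts = restarts,
                 seed = seed),
            class = "ga_config")
}

#' Optimize an objective over the factor box
#'
#' @param objective Function of a named factor vector (see
#'   [factor_vector()]) returning a finite scalar; evaluated many times, so
#'   it should be cheap.
#' @param config A [ga_config()].
#' @param vectorized If `TRUE`, `objective` is called once per generation
#'   with a data frame of compositions (one row each) and must return one
#'   value per row -- much faster for expression-tree objectives.
#' @return An `optimization_result`: list with `best_x` (named factor
#'   vector), `best_value` (objective re-evaluated at `best_x`), `sense`,
#'   and `trace` (data frame of restart, generation, best value so far in
#'   that restart).
#' @examples
#' cfg <- ga_config(population_size = 40, generations = 60, restarts = 2,
#'                  sense = "maximize")
#' res <- optimize_media(function(x) -(x[["KNO3"]] - 1)^2, cfg)
#' res$best_x[["KNO3"]]  # close to 1
#' @export
optimize_media <- function(objective, config = ga_config(),
                           vectorized = FALSE) {
  b <- config$bounds
  k <- nrow(b)
  lo <- b$lo
  hi <- b$hi
  rng <- hi - lo
  nm <- b$factor
  sgn <- if (config$sense == "maximize") 1 else -1
  eval_pop <- function(pop) {
    vals <- if (vectorized) {
      df <- as.data.frame(pop)
      names(df) <- nm
      objective(df)
    } else {
      apply(pop, 1, function(row) objective(stats::setNames(row, nm)))
    }
    if (any(!is.finite(vals))) {
      stop("objective returned a non-finite value inside the bounds box",
           call. = FALSE)
    }
    vals
  }
  all_trace <- list()
  best_x <- NULL
  best_val <- -Inf
  for (rs in seq_len(config$restarts)) {
    res <- with_rng_seed(config$seed + rs - 1, {
      pop <- matrix(stats::runif(config$population_size * k), ncol = k)
      pop <- sweep(sweep(pop, 2, rng, "*"), 2, lo, "+")
      vals <- sgn * eval_pop(pop)
      trace <- numeric(config$generations)
      for (gen in seq_len(config$generations)) {
        ord <- order(vals, decreasing = TRUE)
        # rank-based selection weights (best rank -> largest weight)
        w <- numeric(length(vals))
        w[ord] <- rev(seq_along(vals))
        n_off <- config$population_size - config$elitism
        parents <- matrix(sample.int(config$population_size, 2 * n_off,
                                     replace = TRUE, prob = w), ncol = 2)
        off <- matrix(0, nrow = n_off, ncol = k)
        for (i in seq_len(n_off)) {
          p1 <- pop[parents[i, 1], ]
          p2 <- pop[parents[i, 2], ]
          child <- if (stats::runif(1) < config$crossover_rate) {
            pick <- stats::runif(k) < 0.5
            ifelse(pick, p1, p2)
          } else p1
          mut <- stats::runif(k) < config$mutation_rate
          if (any(mut)) {
            child[mut] <- child[mut] +
              stats::rnorm(sum(mut), 0, config$mutation_scale * rng[mut])
          }
          off[i, ] <- pmin(pmax(child, lo), hi)
        }
        pop <- rbind(pop[ord[seq_len(config$elitism)], , drop = FALSE], off)
        vals <- sgn * eval_pop(pop)
        trace[gen] <- max(vals)
      }
      i <- which.max(vals)
      list(x = pop[i, ], val = vals[i], trace = trace)
    })
    all_trace[[rs]] <- data.frame(restart = rs,
                                  generation = seq_along(res$trace),
                                  best = sgn * res$trace)
    if (res$val > best_val) {
      best_val <- res$val
      best_x <- res$x
    }
  }
  best_x <- stats::setNames(best_x, nm)
  revalue <- if (vectorized) {
    objective(as.data.frame(as.list(best_x)))
  } else {
    objective(best_x)
  }
  structure(list(best_x = best_x,
                 best_value = revalue,  # re-evaluated at return
                 sense = config$sense,
                 trace = do.call(rbind, all_trace)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> ", x$sense, "d value: ",
      format(x$best_value, digits = 6), "\n", sep = "")
  print(round(x$best_x, 3))
  invisible(x)
}

#' Optimize all five responses of a rootstock's published models
#'
#' Maximizes PR, SL and QI and minimizes STN and Vitri over the factor
#' bounds, one GA run-set per response.
#'
#' @param rootstock `"Pyrodwarf"` or `"OHF"`.
#' @param config A [ga_config()]; its `sense` is overridden per response.
#' @param convention Protected-operator convention used to evaluate the
#'   published models (see [protected-ops]).
#' @return Data frame with one row per response: `response`, `sense`,
#'   `optimum` and the six optimal factor levels. The full
#'   `optimization_result`s are attached as attribute `results`.
#' @export
optimize_all <- function(rootstock, config = ga_config(),
                         convention = c("complex", "abs")) {
  convention <- match.arg(convention)
  rootstock <- match_rootstock(rootstock)
  senses <- c(PR = "maximize", SL = "maximize", STN = "minimize",
              Vitri = "minimize", QI = "maximize")
  results <- lapply(names(senses), function(rp) {
    tree <- published_model(rootstock, rp)
    obj <- function(x) evaluate_tree(tree, x, convention = convention)
    cfg <- config
    cfg$sense <- senses[[rp]]
    optimize_media(obj, cfg, vectorized = TRUE)
  })
  names(results) <- names(senses)
  tab <- do.call(rbind, lapply(names(senses), function(rp) {
    r <- results[[rp]]
    cbind(data.frame(response = rp, sense = r$sense,
                     optimum = r$best_value, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$best_x)))
  }))
  attr(tab, "results") <- results
  attr(tab, "note") <-
    "QI optima are computed from the published QI equations"
  tab
}
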