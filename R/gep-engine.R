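#' Gene expression programming engine
#'
#' Symbolic regression with fixed-length multigenic linear genomes. Each
#' gene is a string of symbols with a head (functions or terminals) and a
#' tail (terminals only, length `h * (a_max - 1) + 1`), decoded breadth-first
#' (Karva notation) into an expression tree; a chromosome's phenotype is the
#' fold of its gene trees under a linking operator (addition by default).
#' Selection is roulette-wheel on a decreasing transform of the root
#' relative squared error, with elitism; variation uses per-symbol mutation,
#' head-segment inversion, one- and two-point recombination, whole-gene
#' recombination and gene transposition.
#'
#' @name gep-engine
NULL

#' GEP run configuration
#'
#' Defaults follow the published run settings: 50 chromosomes, head length
#' 8, three genes linked by addition, mutation rate 0.044, inversion 0.1,
#' one-point/two-point/gene recombination 0.1/0.3/0.1, gene transposition
#' 0.1. The generation budget and early stopping are not published; the
#' defaults stop after `generations` or when the best RRSE improves by less
#' than `stop_tol` over `stop_window` generations.
#'
#' @param population_size Chromosomes per generation.
#' @param head_length Gene head length `h`.
#' @param n_genes Genes per chromosome.
#' @param linking Linking operator symbol (binary, folded left).
#' @param function_set Character vector of operator symbols.
#' @param terminal_set Terminal symbols (factor letters).
#' @param use_constants Include an ephemeral-random-constant terminal slot.
#' @param const_range Range from which ephemeral constants are drawn.
#' @param mutation_rate,inversion_rate,one_point_recomb,two_point_recomb,gene_recomb,gene_transposition
#'   Operator rates in \[0, 1\].
#' @param is_transposition,ris_transposition Rates of insertion-sequence and
#'   root-insertion-sequence transposition (segment copied into the gene
#'   head), the classical diversity operators of this method family.
#' @param generations Total generation budget.
#' @param elitism Number of best chromosomes copied unchanged (>= 1).
#' @param stop_tol,stop_window Stagnation rule: when the best RRSE improves
#'   by less than `stop_tol` over `stop_window` generations the population
#'   is reinitialized (a restart); the best chromosome ever seen is kept
#'   aside and returned.
#' @param selection_pressure Exponent on the rank weights used by the
#'   roulette wheel (see [selection_weights()]).
#' @param seed Integer seed.
#' @return A `gep_config` list.
#' @export
gep_config <- function(population_size = 50,
                       head_length = 8,
                       n_genes = 3,
                       linking = "+",
                       function_set = default_function_set(),
                       terminal_set = LETTERS[1:6],
                       use_constants = TRUE,
                       const_range = c(-10, 10),
                       mutation_rate = 0.044,
                       inversion_rate = 0.1,
                       one_point_recomb = 0.1,
                       two_point_recomb = 0.3,
                       gene_recomb = 0.1,
                       gene_transposition = 0.1,
                       is_transposition = 0.1,
                       ris_transposition = 0.1,
                       generations = 500,
                       elitism = 1,
                       stop_tol = 1e-6,
                       stop_window = 75,
                       selection_pressure = 2,
                       seed = 1) {
  rates <- c(mutation_rate, inversion_rate, one_point_recomb,
             two_point_recomb, gene_recomb, gene_transposition,
             is_transposition, ris_transposition)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]",
                                       call. = FALSE)
  if (head_length < 1) stop("head_length must be >= 1", call. = FALSE)
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (elitism < 1) stop("elitism must be >= 1", call. = FALSE)
  tab <- function_table()
  unknown <- setdiff(function_set, names(tab))
  if (length(unknown) > 0) {
    stop("unknown function symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    population_size = population_size, head_length = head_length,
    n_genes = n_genes, linking = linking, function_set = function_set,
    terminal_set = terminal_set, use_constants = use_constants,
    const_range = const_range, mutation_rate = mutation_rate,
    inversion_rate = inversion_rate, one_point_recomb = one_point_recomb,
    two_point_recomb = two_point_recomb, gene_recomb = gene_recomb,
    gene_transposition = gene_transposition,
    is_transposition = is_transposition,
    ris_transposition = ris_transposition, generations = generations,
    elitism = elitism, stop_tol = stop_tol, stop_window = stop_window,
    selection_pressure = selection_pressure, seed = seed),
    class = "gep_config")
}

#' Gene tail length
#'
#' The tail must be long enough that any head decodes to a complete tree:
#' `t = h * (a_max - 1) + 1` where `a_max` is the maximum arity in the
#' function set.
#'
#' @param head_length Head length `h` (>= 1).
#' @param max_arity Maximum operator arity (>= 1).
#' @return Integer tail length.
#' @examples
#' tail_length(8, 2)  # 9, so genes are 17 symbols long
#' @export
tail_length <- function(head_length, max_arity) {
  stopifnot(head_length >= 1, max_arity >= 1)
  head_length * (max_arity - 1) + 1
}

config_max_arity <- function(config) {
  tab <- function_table()
  max(vapply(config$function_set, function(s) tab[[s]]$arity, numeric(1)))
}

gene_length <- function(config) {
  config$head_length + tail_length(config$head_length, config_max_arity(config))
}

CONST_SYM <- "?"

gene_terminal_alphabet <- function(config) {
  c(config$terminal_set, if (config$use_constants) CONST_SYM)
}

random_gene <- function(config) {
  h <- config$head_length
  t <- tail_length(h, config_max_arity(config))
  terms <- gene_terminal_alphabet(config)
  head_alpha <- c(config$function_set, terms)
  symbols <- c(sample(head_alpha, h, replace = TRUE),
               sample(terms, t, replace = TRUE))
  consts <- stats::runif(h + t, config$const_range[1], config$const_range[2])
  list(symbols = symbols, consts = consts)
}

random_chromosome <- function(config) {
  list(genes = replicate(config$n_genes, random_gene(config),
                         simplify = FALSE),
       fitness = NA_real_)
}

#' Decode a gene's K-expression into an expression tree
#'
#' Breadth-first open-reading-frame decoding: the symbol at position 1 is
#' the root; each function node consumes its arity's worth of the next
#' unread symbols, level by level; trailing unused symbols are ignored.
#' The constant placeholder `?` at position `i` becomes the constant stored
#' in `gene$consts[i]`.
#'
#' @param gene A gene: list with `symbols` (character vector) and optional
#'   `consts` (numeric vector of the same length).
#' @param tab Function table (defaults to [function_table()]).
#' @return A `gep_tree`.
#' @examples
#' karva_decode(list(symbols = c("*", "+", "-", "A", "B", "C", "D")))
#' @export
karva_decode <- function(gene, tab = function_table()) {
  syms <- gene$symbols
  arities <- .pearmedia_cache$arities
  if (is.null(arities)) {
    arities <- vapply(tab, `[[`, numeric(1), "arity")
    .pearmedia_cache$arities <- arities
  }
  ar <- arities[syms]
  ar[is.na(ar)] <- 0L
  # open reading frame length: extend until every node's children exist
  m <- 1L
  need <- 1L + ar[1]
  while (m < need) {
    m <- m + 1L
    need <- need + ar[m]
  }
  # in a K-expression the children of node i occupy the positions right
  # after all earlier nodes' children: start_i = 2 + sum(ar[1:(i-1)])
  starts <- c(2L, 2L + cumsum(ar[seq_len(m - 1)]))
  nodes <- vector("list", m)
  for (i in m:1) {
    s <- syms[i]
    node <- if (identical(s, CONST_SYM)) {
      list(sym = ".const", value = gene$consts[i], children = list())
    } else if (ar[i] == 0) {
      list(sym = s, children = list())
    } else {
      list(sym = s, children = nodes[starts[i]:(starts[i] + ar[i] - 1)])
    }
    class(node) <- "gep_tree"
    nodes[[i]] <- node
  }
  nodes[[1]]
}

chromosome_tree <- function(chr, config) {
  trees <- lapply(chr$genes, karva_decode)
  Reduce(function(a, b) {
    structure(list(sym = config$linking, children = list(a, b)),
              class = "gep_tree")
  }, trees)
}

#' Root relative squared error
#'
#' `sqrt(sum((P - O)^2) / sum((O - mean(O))^2))`: the error of the model
#' relative to the error of the mean-only predictor. 0 is a perfect fit; 1
#' matches predicting the mean.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @return Non-negative scalar.
#' @examples
#' fitness_rrse(c(1, 2, 4), c(1, 2, 3))  # sqrt(1/2)
#' @export
fitness_rrse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) stop("observed values are constant; RRSE undefined",
                       call. = FALSE)
  sqrt(sum((predicted - observed)^2) / denom)
}

#' Roulette-wheel selection weights
#'
#' The wheel needs a maximized positive quantity; raw decreasing transforms
#' of RRSE (such as `1000 / (1 + RRSE)`) give nearly flat wheels once the
#' population improves, so weights are rank-based: the chromosome with the
#' `i`-th best (lowest) RRSE receives weight `(n - i + 1)^pressure`.
#' `pressure = 1` is linear ranking; the default `pressure = 2` gives the
#' selection intensity needed to overcome the disruptive operator rates.
#'
#' @param rrse Numeric vector of RRSE values (lower is better).
#' @param pressure Positive exponent.
#' @return Positive weights summing over the population.
#' @export
selection_weights <- function(rrse, pressure = 2) {
  w <- numeric(length(rrse))
  w[order(rrse)] <- rev(seq_along(rrse))^pressure
  w
}

mutate_gene <- function(gene, config) {
  h <- config$head_length
  len <- length(gene$symbols)
  hit <- which(stats::runif(len) < config$mutation_rate)
  if (length(hit) == 0) return(gene)
  terms <- gene_terminal_alphabet(config)
  head_alpha <- c(config$function_set, terms)
  for (i in hit) {
    gene$symbols[i] <- if (i <= h) sample(head_alpha, 1) else sample(terms, 1)
    if (identical(gene$symbols[i], CONST_SYM)) {
      gene$consts[i] <- stats::runif(1, config$const_range[1],
                                     config$const_range[2])
    }
  }
  gene
}

invert_gene <- function(gene, config) {
  h <- config$head_length
  if (h < 2) return(gene)
  pts <- sort(sample.int(h, 2))
  seg <- pts[1]:pts[2]
  gene$symbols[seg] <- rev(gene$symbols[seg])
  gene$consts[seg] <- rev(gene$consts[seg])
  gene
}

flatten_chromosome <- function(chr) {
  list(symbols = unlist(lapply(chr$genes, `[[`, "symbols")),
       consts = unlist(lapply(chr$genes, `[[`, "consts")))
}

unflatten_chromosome <- function(flat, n_genes) {
  glen <- length(flat$symbols) / n_genes
  genes <- lapply(seq_len(n_genes), function(g) {
    idx <- ((g - 1) * glen + 1):(g * glen)
    list(symbols = flat$symbols[idx], consts = flat$consts[idx])
  })
  list(genes = genes, fitness = NA_real_)
}

recombine <- function(chr1, chr2, config, points) {
  f1 <- flatten_chromosome(chr1)
  f2 <- flatten_chromosome(chr2)
  len <- length(f1$symbols)
  cut <- sort(sample.int(len - 1, points))
  swap <- rep(FALSE, len)
  state <- FALSE
  j <- 1
  for (i in seq_len(len)) {
    while (j <= points && i > cut[j]) { state <- !state; j <- j + 1 }
    swap[i] <- state
  }
  a <- f1; b <- f2
  a$symbols[swap] <- f2$symbols[swap]; a$consts[swap] <- f2$consts[swap]
  b$symbols[swap] <- f1$symbols[swap]; b$consts[swap] <- f1$consts[swap]
  list(unflatten_chromosome(a, config$n_genes),
       unflatten_chromosome(b, config$n_genes))
}

# insertion-sequence transposition: copy a short segment from anywhere in
# the gene into a non-root head position, shifting the head right (the tail
# is untouched, so validity is preserved)
is_transpose <- function(gene, config) {
  h <- config$head_length
  if (h < 2) return(gene)
  len <- length(gene$symbols)
  seglen <- sample.int(3, 1)
  start <- sample.int(len - seglen + 1, 1)
  idx <- start:(start + seglen - 1)
  ins <- if (h == 2) 2 else sample(2:h, 1)
  newhead <- c(gene$symbols[seq_len(ins - 1)], gene$symbols[idx],
               gene$symbols[ins:h])[seq_len(h)]
  newconst <- c(gene$consts[seq_len(ins - 1)], gene$consts[idx],
                gene$consts[ins:h])[seq_len(h)]
  gene$symbols[seq_len(h)] <- newhead
  gene$consts[seq_len(h)] <- newconst
  gene
}

# root-insertion-sequence transposition: a head segment starting at a
# function symbol is copied to the front of the head
ris_transpose <- function(gene, config) {
  h <- config$head_length
  fpos <- which(gene$symbols[seq_len(h)] %in% config$function_set)
  fpos <- fpos[fpos > 1]
  if (length(fpos) == 0) return(gene)
  start <- if (length(fpos) == 1) fpos else sample(fpos, 1)
  seglen <- sample.int(min(3, h - start + 1), 1)
  idx <- start:(start + seglen - 1)
  newhead <- c(gene$symbols[idx], gene$symbols[seq_len(h)])[seq_len(h)]
  newconst <- c(gene$consts[idx], gene$consts[seq_len(h)])[seq_len(h)]
  gene$symbols[seq_len(h)] <- newhead
  gene$consts[seq_len(h)] <- newconst
  gene
}

gene_recombine <- function(chr1, chr2, config) {
  g <- sample.int(config$n_genes, 1)
  tmp <- chr1$genes[[g]]
  chr1$genes[[g]] <- chr2$genes[[g]]
  chr2$genes[[g]] <- tmp
  chr1$fitness <- NA_real_
  chr2$fitness <- NA_real_
  list(chr1, chr2)
}

transpose_gene <- function(chr, config) {
  if (config$n_genes < 2) return(chr)
  g <- sample.int(config$n_genes, 1)
  order <- c(g, setdiff(seq_len(config$n_genes), g))
  chr$genes <- chr$genes[order]
  chr$fitness <- NA_real_
  chr
}

#' Apply the genetic operators to a population
#'
#' Elite chromosomes (the best `config$elitism` by stored fitness) pass
#' unchanged; the rest undergo mutation, inversion, one-point, two-point
#' and whole-gene recombination and gene transposition at their configured
#' rates. Gene length and the tail-terminal invariant are preserved by
#' construction.
#'
#' @param population List of chromosomes with `fitness` (RRSE) fields.
#' @param config A [gep_config()].
#' @return List of chromosomes of the same length.
#' @export
apply_operators <- function(population, config) {
  n <- length(population)
  ord <- order(vapply(population, `[[`, numeric(1), "fitness"))
  elites <- population[ord[seq_len(min(config$elitism, n))]]
  pool <- population
  # mutation + inversion (per chromosome)
  pool <- lapply(pool, function(chr) {
    chr$genes <- lapply(chr$genes, mutate_gene, config = config)
    if (stats::runif(1) < config$inversion_rate) {
      g <- sample.int(config$n_genes, 1)
      chr$genes[[g]] <- invert_gene(chr$genes[[g]], config)
    }
    chr$fitness <- NA_real_
    chr
  })
  # pairwise operators
  pair_apply <- function(pool, rate, fn) {
    if (length(pool) < 2) return(pool)
    idx <- sample.int(length(pool))
    for (k in seq(1, length(idx) - 1, by = 2)) {
      if (stats::runif(1) < rate) {
        res <- fn(pool[[idx[k]]], pool[[idx[k + 1]]])
        pool[[idx[k]]] <- res[[1]]
        pool[[idx[k + 1]]] <- res[[2]]
      }
    }
    pool
  }
  pool <- pair_apply(pool, config$one_point_recomb,
                     function(a, b) recombine(a, b, config, 1))
  pool <- pair_apply(pool, config$two_point_recomb,
                     function(a, b) recombine(a, b, config, 2))
  pool <- pair_apply(pool, config$gene_recomb,
                     function(a, b) gene_recombine(a, b, config))
  pool <- lapply(pool, function(chr) {
    if (stats::runif(1) < config$gene_transposition) {
      chr <- transpose_gene(chr, config)
    }
    if (stats::runif(1) < config$is_transposition) {
      g <- sample.int(config$n_genes, 1)
      chr$genes[[g]] <- is_transpose(chr$genes[[g]], config)
      chr$fitness <- NA_real_
    }
    if (stats::runif(1) < config$ris_transposition) {
      g <- sample.int(config$n_genes, 1)
      chr$genes[[g]] <- ris_transpose(chr$genes[[g]], config)
      chr$fitness <- NA_real_
    }
    chr
  })
  # elites replace the tail of the pool
  if (length(elites) > 0) {
    pool[seq_len(length(elites))] <- elites
  }
  pool
}

evaluate_population <- function(population, config, x, y,
                                denom = sum((y - mean(y))^2)) {
  lapply(population, function(chr) {
    if (!is.na(chr$fitness)) return(chr)
    tree <- chromosome_tree(chr, config)
    pred <- evaluate_tree(tree, x, convention = "abs")
    rrse <- sqrt(sum((pred - y)^2) / denom)
    chr$fitness <- if (is.finite(rrse)) rrse else Inf
    chr
  })
}

roulette_select <- function(population, n, pressure = 2) {
  rrse <- vapply(population, `[[`, numeric(1), "fitness")
  rrse[!is.finite(rrse)] <- max(rrse[is.finite(rrse)], 1) * 10
  w <- selection_weights(rrse, pressure)
  idx <- sample.int(length(population), n, replace = TRUE, prob = w)
  population[idx]
}

#' Evolve a symbolic-regression model
#'
#' Runs the generational loop (express, evaluate RRSE fitness, roulette
#' selection with elitism, genetic operators) on training records.
#'
#' @param train Data frame containing the six factor columns and the
#'   response (>= 10 rows).
#' @param response Response column name.
#' @param config A [gep_config()].
#' @return A `gep_model`: list with `chromosome`, `tree`, `formula`,
#'   `rrse`, `history` (data frame of generation, best_rrse, mean_rrse) and
#'   `config`.
#' @export
evolve <- function(train, response, config = gep_config()) {
  stopifnot(is.data.frame(train))
  if (nrow(train) < 10) stop("need at least 10 training records",
                             call. = FALSE)
  y <- train[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  if (stats::var(y) == 0) stop("response is constant; nothing to fit",
                               call. = FALSE)
  x <- as_factor_frame(train)
  with_rng_seed(config$seed, {
    pop <- replicate(config$population_size, random_chromosome(config),
                     simplify = FALSE)
    pop <- evaluate_population(pop, config, x, y)
    hist_best <- numeric(config$generations)
    hist_mean <- numeric(config$generations)
    best <- pop[[which.min(vapply(pop, `[[`, numeric(1), "fitness"))]]
    gens_run <- 0
    stagnant <- 0
    cur_best <- best            # best of the current (re)start
    for (gen in seq_len(config$generations)) {
      sel <- roulette_select(pop, config$population_size,
                             config$selection_pressure)
      # keep current best's fitness available to apply_operators' elitism
      sel[[1]] <- cur_best
      pop <- apply_operators(sel, config)
      pop <- evaluate_population(pop, config, x, y)
      gen_best <- pop[[which.min(vapply(pop, `[[`, numeric(1), "fitness"))]]
      improved <- gen_best$fitness < cur_best$fitness - config$stop_tol
      if (gen_best$fitness < cur_best$fitness) cur_best <- gen_best
      if (cur_best$fitness < best$fitness) best <- cur_best
      fits <- vapply(pop, `[[`, numeric(1), "fitness")
      hist_best[gen] <- best$fitness
      hist_mean[gen] <- mean(fits[is.finite(fits)])
      gens_run <- gen
      if (best$fitness < 1e-9) break
      # stagnation restart: reinitialize the search population (the
      # best-so-far chromosome stays archived and is returned); the
      # stagnation clock is local to the current population
      stagnant <- if (improved) 0 else stagnant + 1
      if (stagnant >= config$stop_window) {
        pop <- replicate(config$population_size, random_chromosome(config),
                         simplify = FALSE)
        pop <- evaluate_population(pop, config, x, y)
        cur_best <- pop[[which.min(vapply(pop, `[[`, numeric(1),
                                          "fitness"))]]
        stagnant <- 0
      }
    }
  })
  tree <- chromosome_tree(best, config)
  structure(list(chromosome = best, tree = tree,
                 formula = to_formula_string(tree),
                 rrse = best$fitness, response = response,
                 history = data.frame(generation = seq_len(gens_run),
                                      best_rrse = hist_best[seq_len(gens_run)],
                                      mean_rrse = hist_mean[seq_len(gens_run)]),
                 config = config),
            class = "gep_model")
}

#' @export
predict.gep_model <- function(object, newdata, ...) {
  evaluate_tree(object$tree, newdata, convention = "abs")
}

#' @export
print.gep_model <- function(x, ...) {
  cat("<gep_model> response:", x$response, " RRSE:",
      format(x$rrse, digits = 4), "\n  ", x$formula, "\n")
  invisible(x)
}
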