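#' Expression trees over the media factors
#'
#' A `gep_tree` is a finite rooted tree whose internal nodes are operators
#' from [function_table()] and whose leaves are either factor terminals
#' (symbols `A`--`F`, see [factor_symbols()]) or numeric constants. It is the
#' phenotype of the symbolic-regression engine and the representation of the
#' ten published media-response models.
#'
#' @name gep_tree
NULL

#' Build a tree node
#'
#' @param sym Operator symbol (a name in [function_table()]).
#' @param ... Child trees, one per operand.
#' @return A `gep_tree`.
#' @export
tree_node <- function(sym, ...) {
  children <- list(...)
  tab <- function_table()
  if (is.null(tab[[sym]])) {
    stop("unknown operator symbol: '", sym, "'", call. = FALSE)
  }
  if (length(children) != tab[[sym]]$arity) {
    stop("operator '", sym, "' expects ", tab[[sym]]$arity,
         " operand(s), got ", length(children), call. = FALSE)
  }
  structure(list(sym = sym, children = children), class = "gep_tree")
}

#' @rdname tree_node
#' @param name Terminal symbol, one of `A`--`F`.
#' @export
tree_leaf <- function(name) {
  if (!name %in% names(factor_symbols())) {
    stop("unknown terminal symbol: '", name, "'", call. = FALSE)
  }
  structure(list(sym = name, children = list()), class = "gep_tree")
}

#' @rdname tree_node
#' @param value Numeric constant.
#' @export
tree_const <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(sym = ".const", value = value, children = list()),
            class = "gep_tree")
}

is_leaf <- function(t) length(t$children) == 0

#' Validate an expression tree
#'
#' Checks that every internal node's symbol is in the function table with
#' matching arity and that every leaf is a known terminal or a finite
#' constant.
#'
#' @param tree A `gep_tree`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  tab <- function_table()
  terms <- names(factor_symbols())
  walk <- function(t) {
    if (!inherits(t, "gep_tree") && !is.list(t)) {
      stop("malformed tree node", call. = FALSE)
    }
    if (identical(t$sym, ".const")) {
      if (!is.finite(t$value)) stop("non-finite constant", call. = FALSE)
      return(invisible(TRUE))
    }
    if (length(t$children) == 0) {
      if (!t$sym %in% terms) {
        stop("unknown symbol: '", t$sym, "'", call. = FALSE)
      }
      return(invisible(TRUE))
    }
    op <- tab[[t$sym]]
    if (is.null(op)) stop("unknown symbol: '", t$sym, "'", call. = FALSE)
    if (length(t$children) != op$arity) {
      stop("arity mismatch at '", t$sym, "': expected ", op$arity,
           ", found ", length(t$children), call. = FALSE)
    }
    for (ch in t$children) walk(ch)
    invisible(TRUE)
  }
  walk(tree)
}

#' Evaluate an expression tree at one or more media compositions
#'
#' Evaluation is vectorized: `x` may be a single named composition (see
#' [factor_vector()]) or a data frame of compositions, and the result has
#' one value per row. All operators use protected rules (see
#' [protected-ops]); under the `"complex"` convention the computation runs
#' in complex arithmetic and the real part is returned.
#'
#' @param tree A `gep_tree`.
#' @param x Named numeric vector, list or data frame of factor levels
#'   (names may be factor names or symbols `A`--`F`).
#' @param convention `"abs"` (default) or `"complex"`.
#' @return Numeric vector of finite values, one per composition.
#' @examples
#' t <- parse_formula("((A + B) * (C - D))")
#' evaluate_tree(t, c(A = 1, B = 2, C = 5, D = 3, E = 1, F = 0.1))
#' @export
evaluate_tree <- function(tree, x, convention = c("abs", "complex")) {
  convention <- match.arg(convention)
  tab <- function_table()
  xf <- as_factor_frame(x)
  nr <- nrow(xf)
  xf <- unclass(xf)  # plain-list column access in the hot recursion
  slot <- if (convention == "abs") "abs" else "cpx"
  rec <- function(t) {
    s <- t$sym
    if (s == ".const") return(t$value)
    ch <- t$children
    n <- length(ch)
    if (n == 0) {
      v <- xf[[s]]
      if (is.null(v)) stop("unknown symbol: '", s, "'", call. = FALSE)
      return(v)
    }
    op <- tab[[s]]
    if (is.null(op)) stop("unknown symbol: '", s, "'", call. = FALSE)
    if (n != op$arity) {
      stop("arity mismatch at '", s, "'", call. = FALSE)
    }
    if (n == 1) op[[slot]](rec(ch[[1]]))
    else op[[slot]](rec(ch[[1]]), rec(ch[[2]]))
  }
  out <- rec(tree)
  if (is.complex(out)) out <- Re(out)
  if (length(out) == 1 && nr > 1) out <- rep(out, nr)
  out
}

#' Render a tree as a parenthesized infix formula
#'
#' The rendering round-trips: `parse_formula(to_formula_string(t))`
#' evaluates identically to `t` at any composition.
#'
#' @param tree A `gep_tree`.
#' @return A single character string.
#' @export
to_formula_string <- function(tree) {
  tab <- function_table()
  rec <- function(t) {
    if (identical(t$sym, ".const")) {
      return(format(t$value, digits = 17, scientific = FALSE, trim = TRUE))
    }
    if (length(t$children) == 0) return(t$sym)
    do.call(sprintf, c(list(tab[[t$sym]]$fmt), lapply(t$children, rec)))
  }
  rec(tree)
}

#' Parse an infix formula into an expression tree
#'
#' Accepts the rendering produced by [to_formula_string()]: the operators
#' `+ - * /`, the unary functions of [function_table()] in prefix form
#' (`sqrt(x)`, `cbrt(x)`, `inv(x)`, `sq(x)`, ...), `avg2(a, b)`, numeric
#' constants and the terminals `A`--`F`.
#'
#' @param text Formula string.
#' @return A `gep_tree`.
#' @export
parse_formula <- function(text) {
  as_gep_tree(str2lang(text))
}

# Convert a quoted R expression into a gep_tree. Unary minus folds into
# constants where possible, otherwise becomes 'neg'.
as_gep_tree <- function(e) {
  if (is.numeric(e)) return(tree_const(as.numeric(e)))
  if (is.name(e)) {
    nm <- as.character(e)
    return(tree_leaf(nm))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (fn == "(") return(as_gep_tree(e[[2]]))
    if (fn == "-" && length(e) == 2) {
      ch <- as_gep_tree(e[[2]])
      if (identical(ch$sym, ".const")) return(tree_const(-ch$value))
      return(tree_node("neg", ch))
    }
    if (fn == "log") fn <- "ln"
    args <- lapply(as.list(e)[-1], as_gep_tree)
    return(do.call(tree_node, c(list(fn), args)))
  }
  stop("cannot convert expression of class ", class(e)[1], call. = FALSE)
}

#' Top-level linked terms of a model tree
#'
#' Multigenic models are linked by addition; this flattens the top-level
#' chain of `+` nodes and returns the linked sub-trees.
#'
#' @param tree A `gep_tree`.
#' @return List of `gep_tree` terms.
#' @export
linked_terms <- function(tree) {
  if (identical(tree$sym, "+")) {
    c(linked_terms(tree$children[[1]]), linked_terms(tree$children[[2]]))
  } else {
    list(tree)
  }
}

#' Collect constants appearing in a tree
#' @param tree A `gep_tree`.
#' @return Numeric vector of constant leaf values, in depth-first order.
#' @export
tree_constants <- function(tree) {
  if (identical(tree$sym, ".const")) return(tree$value)
  if (length(tree$children) == 0) return(numeric(0))
  unlist(lapply(tree$children, tree_constants))
}

#' @export
print.gep_tree <- function(x, ...) {
  cat("<gep_tree> ", to_formula_string(x), "\n", sep = "")
  invisible(x)
}
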