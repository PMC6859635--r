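#' Protected arithmetic for expression-tree evaluation
#'
#' Symbolic-regression models must be evaluable everywhere in the design box,
#' so every operator carries a protected (total) evaluation rule. Two
#' conventions are provided:
#'
#' \describe{
#'   \item{`"abs"`}{real arithmetic: `sqrt(x) = sqrt(|x|)` (likewise even
#'     roots), odd roots are sign-preserving, `ln(x) = log(max(|x|, eps))`,
#'     division and inverse clamp the denominator to magnitude `eps = 1e-9`,
#'     and `exp` clamps its argument to \eqn{[-50, 50]}.}
#'   \item{`"complex"`}{evaluation in complex arithmetic with principal
#'     branches for even roots and logarithms of negative arguments; odd
#'     roots remain real and sign-preserving; denominators of magnitude
#'     below `eps` are clamped; the real part is taken once at the end.}
#' }
#'
#' The two conventions agree wherever all intermediate arguments are
#' non-negative. See the methods vignette for why both exist: the `"abs"`
#' rule reproduces the published models' fit to the observed data, while the
#' `"complex"` rule reproduces the published optimization results.
#'
#' @name protected-ops
NULL

PROT_EPS <- 1e-9
EXP_CLAMP <- 50

clamp_den <- function(b) {
  small <- abs(b) < PROT_EPS
  if (any(small)) {
    s <- sign(Re(b[small]))
    s[s == 0] <- 1
    b[small] <- s * PROT_EPS
  }
  b
}

signed_root <- function(x, n) {
  # odd-n root, sign preserving; for complex input with nonzero imaginary
  # part, the principal branch
  if (is.complex(x)) {
    realish <- Im(x) == 0
    out <- x^(1 / n)
    out[realish] <- complex(real = sign(Re(x[realish])) *
                              abs(Re(x[realish]))^(1 / n), imaginary = 0)
    return(out)
  }
  sign(x) * abs(x)^(1 / n)
}

even_root_abs <- function(x, n) abs(x)^(1 / n)

even_root_cpx <- function(x, n) {
  if (!is.complex(x)) x <- as.complex(x)
  x^(1 / n)
}

exp_clamped <- function(x) {
  if (is.complex(x)) {
    exp(complex(real = pmin(pmax(Re(x), -EXP_CLAMP), EXP_CLAMP),
                imaginary = Im(x)))
  } else {
    exp(pmin(pmax(x, -EXP_CLAMP), EXP_CLAMP))
  }
}

ln_abs <- function(x) log(pmax(abs(x), PROT_EPS))

ln_cpx <- function(x) {
  if (!is.complex(x)) x <- as.complex(x)
  small <- abs(x) < PROT_EPS
  x[small] <- PROT_EPS
  log(x)
}

#' The expression-tree function table
#'
#' Every operator available to expression trees and the symbolic-regression
#' engine: its arity and its protected evaluation rule under both
#' conventions (see [protected-ops]). The set covers the published models'
#' vocabulary: the four arithmetic operators, square/cube/4th/6th/9th roots,
#' trigonometric functions, arc-tangent, powers two and three, exponential,
#' natural logarithm, inverse, hyperbolic tangent, two-argument average, and
#' unary negation.
#'
#' @return Named list; each element has fields `arity`, `abs` and `cpx`
#'   (evaluation functions) and `fmt` (an infix/prefix format template used
#'   by [to_formula_string()]).
#' @export
function_table <- function() {
  if (!is.null(.pearmedia_cache$function_table)) {
    return(.pearmedia_cache$function_table)
  }
  .pearmedia_cache$function_table <- build_function_table()
  .pearmedia_cache$function_table
}

.pearmedia_cache <- new.env(parent = emptyenv())

build_function_table <- function() {
  list(
    "+"    = list(arity = 2, abs = `+`, cpx = `+`, fmt = "(%s + %s)"),
    "-"    = list(arity = 2, abs = `-`, cpx = `-`, fmt = "(%s - %s)"),
    "*"    = list(arity = 2, abs = `*`, cpx = `*`, fmt = "(%s * %s)"),
    "/"    = list(arity = 2,
                  abs = function(a, b) a / clamp_den(b),
                  cpx = function(a, b) a / clamp_den(b),
                  fmt = "(%s / %s)"),
    "sqrt" = list(arity = 1,
                  abs = function(x) even_root_abs(x, 2),
                  cpx = function(x) even_root_cpx(x, 2),
                  fmt = "sqrt(%s)"),
    "cbrt" = list(arity = 1,
                  abs = function(x) signed_root(x, 3),
                  cpx = function(x) signed_root(x, 3),
                  fmt = "cbrt(%s)"),
    "root4" = list(arity = 1,
                   abs = function(x) even_root_abs(x, 4),
                   cpx = function(x) even_root_cpx(x, 4),
                   fmt = "root4(%s)"),
    "root6" = list(arity = 1,
                   abs = function(x) even_root_abs(x, 6),
                   cpx = function(x) even_root_cpx(x, 6),
                   fmt = "root6(%s)"),
    "root9" = list(arity = 1,
                   abs = function(x) signed_root(x, 9),
                   cpx = function(x) signed_root(x, 9),
                   fmt = "root9(%s)"),
    "sin"  = list(arity = 1, abs = sin, cpx = sin, fmt = "sin(%s)"),
    "cos"  = list(arity = 1, abs = cos, cpx = cos, fmt = "cos(%s)"),
    "atan" = list(arity = 1, abs = atan,
                  cpx = function(x) atan(Re(x)),  # principal real branch
                  fmt = "atan(%s)"),
    "sq"   = list(arity = 1, abs = function(x) x^2, cpx = function(x) x^2,
                  fmt = "sq(%s)"),
    "cube" = list(arity = 1, abs = function(x) x^3, cpx = function(x) x^3,
                  fmt = "cube(%s)"),
    "exp"  = list(arity = 1, abs = exp_clamped, cpx = exp_clamped,
                  fmt = "exp(%s)"),
    "ln"   = list(arity = 1, abs = ln_abs, cpx = ln_cpx, fmt = "ln(%s)"),
    "inv"  = list(arity = 1,
                  abs = function(x) 1 / clamp_den(x),
                  cpx = function(x) 1 / clamp_den(x),
                  fmt = "inv(%s)"),
    "tanh" = list(arity = 1, abs = tanh,
                  cpx = function(x) tanh(Re(x)),
                  fmt = "tanh(%s)"),
    "avg2" = list(arity = 2,
                  abs = function(a, b) (a + b) / 2,
                  cpx = function(a, b) (a + b) / 2,
                  fmt = "((%s + %s) / 2)"),
    "neg"  = list(arity = 1, abs = function(x) -x, cpx = function(x) -x,
                  fmt = "(-%s)")
  )
}

#' Default symbolic-regression function set
#'
#' The operator vocabulary used when evolving new models: arithmetic,
#' square and cube roots, trigonometry, powers, exponential, logarithm,
#' inverse, hyperbolic tangent and two-input average.
#'
#' @return Character vector of symbols, a subset of `names(function_table())`.
#' @export
default_function_set <- function() {
  c("+", "-", "*", "/", "sqrt", "cbrt", "sin", "cos", "atan",
    "sq", "cube", "exp", "ln", "inv", "tanh", "avg2")
}
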