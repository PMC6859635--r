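#' Media factors
#'
#' The six media components varied in the proliferation experiments, expressed
#' as multiples of their concentration in Murashige-Skoog (MS) basal medium,
#' except the two hormones which are absolute concentrations in mg/l:
#'
#' \describe{
#'   \item{KNO3}{potassium nitrate, 0.5--2 x MS (symbol A)}
#'   \item{NH4NO3}{ammonium nitrate, 0.5--2 x MS (symbol B)}
#'   \item{mesos}{CaCl2 + KH2PO4 + MgSO4 group, 0.5--2.5 x MS (symbol C)}
#'   \item{minors}{micronutrients + chelated iron, 0.5--4 x MS (symbol D)}
#'   \item{BAP}{6-benzylaminopurine, 0.5--3 mg/l (symbol E)}
#'   \item{IBA}{indole-3-butyric acid, 0.05--0.2 mg/l (symbol F)}
#' }
#'
#' The single-letter symbols are the terminal names used inside expression
#' trees; they follow the column order of the designed experiment tables
#' (KNO3 first).
#'
#' @name media-factors
NULL

#' Factor names in design-table order
#' @return Character vector of the six factor names.
#' @export
factor_names <- function() {
  c("KNO3", "NH4NO3", "mesos", "minors", "BAP", "IBA")
}

#' Map expression-tree terminal symbols to factor names
#' @return Named character vector: names are symbols A--F, values factor names.
#' @export
factor_symbols <- function() {
  stats::setNames(factor_names(), LETTERS[1:6])
}

#' Experimental factor bounds
#'
#' The admissible range of each media factor, i.e. the box over which designs
#' are constructed and media compositions are optimized.
#'
#' @return Data frame with columns `factor`, `lo`, `hi`, `units`.
#' @export
factor_bounds <- function() {
  data.frame(
    factor = factor_names(),
    lo = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.05),
    hi = c(2.0, 2.0, 2.5, 4.0, 3.0, 0.20),
    units = c("x MS", "x MS", "x MS", "x MS", "mg/l", "mg/l"),
    stringsAsFactors = FALSE
  )
}

#' Construct a media composition (factor vector)
#'
#' @param KNO3,NH4NO3,mesos,minors,BAP,IBA Factor levels (see
#'   [media-factors]).
#' @param check If `TRUE` (default) warn when a level falls outside the
#'   experimental range; out-of-range compositions are returned unchanged.
#' @return Named numeric vector of length 6 in design-table order.
#' @examples
#' factor_vector(1.25, 0.5, 1.5, 2.25, 0.5, 0.2)
#' @export
factor_vector <- function(KNO3, NH4NO3, mesos, minors, BAP, IBA, check = TRUE) {
  x <- c(KNO3 = KNO3, NH4NO3 = NH4NO3, mesos = mesos, minors = minors,
         BAP = BAP, IBA = IBA)
  if (any(!is.finite(x))) {
    stop("all factor levels must be finite", call. = FALSE)
  }
  if (check) check_factor_ranges(x)
  x
}

#' Check factor levels against the experimental ranges
#'
#' A predicate that warns (does not reject) when levels lie outside the
#' design box; the three control media all fall inside it.
#'
#' @param x Named numeric vector of factor levels.
#' @return `TRUE` invisibly if all levels are in range, otherwise `FALSE`
#'   invisibly, with a warning naming the offending factors.
#' @export
check_factor_ranges <- function(x) {
  b <- factor_bounds()
  x <- x[b$factor]
  bad <- b$factor[x < b$lo | x > b$hi]
  if (length(bad) > 0) {
    warning("factor level(s) outside experimental range: ",
            paste(bad, collapse = ", "), call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

# Normalize user input (named vector, list, or data.frame; names may be
# factor names or symbols A-F) into a data.frame with columns A..F.
as_factor_frame <- function(x) {
  # fast path: already in canonical A..F form (hot loop of the engines)
  if (is.data.frame(x) && identical(names(x), LETTERS[1:6])) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.data.frame(as.list(x))
  } else if (is.list(x) && !is.data.frame(x)) {
    x <- as.data.frame(x)
  }
  if (!is.data.frame(x)) {
    stop("factor input must be a named vector, list or data.frame",
         call. = FALSE)
  }
  syms <- factor_symbols()
  out <- data.frame(row.names = seq_len(nrow(x)))
  for (s in names(syms)) {
    col <- if (s %in% names(x)) x[[s]] else x[[syms[[s]]]]
    if (is.null(col)) {
      stop("missing factor '", syms[[s]], "' (symbol ", s, ")", call. = FALSE)
    }
    out[[s]] <- as.numeric(col)
  }
  out
}
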