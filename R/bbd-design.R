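#' Box-Behnken designs
#'
#' Three-level response-surface designs whose runs vary a small subset of
#' factors at the +/-1 levels while holding the rest at the mid level. The
#' six-factor design used for the media experiments has 48 edge runs
#' (factors varied three at a time over six blocks) and no centre runs.
#'
#' @name bbd
NULL

#' Factor specification for coded designs
#'
#' @param name Factor name.
#' @param low,mid,high Actual levels mapped to coded -1, 0, +1.
#' @param units Unit label.
#' @return A `factor_spec` list.
#' @export
factor_spec <- function(name, low, mid, high, units = "") {
  if (!(low < mid && mid < high)) {
    stop("levels must satisfy low < mid < high for factor '", name, "'",
         call. = FALSE)
  }
  structure(list(name = name, low = low, mid = mid, high = high,
                 units = units), class = "factor_spec")
}

#' The media-experiment factor levels
#'
#' Low/mid/high actual levels of the six media factors. The IBA mid level
#' is 0.125 mg/l (printed designs round it to 0.13).
#'
#' @return List of six [factor_spec()] objects in design-table order.
#' @export
media_factor_specs <- function() {
  list(
    factor_spec("KNO3",   0.50, 1.25, 2.00, "x MS"),
    factor_spec("NH4NO3", 0.50, 1.25, 2.00, "x MS"),
    factor_spec("mesos",  0.50, 1.50, 2.50, "x MS"),
    factor_spec("minors", 0.50, 2.25, 4.00, "x MS"),
    factor_spec("BAP",    0.50, 1.75, 3.00, "mg/l"),
    factor_spec("IBA",    0.05, 0.125, 0.20, "mg/l")
  )
}

# Blocks (subsets of factors varied together) for the edge-run BBD.
# k = 6 and k = 7 use the classical three-at-a-time blocking; other k vary
# factors pairwise.
bbd_blocks <- function(k) {
  if (k == 6) {
    list(c(1, 2, 4), c(2, 3, 5), c(3, 4, 6), c(1, 4, 5), c(2, 5, 6),
         c(1, 3, 6))
  } else if (k == 7) {
    list(c(4, 5, 6), c(1, 6, 7), c(2, 5, 7), c(1, 2, 4), c(3, 4, 7),
         c(1, 3, 5), c(2, 3, 6))
  } else {
    utils::combn(k, 2, simplify = FALSE)
  }
}

#' Generate a Box-Behnken design in coded units
#'
#' Builds the edge-run set: for each block of factors, all +/-1 sign
#' combinations with the remaining factors at 0. Runs are deduplicated and
#' ordered lexicographically by block then signs. For `k = 6` this yields
#' exactly 48 runs.
#'
#' @param k Number of factors (>= 3).
#' @param n_center Number of all-mid centre runs appended (default 0,
#'   matching the media experiments).
#' @return Matrix of coded runs (entries -1, 0, +1), one row per run.
#' @examples
#' nrow(bbd_generate(6))  # 48
#' @export
bbd_generate <- function(k, n_center = 0) {
  if (!is.numeric(k) || k < 3) stop("k must be >= 3", call. = FALSE)
  k <- as.integer(k)
  blocks <- bbd_blocks(k)
  rows <- list()
  for (b in blocks) {
    m <- length(b)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
    # lexicographic over sign combinations
    signs <- signs[do.call(order, as.data.frame(signs)), , drop = FALSE]
    for (i in seq_len(nrow(signs))) {
      run <- rep(0, k)
      run[b] <- signs[i, ]
      rows[[length(rows) + 1]] <- run
    }
  }
  mat <- unique(do.call(rbind, rows))
  if (n_center > 0) {
    mat <- rbind(mat, matrix(0, nrow = n_center, ncol = k))
  }
  dimnames(mat) <- list(NULL, paste0("X", seq_len(k)))
  mat
}

check_coded <- function(coded) {
  if (!all(coded %in% c(-1, 0, 1))) {
    stop("coded levels must be -1, 0 or +1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert coded levels to actual factor levels
#'
#' @param coded Numeric vector or matrix of coded levels in \{-1, 0, +1\}.
#' @param specs List of [factor_spec()]s, one per column (default the media
#'   factors).
#' @return Numeric vector or data frame of actual levels, named by factor.
#' @export
code_to_actual <- function(coded, specs = media_factor_specs()) {
  vec <- is.null(dim(coded))
  m <- if (vec) matrix(coded, nrow = 1) else as.matrix(coded)
  if (ncol(m) != length(specs)) {
    stop("coded vector length must match number of factor specs",
         call. = FALSE)
  }
  check_coded(m)
  out <- vapply(seq_along(specs), function(j) {
    s <- specs[[j]]
    c(s$low, s$mid, s$high)[m[, j] + 2]
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m))
  colnames(out) <- vapply(specs, `[[`, "", "name")
  if (vec) out[1, ] else as.data.frame(out)
}

#' Convert actual factor levels to coded levels
#'
#' Matches each value to the nearest of the three spec levels; printed
#' designs round levels (e.g. IBA mid 0.125 prints as 0.13), so matching
#' uses an absolute tolerance.
#'
#' @param actual Numeric vector or matrix of actual levels.
#' @param specs List of [factor_spec()]s.
#' @param tol Level-matching tolerance (default 0.01).
#' @return Vector or matrix of coded levels.
#' @export
actual_to_code <- function(actual, specs = media_factor_specs(), tol = 0.01) {
  vec <- is.null(dim(actual))
  m <- if (vec) matrix(actual, nrow = 1) else as.matrix(actual)
  if (ncol(m) != length(specs)) {
    stop("actual vector length must match number of factor specs",
         call. = FALSE)
  }
  out <- vapply(seq_along(specs), function(j) {
    s <- specs[[j]]
    lv <- c(s$low, s$mid, s$high)
    idx <- apply(abs(outer(m[, j], lv, "-")), 1, which.min)
    dev <- abs(m[, j] - lv[idx])
    if (any(dev > tol)) {
      stop("level(s) of factor '", s$name, "' do not match any design level ",
           "within tolerance ", tol, call. = FALSE)
    }
    c(-1, 0, 1)[idx]
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(NULL, vapply(specs, `[[`, "", "name")))
  if (vec) out[1, ] else out
}

#' Load the 48-run media design
#'
#' The designed experiment actually run for both rootstocks, in its printed
#' run order and actual (rounded) factor levels.
#'
#' @return Data frame with columns `medium_id` and the six factors.
#' @export
load_paper_design <- function() {
  path <- pearmedia_extdata("bbd_design_48run.csv")
  check_fixture_digest(path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
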