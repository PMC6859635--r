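#' Model-comparison statistics
#'
#' The four indices used to compare fitted models, with observed values
#' \eqn{O_i} and predictions \eqn{P_i}:
#' \deqn{RMSE = \sqrt{\sum (O_i - P_i)^2 / N}}
#' \deqn{MARE = \frac{1}{N'} \sum |(O_i - P_i) / O_i|}
#' \deqn{MBE = \frac{1}{N} \sum (O_i - P_i)}
#' \deqn{r = \frac{\sum (O_i - \bar O)(P_i - \bar P)}
#'            {\sqrt{\sum (O_i - \bar O)^2 \sum (P_i - \bar P)^2}}}
#' MARE terms with \eqn{O_i = 0} are undefined and excluded (their count is
#' reported); incidence responses legitimately contain zeros. The printed
#' correlation formula is a Pearson correlation without squaring, so both
#' `r` and `r_squared = r^2` are reported.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return A `metrics_report`: list with `rmse`, `mare`, `n_excluded_mare`,
#'   `mbe`, `r`, `r_squared`, `n`. `r` is `NA` when either vector is
#'   constant.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  nz <- observed != 0
  mare <- if (any(nz)) mean(abs(err[nz] / observed[nz])) else NA_real_
  mbe <- mean(err)
  r <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    NA_real_
  } else {
    stats::cor(observed, predicted)
  }
  structure(list(rmse = rmse, mare = mare, n_excluded_mare = sum(!nz),
                 mbe = mbe, r = r, r_squared = r^2, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RMSE %.4f  MARE %.4f  MBE %+.4f  r2 %.4f  (n = %d",
              x$rmse, x$mare, x$mbe, x$r_squared, x$n))
  if (x$n_excluded_mare > 0) {
    cat(",", x$n_excluded_mare, "zero-observation term(s) excluded from MARE")
  }
  cat(")\n")
  invisible(x)
}

#' Tabulate metrics reports
#'
#' @param reports Named list of `metrics_report`s (names identify models).
#' @return Data frame with one row per report.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]
    data.frame(model = nm, rmse = m$rmse, mare = m$mare, mbe = m$mbe,
               r_squared = m$r_squared, n = m$n,
               stringsAsFactors = FALSE)
  }))
}
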