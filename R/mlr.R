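#' Multiple linear regression baseline
#'
#' Ordinary least squares on the six media factors (main effects only;
#' an optional quadratic expansion adds squared terms). This is the
#' conventional benchmark the nonlinear models are compared against.
#'
#' @param train Data frame with the factor columns and the response.
#' @param response Response column name.
#' @param quadratic Add squared factor terms (default `FALSE`).
#' @param inputs Input column names (default the six media factors).
#' @return An `mlr_model`: list with `fit` (the underlying `lm`),
#'   `coefficients`, `response` and `inputs`.
#' @examples
#' d <- load_dataset("OHF")
#' m <- fit_mlr(d, "PR")
#' coef(m$fit)
#' @export
fit_mlr <- function(train, response, quadratic = FALSE,
                    inputs = factor_names()) {
  stopifnot(is.data.frame(train))
  y <- train[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  x <- train[, inputs, drop = FALSE]
  if (quadratic) {
    for (nm in inputs) x[[paste0(nm, "_sq")]] <- x[[nm]]^2
  }
  if (nrow(x) <= ncol(x) + 1) {
    stop("need more records than parameters", call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(x))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- cbind(x, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 response = response, inputs = names(x)),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  for (nm in object$inputs) {
    if (!nm %in% names(nd) && endsWith(nm, "_sq")) {
      nd[[nm]] <- nd[[sub("_sq$", "", nm)]]^2
    }
  }
  as.numeric(stats::predict(object$fit, newdata = nd))
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("<mlr_model> response:", x$response, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Export an MLR coefficient table
#'
#' @param model An `mlr_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_mlr_coefficients <- function(model, path) {
  utils::write.csv(data.frame(term = names(model$coefficients),
                              estimate = unname(model$coefficients)),
                   path, row.names = FALSE)
  invisible(path)
}
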