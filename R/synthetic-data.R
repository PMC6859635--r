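#' Synthetic replicate-level observations
#'
#' The published dataset contains only per-medium means, but the modelling
#' protocol operates on replicate-level records (51 media x 10 replicate
#' jars = 510 observations per rootstock). This module generates such
#' records from a known ground-truth response surface plus Gaussian noise,
#' so every downstream stage (splitting, fitting, evaluation, optimization)
#' is testable end to end with a known truth.
#'
#' @name synthetic-data
NULL

#' Specify a ground-truth response surface
#'
#' @param ground_truth Named list mapping response name to a function of a
#'   factor data frame returning the noiseless response.
#' @param noise_sd Named numeric vector of Gaussian noise standard
#'   deviations per response (>= 0).
#' @param replicates Replicate jars per medium (default 10).
#' @param response_bounds Named list of `c(lo, hi)` bounds used to clip
#'   generated values.
#' @return A `surface_spec` list.
#' @export
surface_spec <- function(ground_truth, noise_sd, replicates = 10,
                         response_bounds = default_response_bounds()) {
  stopifnot(is.list(ground_truth), length(ground_truth) > 0)
  if (!all(names(ground_truth) %in% names(noise_sd))) {
    stop("noise_sd must name every response in ground_truth", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  for (r in names(ground_truth)) {
    b <- response_bounds[[r]]
    if (is.null(b) || !(b[1] < b[2])) {
      stop("response_bounds must give ordered (lo, hi) for '", r, "'",
           call. = FALSE)
    }
  }
  structure(list(ground_truth = ground_truth, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 response_bounds = response_bounds),
            class = "surface_spec")
}

#' Default response bounds
#'
#' Incidences (STN, Vitri) are percentages in \[0, 100\], the quality index
#' is a 1--5 score, and counts/lengths (PR, SL) are non-negative.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_response_bounds <- function() {
  list(PR = c(0, Inf), SL = c(0, Inf), STN = c(0, 100), Vitri = c(0, 100),
       QI = c(1, 5))
}

#' Surface spec built from the published models
#'
#' Ground truth is the set of five published equations for the rootstock
#' (evaluated under the `"abs"` convention, which reproduces their fit to
#' the observed means); a single `noise_sd` value is interpreted as a
#' fraction irrelevant -- it is used as the common standard deviation unless
#' a named vector is supplied.
#'
#' @param rootstock `"Pyrodwarf"` or `"OHF"`.
#' @param noise_sd Single value or named per-response vector of noise SDs.
#'   The default scales each response's noise to 10% of its observed range
#'   in the packaged dataset.
#' @param replicates Replicate jars per medium (default 10).
#' @return A [surface_spec()].
#' @export
spec_from_published <- function(rootstock, noise_sd = NULL, replicates = 10) {
  rootstock <- match_rootstock(rootstock)
  responses <- response_names()
  gt <- lapply(responses, function(rp) {
    tree <- published_model(rootstock, rp)
    function(x) evaluate_tree(tree, x, convention = "abs")
  })
  names(gt) <- responses
  if (is.null(noise_sd)) {
    d <- load_dataset(rootstock)
    noise_sd <- vapply(responses, function(rp) {
      0.1 * diff(range(d[[rp]]))
    }, numeric(1))
  } else if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(responses)), responses)
  }
  surface_spec(gt, noise_sd, replicates = replicates)
}

#' Generate replicate-level observations
#'
#' Each design point is replicated `spec$replicates` times; every response
#' is `clip(truth + N(0, sd), lo, hi)`, with PR additionally rounded to
#' quarter-shoot resolution to mimic per-jar count averaging.
#'
#' @param design Data frame of factor levels (one row per medium); a
#'   `medium_id` column is carried through if present.
#' @param spec A [surface_spec()].
#' @param seed Integer seed.
#' @return Data frame with `medium_id`, `replicate_id`, the factor columns
#'   and one column per response; `nrow = nrow(design) * spec$replicates`.
#' @examples
#' des <- load_paper_design()
#' spc <- spec_from_published("Pyrodwarf", noise_sd = 0)
#' reps <- generate_replicates(des[1:3, ], spc, seed = 1)
#' @export
generate_replicates <- function(design, spec, seed = 1) {
  stopifnot(inherits(spec, "surface_spec"))
  if (!is.data.frame(design)) design <- as.data.frame(design)
  if (nrow(design) == 0) stop("design must be non-empty", call. = FALSE)
  n <- nrow(design)
  reps <- spec$replicates
  idx <- rep(seq_len(n), each = reps)
  out <- design[idx, intersect(factor_names(), names(design)), drop = FALSE]
  out <- data.frame(
    medium_id = if ("medium_id" %in% names(design)) design$medium_id[idx]
                else as.character(idx),
    replicate_id = rep(seq_len(reps), times = n),
    out, row.names = NULL, stringsAsFactors = FALSE
  )
  with_rng_seed(seed, {
    for (rp in names(spec$ground_truth)) {
      truth <- spec$ground_truth[[rp]](design)
      val <- rep(truth, each = reps) +
        stats::rnorm(n * reps, 0, spec$noise_sd[[rp]])
      # quarter-shoot resolution mimics count averaging over jars; skipped
      # in the noiseless case so the generator is then exactly the identity
      if (rp == "PR" && spec$noise_sd[[rp]] > 0) val <- round(val * 4) / 4
      b <- spec$response_bounds[[rp]]
      out[[rp]] <- pmin(pmax(val, b[1]), b[2])
    }
  })
  out
}
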