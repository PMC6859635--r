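#' Packaged experiment data
#'
#' Per-medium mean growth responses for the 48 designed media plus three
#' control media (MS, WPM, QL basal formulations, all at 1x MS factor levels
#' with 2.5 mg/l BAP and 0.2 mg/l IBA), for each rootstock. Values are the
#' printed per-medium means; the underlying experiment used at least ten
#' replicate jars per medium, whose raw values were never published (see
#' [generate_replicates()] for emulating them).
#'
#' @name paper-data
NULL

FIXTURE_DIGESTS <- c(
  "bbd_design_48run.csv" = "6ce58f13d008da8b41d7b06457e0078b",
  "ohf_media_means.csv"        = "99c11d4747990eb207902e942c947526",
  "pyrodwarf_media_means.csv"  = "eab8793aad387d9ed53b685dcd84900b"
)

pearmedia_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pearmedia")
  if (path == "") {
    # during development (package not installed) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    stop("packaged fixture '", file, "' not found", call. = FALSE)
  }
  path
}

check_fixture_digest <- function(path) {
  file <- basename(path)
  expected <- FIXTURE_DIGESTS[[file]]
  if (is.null(expected)) return(invisible(TRUE))
  got <- unname(tools::md5sum(path))
  if (!identical(got, expected)) {
    stop("fixture '", file, "' failed its integrity check (md5 ", got,
         ", expected ", expected, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load the per-medium growth dataset for a rootstock
#'
#' @param rootstock `"Pyrodwarf"` or `"OHF"`.
#' @return Data frame of 51 media (48 designed + MS, WPM, QL controls) with
#'   columns `medium_id`, the six factors (see [media-factors]) and the five
#'   responses `PR`, `SL`, `STN`, `Vitri`, `QI`, in printed order.
#' @examples
#' head(load_dataset("OHF"))
#' @export
load_dataset <- function(rootstock) {
  rootstock <- match_rootstock(rootstock)
  file <- if (rootstock == "OHF") "ohf_media_means.csv" else "pyrodwarf_media_means.csv"
  path <- pearmedia_extdata(file)
  check_fixture_digest(path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 51)
  d
}

# run expr with a temporarily seeded RNG, restoring prior state
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split records into training and test sets
#'
#' Uniform sampling without replacement, reproducible from `seed`. The
#' modelling protocol draws 70% of the replicate-level observations for
#' training (357 of 510) and keeps the rest for testing.
#'
#' @param records Data frame of observation records.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train`, `test` (disjoint data frames whose
#'   row counts are `round(n * train_fraction)` and the remainder) and
#'   `seed`.
#' @examples
#' sp <- split_train_test(data.frame(y = 1:10), 0.7, seed = 1)
#' nrow(sp$train)  # 7
#' @export
split_train_test <- function(records, train_fraction = 0.7, seed = 1) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(records)
  n_train <- round(n * train_fraction)
  idx <- with_rng_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE],
       seed = seed)
}
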