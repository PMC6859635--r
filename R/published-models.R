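#' Published media-response models
#'
#' Hard-coded transcriptions of the ten published gene-expression-programming
#' equations relating the six media factors to the five growth responses
#' (PR, SL, STN, Vitri, QI) for the rootstocks Pyrodwarf and OHF. Each model
#' is the sum of three sub-expressions (three genes linked by addition);
#' constants are kept at full printed precision.
#'
#' Terminal symbols follow the designed-experiment column order:
#' A = KNO3, B = NH4NO3, C = mesos, D = minors, E = BAP, F = IBA.
#' The typeset equations elsewhere gloss A as NH4NO3 and B as KNO3; that
#' gloss is inconsistent with the observed data, against which the mapping
#' used here reproduces the published goodness-of-fit for six of the ten
#' equations (see the methods vignette for the evidence). The published
#' optimization table is read in the same column order.
#'
#' @name published-models
NULL

# Three quoted gene-terms per model, linked by addition in published_model().
published_model_terms <- function() {
  list(
    Pyrodwarf = list(
      PR = list(
        quote(exp((F - B) * C) - D),
        quote(inv(ln((sqrt((E - 2.1016) / 2) + E) / 2)) + D),
        quote(sq(cbrt(3.1775 - C)) + cbrt(exp(A) / (C + 0.11065)))
      ),
      SL = list(
        quote(cbrt(ln(cube(D))) + (F * (((C + A) / 2) * E))),
        quote(2.4011 *
                sq((((((E + 1.7251) / 2) * 2.7057) + (1.7251 - B)) / 2) - E)),
        quote(cbrt(2.3488 * ((inv(E) - 7.0907) + (E - D))))
      ),
      STN = list(
        quote(((D + (sqrt(C) * (F - E))) / 2) + exp(A - C)),
        quote((B - (((6.1753 / E) + E) / 2)) + ((9.3446 * A) * ln(B))),
        quote((((ln(F) + (11.3038 / A)) - E + 1.0814) +
                 (15.0404 * sq(A))) / 2)
      ),
      Vitri = list(
        quote((((exp(B) * B) * inv(C)) / 2) - (D - B) - 1.5069),
        quote(((exp(2.988 - D) + ((A - 9.0917) / 2)) / 2) *
                ((2 * B) - (B * D))),
        quote((((((E + B) / 2) + B) / 2 + F + 8.8145) / 2) *
                (((A + B) / 2) + (2 * B)))
      ),
      QI = list(
        quote(root9((D * A) / (sqrt(C) * B))),
        quote(cbrt(inv(((E / 30.7869) + B) / 2) + (0.9692 - A - B))),
        quote(root6((exp(C) * (10.3785 + F)) + inv(F) - A))
      )
    ),
    OHF = list(
      PR = list(
        quote(sqrt((0.0894 * D * B) + inv(A + E))),
        quote(cbrt((-8.5762 / A) - 6.8234) * inv(3.2661 - E)),
        quote(((((C + 0.1838) / 2) + 6.8196) / 2) + inv(C) + ((B * F) - B))
      ),
      SL = list(
        quote((ln((B + 4.8333) / 2) + (((D + 4.7651) / 2) - (A + B))) / 2),
        quote(C + exp((-2.8335 * A) * (((D - 6.4679) + (9.3060 * C)) / 2))),
        quote(exp(((((3.8362 * F) - A) + ((E + 3.1237) / 2)) / 2) -
                    inv(3.4882 - E)))
      ),
      STN = list(
        quote(sq(B) - cbrt(((C / E) + 8.1303) / ln(A))),
        quote((exp(A) + cube(C)) - C),
        quote(F + ((D + (sq(-4.4380 / C) - (6.1907 / B))) / 2))
      ),
      Vitri = list(
        quote(E * (A + ((((E - 0.8805) / 2) * B) / (F + A)))),
        quote((A - (cbrt(A) - 6.8169)) / sq(D)),
        quote(((A + (2 * D) - 6.8579) / 2) * ((sq(D) + (B / A)) / 2))
      ),
      QI = list(
        quote(sqrt(cube(root4(((inv(E) + 8.3712) / 2) * (C - F))))),
        quote(inv(((C - 5.1079) * sqrt(D)) * ((C * A) - 5.0292))),
        quote((inv(B) + ln(ln(C / 0.3661) * (D + F))) / 2)
      )
    )
  )
}

#' Rootstocks with published models
#' @return Character vector of rootstock names.
#' @export
rootstock_names <- function() c("Pyrodwarf", "OHF")

#' Growth responses with published models
#' @return Character vector of response names: proliferation rate (PR,
#'   shoots per explant), shoot length (SL, cm), shoot-tip necrosis
#'   (STN, %), vitrification (Vitri, %), quality index (QI, 1--5 score).
#' @export
response_names <- function() c("PR", "SL", "STN", "Vitri", "QI")

match_rootstock <- function(rootstock) {
  i <- match(tolower(rootstock), tolower(rootstock_names()))
  if (is.na(i)) {
    stop("unknown rootstock '", rootstock, "'; valid: ",
         paste(rootstock_names(), collapse = ", "), call. = FALSE)
  }
  rootstock_names()[i]
}

match_response <- function(response) {
  aliases <- c(stats::setNames(response_names(), tolower(response_names())),
               ql = "QI", vit = "Vitri", vitrification = "Vitri")
  out <- aliases[tolower(response)]
  if (is.na(out)) {
    stop("unknown response '", response, "'; valid: ",
         paste(response_names(), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Retrieve a published model as an expression tree
#'
#' @param rootstock `"Pyrodwarf"` or `"OHF"`.
#' @param response One of `r paste(response_names(), collapse = ", ")`.
#' @return A `gep_tree` whose top node links three gene sub-trees by
#'   addition; the sub-trees are attached as attribute `gene_terms`.
#' @examples
#' published_model("Pyrodwarf", "PR")
#' @export
published_model <- function(rootstock, response) {
  rootstock <- match_rootstock(rootstock)
  response <- match_response(response)
  terms <- published_model_terms()[[rootstock]][[response]]
  genes <- lapply(terms, as_gep_tree)
  tree <- Reduce(function(a, b) tree_node("+", a, b), genes)
  attr(tree, "gene_terms") <- genes
  attr(tree, "rootstock") <- rootstock
  attr(tree, "response") <- response
  tree
}

#' Predict a growth response from a published model
#'
#' @inheritParams published_model
#' @param x Media composition(s); see [evaluate_tree()].
#' @param convention Protected-operator convention (see [protected-ops]).
#'   `"abs"` reproduces the models' fit to the observed per-medium means;
#'   `"complex"` reproduces the published optimization table.
#' @return Numeric vector of predicted response values.
#' @examples
#' predict_published("Pyrodwarf", "SL",
#'   factor_vector(1.83, 0.51, 1.74, 2.60, 0.59, 0.16))
#' @export
predict_published <- function(rootstock, response, x,
                              convention = c("abs", "complex")) {
  convention <- match.arg(convention)
  evaluate_tree(published_model(rootstock, response), x,
                convention = convention)
}

#' Export the published-model registry
#'
#' Writes all ten models as a JSON array of
#' `{rootstock, response, formula}` records; formulas round-trip through
#' [parse_formula()].
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_model_registry <- function(path) {
  rows <- do.call(rbind, lapply(rootstock_names(), function(rs) {
    do.call(rbind, lapply(response_names(), function(rp) {
      data.frame(rootstock = rs, response = rp,
                 formula = to_formula_string(published_model(rs, rp)),
                 stringsAsFactors = FALSE)
    }))
  }))
  jsonlite::write_json(rows, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
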