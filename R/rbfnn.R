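#' Radial-basis-function network regression
#'
#' A single-hidden-layer network whose hidden units are Gaussian functions
#' of the distance to learned centers:
#' \deqn{Y(x) = \sum_j W_j \exp(-\|x - c_j\|^2 / (2 \sigma_j^2)) + b.}
#' Centers and widths are fixed after initialization (k-means centers,
#' nearest-center widths); the output weights and bias are trained by
#' batch gradient descent on mean squared error. Inputs are standardized to
#' zero mean and unit variance internally.
#'
#' @name rbfnn
NULL

#' Predict from an RBF network
#'
#' @param net An `rbf_network` from [train_rbf()] or [rbf_network()].
#' @param x Numeric vector, matrix or data frame of inputs in the network's
#'   original (unstandardized) input space.
#' @return Numeric vector of predictions.
#' @export
rbf_predict <- function(net, x) {
  stopifnot(inherits(net, "rbf_network"))
  m <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(m) != ncol(net$centers)) {
    stop("input dimension ", ncol(m), " does not match network dimension ",
         ncol(net$centers), call. = FALSE)
  }
  z <- sweep(sweep(m, 2, net$center_shift), 2, net$center_scale, "/")
  phi <- rbf_activations(z, net$centers, net$widths)
  as.numeric(phi %*% net$weights + net$bias)
}

rbf_activations <- function(z, centers, widths) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(z)), rowSums(centers^2)) - 2 * z %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-sweep(d2, 2, 2 * widths^2, "/"))
}

#' Construct an RBF network directly
#'
#' @param centers Matrix of hidden-unit centers (standardized space).
#' @param widths Positive numeric vector of unit widths.
#' @param weights Output weights, one per hidden unit.
#' @param bias Output bias.
#' @param center_shift,center_scale Input standardization constants.
#' @return An `rbf_network`.
#' @export
rbf_network <- function(centers, widths, weights, bias,
                        center_shift = rep(0, ncol(centers)),
                        center_scale = rep(1, ncol(centers))) {
  centers <- as.matrix(centers)
  if (any(widths <= 0)) stop("widths must be positive", call. = FALSE)
  if (nrow(centers) != length(widths) ||
      nrow(centers) != length(weights)) {
    stop("centers, widths and weights must agree in hidden-unit count",
         call. = FALSE)
  }
  structure(list(centers = centers, widths = widths,
                 weights = as.numeric(weights), bias = bias,
                 center_shift = center_shift, center_scale = center_scale,
                 loss = numeric(0)),
            class = "rbf_network")
}

#' Train an RBF network
#'
#' Centers are initialized by k-means on the standardized inputs, widths by
#' the distance to the nearest other center; output weights and bias start
#' at zero and are updated by full-batch gradient descent on MSE. With
#' `epochs = 0` the initialization is returned unchanged.
#'
#' @param train Data frame containing the factor columns and the response.
#' @param response Response column name.
#' @param n_hidden Hidden-unit count (>= 1).
#' @param learning_rate Positive gradient-descent step size.
#' @param epochs Number of full-batch updates.
#' @param seed Integer seed (k-means initialization).
#' @param inputs Input column names (default the six media factors).
#' @return An `rbf_network` with a `loss` vector (MSE per epoch).
#' @export
train_rbf <- function(train, response, n_hidden = 10, learning_rate = 0.05,
                      epochs = 500, seed = 1, inputs = factor_names()) {
  stopifnot(is.data.frame(train))
  if (n_hidden < 1) stop("n_hidden must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive",
                               call. = FALSE)
  y <- train[[response]]
  if (is.null(y)) stop("response column '", response, "' not found",
                       call. = FALSE)
  x <- as.matrix(train[, inputs, drop = FALSE])
  if (nrow(x) < n_hidden) stop("need at least n_hidden training records",
                               call. = FALSE)
  shift <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, shift), 2, scale, "/")
  centers <- with_rng_seed(seed, {
    uz <- unique(z)
    if (nrow(uz) <= n_hidden) {
      uz
    } else {
      stats::kmeans(z, centers = n_hidden, nstart = 5,
                    iter.max = 50)$centers
    }
  })
  centers <- as.matrix(centers)
  nh <- nrow(centers)
  widths <- if (nh == 1) {
    rep(mean(sqrt(rowSums(sweep(z, 2, centers[1, ])^2))) + 1e-8, 1)
  } else {
    dc <- as.matrix(stats::dist(centers))
    diag(dc) <- Inf
    apply(dc, 1, min)
  }
  widths[widths <= 0 | !is.finite(widths)] <- 1
  net <- rbf_network(centers, widths, weights = rep(0, nh), bias = 0,
                     center_shift = shift, center_scale = scale)
  phi <- rbf_activations(z, centers, widths)
  tphi <- t(phi)
  w <- net$weights
  b <- net$bias
  n <- length(y)
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    resid <- y - (phi %*% w + b)
    w <- w + learning_rate * 2 / n * as.numeric(tphi %*% resid)
    b <- b + learning_rate * 2 / n * sum(resid)
    loss[ep] <- mean((y - (phi %*% w + b))^2)
  }
  net$weights <- w
  net$bias <- b
  net$loss <- loss
  net$response <- response
  net
}

#' Choose the hidden-unit count by held-out error
#'
#' Fits candidate networks and returns the one with the lowest RMSE on a
#' held-out subset.
#'
#' @inheritParams train_rbf
#' @param candidates Hidden-unit counts to try.
#' @param holdout_fraction Fraction of `train` held out for selection.
#' @return The selected `rbf_network`, refit on all of `train`; the
#'   candidate RMSEs are attached as attribute `selection`.
#' @export
select_rbf <- function(train, response, candidates = c(5, 10, 15, 20),
                       learning_rate = 0.05, epochs = 500, seed = 1,
                       holdout_fraction = 0.25) {
  sp <- split_train_test(train, 1 - holdout_fraction, seed = seed)
  rmse <- vapply(candidates, function(nh) {
    nh <- min(nh, nrow(sp$train))
    net <- train_rbf(sp$train, response, n_hidden = nh,
                     learning_rate = learning_rate, epochs = epochs,
                     seed = seed)
    sqrt(mean((sp$test[[response]] - rbf_predict(net, as.matrix(
      sp$test[, factor_names(), drop = FALSE])))^2))
  }, numeric(1))
  best <- candidates[which.min(rmse)]
  net <- train_rbf(train, response, n_hidden = best,
                   learning_rate = learning_rate, epochs = epochs,
                   seed = seed)
  attr(net, "selection") <- data.frame(n_hidden = candidates, rmse = rmse)
  net
}

#' @export
predict.rbf_network <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, factor_names(), drop = FALSE])
  }
  rbf_predict(object, newdata)
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("<rbf_network> ", nrow(x$centers), " Gaussian unit(s), ",
      ncol(x$centers), " input(s)\n", sep = "")
  invisible(x)
}
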