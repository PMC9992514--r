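#' Ridge autoregressor configuration
#'
#' @param l2_penalty Non-negative L2 penalty on the (non-intercept)
#'   weights.
#' @param learning_rate Gradient-descent step size; \code{NULL} (default)
#'   picks 1/L from the curvature of the quadratic objective.
#' @param max_epochs Maximum gradient steps (default 5000).
#' @param tol Gradient-norm convergence tolerance (default 1e-10).
#' @param seed Recorded for provenance (the fit is deterministic).
#' @export
ridge_config <- function(l2_penalty = 1.0, learning_rate = NULL,
                         max_epochs = 5000, tol = 1e-10, seed = 1) {
  assert_that(l2_penalty >= 0, "trop_argument_error",
              "l2_penalty must be >= 0")
  structure(list(l2_penalty = l2_penalty, learning_rate = learning_rate,
                 max_epochs = max_epochs, tol = tol,
                 seed = as.integer(seed)),
            class = "ridge_config")
}

flatten_windows <- function(ws) {
  n <- length(ws)
  h <- dim(ws$inputs)[2]; d <- dim(ws$inputs)[3]
  matrix(aperm(ws$inputs, c(1, 3, 2)), nrow = n)
}

#' Fit a ridge autoregressor over flattened history windows
#'
#' Minimizes \eqn{\|y - b_0 - X w\|^2 + \lambda \|w\|^2} (intercept
#' unpenalized) by deterministic gradient descent with momentum; the
#' solution agrees with the closed-form ridge estimate to the stated
#' tolerance.
#'
#' @param windows A \code{window_set}.
#' @param config A \code{ridge_config}.
#' @return A list with \code{weights} (named, intercept first),
#'   \code{config} and \code{n_iter}; class \code{ridge_model}.
#' @export
ridge_fit <- function(windows, config = ridge_config()) {
  X <- flatten_windows(windows)
  y <- windows$targets
  assert_that(all(is.finite(X)) && all(is.finite(y)), "trop_data_error",
              "non-finite values in training windows")
  # unpenalized intercept handled by centering: gradient descent runs on
  # the centered problem, the intercept follows analytically; the fixed
  # point equals the closed-form ridge solution with intercept excluded
  # from the penalty
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  lam <- config$l2_penalty
  # gradient of f(w) = (||yc - Xc w||^2 + lam ||w||^2) / (2n)
  G <- crossprod(Xc) / n
  b <- drop(crossprod(Xc, yc)) / n
  lr <- config$learning_rate
  if (is.null(lr)) {
    L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) +
      lam / n
    lr <- 1 / L
  }
  w <- numeric(ncol(X))
  vel <- numeric(ncol(X))
  mom <- 0.9
  it <- 0L
  for (it in seq_len(config$max_epochs)) {
    grad <- drop(G %*% w) - b + lam * w / n
    if (sqrt(sum(grad^2)) < config$tol) break
    vel <- mom * vel - lr * grad
    w <- w + vel
  }
  w <- c(ym - sum(xm * w), w)
  names(w) <- c("(Intercept)", paste0("x", seq_along(xm)))
  structure(list(weights = w, config = config, n_iter = it),
            class = "ridge_model")
}

ridge_predict <- function(model, windows) {
  X <- cbind(1, flatten_windows(windows))
  drop(X %*% model$weights)
}

#' Heuristic level forecasts from an observed series
#'
#' \code{"last"} predicts the final observed level again (zero change);
#' \code{"mean"} predicts the arithmetic mean of the last \code{k}
#' observed levels.
#'
#' @param series Observed levels, oldest first.
#' @param kind \code{"last"} or \code{"mean"}.
#' @param k Number of trailing observations for \code{"mean"} (default 4).
#' @return Scalar predicted level.
#' @export
baseline_predict <- function(series, kind = c("last", "mean"), k = 4) {
  kind <- match.arg(kind)
  n <- length(series)
  assert_that(n >= 1, "trop_argument_error", "series is empty")
  if (kind == "last") return(series[n])
  assert_that(k >= 1 && k <= n, "trop_argument_error",
              "k = %d exceeds series length %d", k, n)
  mean(series[(n - k + 1):n])
}
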