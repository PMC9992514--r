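#' First difference of an ordered series
#'
#' The single "integration step": replaces a level series by its
#' consecutive year-over-year changes, dropping the first element.
#'
#' @param series Numeric vector of length >= 2.
#' @return Numeric vector of length \code{length(series) - 1} with
#'   \code{out[i] = series[i + 1] - series[i]}.
#' @export
difference <- function(series) {
  assert_that(length(series) >= 2, "trop_argument_error",
              "difference() needs a series of length >= 2")
  diff(series)
}

#' Reconstruct a level forecast from a predicted change
#'
#' Adds the predicted next-step change back onto the last observed level:
#' \eqn{Y_{t+1} = Y_t + P_t}.
#'
#' @param last_level Last observed level \eqn{Y_t}.
#' @param predicted_change Predicted change \eqn{P_t}.
#' @return The reconstructed level.
#' @export
reconstruct <- function(last_level, predicted_change) {
  last_level + predicted_change
}

#' Build sliding history windows over differenced feature sequences
#'
#' For each county and each requested target year, takes the
#' \code{history} consecutive differenced steps immediately preceding the
#' target change as model input, and the outcome change into the target
#' year as the training/evaluation target. Each step vector holds the
#' outcome change into its year; covariates are either their changes (the
#' sequence's differencing flag on) or their levels at the step's year.
#'
#' @param sequences List of \code{feature_sequence} from
#'   [build_sequences()].
#' @param history Number of differenced steps per window (>= 1).
#' @param target_years Years whose change is to be predicted.
#' @return A \code{window_set}: list with \code{inputs} (windows x
#'   history x dim array), \code{targets} (outcome change per window) and
#'   \code{anchors} (data frame: fips, anchor year \eqn{t}, anchor level
#'   \eqn{Y_t}, target year \eqn{t+1}).
#' @export
make_windows <- function(sequences, history, target_years) {
  assert_that(history >= 1, "trop_argument_error", "history must be >= 1")
  dims <- vapply(sequences, function(s) ncol(s$values), integer(1))
  assert_that(length(unique(dims)) == 1, "trop_argument_error",
              "sequences have inconsistent feature dimensions")
  d <- dims[1]
  n <- length(sequences) * length(target_years)
  inputs <- array(NA_real_, c(n, history, d))
  targets <- numeric(n)
  anchors <- data.frame(fips = character(n), anchor_year = integer(n),
                        anchor_level = numeric(n), target_year = integer(n),
                        truth_level = numeric(n), stringsAsFactors = FALSE)
  w <- 0L
  for (s in sequences) {
    years <- s$years
    for (ty in target_years) {
      # target change spans (ty-1, ty); inputs span (ty-1-history, ty-1)
      first_needed <- ty - 1L - history
      assert_that(first_needed >= years[1] && ty <= years[length(years)],
                  "trop_argument_error",
                  "county %s: history %d cannot be supplied for target year %d",
                  s$fips, history, ty)
      w <- w + 1L
      for (j in seq_len(history)) {
        y1 <- first_needed + j - 1L   # step covers (y1, y1 + 1)
        i1 <- match(y1, years); i2 <- i1 + 1L
        step <- numeric(d)
        step[1] <- s$values[i2, 1] - s$values[i1, 1]
        if (d > 1) {
          step[-1] <- if (s$diff_covariates)
            s$values[i2, -1] - s$values[i1, -1]
          else s$values[i2, -1]
        }
        inputs[w, j, ] <- step
      }
      ia <- match(ty - 1L, years)
      targets[w] <- s$values[ia + 1L, 1] - s$values[ia, 1]
      anchors$fips[w] <- s$fips
      anchors$anchor_year[w] <- ty - 1L
      anchors$anchor_level[w] <- s$values[ia, 1]
      anchors$target_year[w] <- ty
      anchors$truth_level[w] <- s$values[ia + 1L, 1]
    }
  }
  new_window_set(inputs, targets, anchors)
}

new_window_set <- function(inputs, targets, anchors) {
  stopifnot(dim(inputs)[1] == length(targets),
            nrow(anchors) == length(targets))
  structure(list(inputs = inputs, targets = targets, anchors = anchors),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows, history %d, feature dim %d, target years %s\n",
              dim(x$inputs)[1], dim(x$inputs)[2], dim(x$inputs)[3],
              paste(sort(unique(x$anchors$target_year)), collapse = ", ")))
  invisible(x)
}

#' @export
length.window_set <- function(x) dim(x$inputs)[1]

subset_windows <- function(ws, idx) {
  new_window_set(ws$inputs[idx, , , drop = FALSE], ws$targets[idx],
                 ws$anchors[idx, , drop = FALSE])
}

#' Flatten a window set to an audit table
#'
#' One row per window: anchor metadata, target, and the flattened input
#' steps (\code{h<j>_f<k>} columns).
#'
#' @param x A \code{window_set}.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.window_set <- function(x, ...) {
  n <- length(x)
  h <- dim(x$inputs)[2]; d <- dim(x$inputs)[3]
  flat <- matrix(aperm(x$inputs, c(1, 3, 2)), nrow = n)
  colnames(flat) <- paste0("h", rep(seq_len(h), each = d), "_f",
                           rep(seq_len(d), h))
  cbind(x$anchors, target_change = x$targets, as.data.frame(flat))
}
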