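#' Training configuration for the gradient-trained forecasters
#'
#' Optimization is minibatch AdamW (adaptive moments with decoupled
#' weight decay) on the mean squared error of the predicted change, with
#' early stopping on a held-out development split of training counties.
#'
#' @param learning_rate AdamW step size (default 1e-3).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param max_epochs Maximum epochs (default 500).
#' @param patience Early-stopping patience in epochs on dev MSE
#'   (default 25).
#' @param batch_size Minibatch size (default 64).
#' @param dev_fraction Fraction of training counties held out for the
#'   development split, in (0, 0.5] (default 0.2).
#' @param seed Seed for the dev split, parameter init and minibatch
#'   shuffling.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         max_epochs = 500, patience = 25, batch_size = 64,
                         dev_fraction = 0.2, seed = 1) {
  assert_that(learning_rate > 0, "trop_argument_error",
              "learning_rate must be > 0")
  assert_that(dev_fraction > 0 && dev_fraction <= 0.5,
              "trop_argument_error", "dev_fraction must be in (0, 0.5]")
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 dev_fraction = dev_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Hyperparameter search space
#'
#' Seeded random-sampling search over the documented ranges: learning
#' rate log-uniform on [5e-5, 5e-3], weight decay uniform on [0, 1],
#' dropout on the grid 0.10, 0.15, ..., 0.50, and hidden size on
#' 1, 3, ..., 15 (univariate) or 32, 48, ..., 256 (multivariate).
#'
#' @param n_trials Number of sampled configurations (default 25).
#' @param univariate Use the univariate hidden-size grid (default FALSE).
#' @param seed Sampling seed.
#' @export
search_space <- function(n_trials = 25, univariate = FALSE, seed = 1) {
  structure(list(lr_range = c(5e-5, 5e-3), wd_range = c(0, 1.0),
                 dropout_grid = seq(0.10, 0.50, by = 0.05),
                 hidden_grid = if (univariate) seq(1L, 16L, by = 2L)
                               else seq(32L, 256L, by = 16L),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "search_space")
}

sample_trial <- function(space) {
  list(learning_rate = exp(stats::runif(1, log(space$lr_range[1]),
                                        log(space$lr_range[2]))),
       weight_decay = stats::runif(1, space$wd_range[1], space$wd_range[2]),
       dropout = sample(space$dropout_grid, 1),
       hidden = sample(space$hidden_grid, 1))
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}

new_adamw_state <- function(params) {
  list(m = params_zero_like(params), v = params_zero_like(params), t = 0L)
}

model_loss_grad <- function(kind, params, X, y, config, training) {
  switch(kind,
         transformer = trop_loss_grad(params, X, y, config, training),
         rnn = rnn_loss_grad(params, X, y, config, training),
         stop_trop("trop_argument_error", "unknown model kind %s", kind))
}

model_init <- function(kind, config) {
  switch(kind, transformer = trop_init(config), rnn = rnn_init(config))
}

#' Train a forecaster on a training window set
#'
#' Splits training counties into fit/dev by a seeded partition, runs
#' minibatch AdamW on the MSE of the predicted change with early
#' stopping on dev MSE, and returns the best-dev parameters. With a
#' \code{search_space}, \code{n_trials} sampled configurations are
#' trained and the dev-best trial is returned. Fully deterministic given
#' the seeds in \code{config}.
#'
#' @param model_kind \code{"transformer"}, \code{"rnn"} or
#'   \code{"ridge"}.
#' @param windows_train A \code{window_set} of training windows.
#' @param config A \code{train_config} (for ridge, a
#'   \code{ridge_config}).
#' @param model_config A \code{trop_config} / \code{rnn_config} for the
#'   neural kinds; ignored for ridge and baselines.
#' @param search Optional \code{search_space}.
#' @return A \code{trop_model}: list with \code{kind}, \code{config},
#'   \code{params} (or \code{fit} for ridge) and a training \code{log}.
#' @export
train <- function(model_kind = c("transformer", "rnn", "ridge"),
                  windows_train, config = train_config(),
                  model_config = NULL, search = NULL) {
  model_kind <- match.arg(model_kind)
  assert_that(length(windows_train) > 0, "trop_argument_error",
              "no training windows")
  if (model_kind == "ridge") {
    rc <- if (inherits(config, "ridge_config")) config else ridge_config()
    fit <- ridge_fit(windows_train, rc)
    return(structure(list(kind = "ridge", fit = fit, config = rc,
                          log = list(n_iter = fit$n_iter)),
                     class = "trop_model"))
  }
  assert_that(!is.null(model_config), "trop_argument_error",
              "model_config is required for %s", model_kind)
  if (is.null(search)) {
    res <- train_one(model_kind, windows_train, config, model_config)
    return(structure(res, class = "trop_model"))
  }
  trials <- with_substream(search$seed, "hyper_search",
    lapply(seq_len(search$n_trials), function(i) sample_trial(search)))
  best <- NULL
  tlog <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    cfg_i <- config
    cfg_i$learning_rate <- tr$learning_rate
    cfg_i$weight_decay <- tr$weight_decay
    mc_i <- model_config
    mc_i$dropout <- tr$dropout
    if (model_kind == "transformer") mc_i$ff_hidden <- tr$hidden
    else mc_i$hidden_size <- tr$hidden
    res <- train_one(model_kind, windows_train, cfg_i, mc_i)
    tlog[[i]] <- c(tr, dev_mse = res$log$best_dev_mse)
    if (is.null(best) || res$log$best_dev_mse < best$log$best_dev_mse)
      best <- res
  }
  best$log$trials <- tlog
  structure(best, class = "trop_model")
}

train_one <- function(kind, windows, config, model_config) {
  counties <- unique(windows$anchors$fips)
  n_dev <- max(1L, floor(length(counties) * config$dev_fraction))
  dev_counties <- with_substream(config$seed, "dev_split",
                                 sample(counties, n_dev))
  is_dev <- windows$anchors$fips %in% dev_counties
  fit_idx <- which(!is_dev); dev_idx <- which(is_dev)
  if (length(fit_idx) == 0) { fit_idx <- dev_idx }
  Xfit <- windows$inputs[fit_idx, , , drop = FALSE]
  yfit <- windows$targets[fit_idx]
  Xdev <- windows$inputs[dev_idx, , , drop = FALSE]
  ydev <- windows$targets[dev_idx]

  params <- model_init(kind, model_config)
  state <- new_adamw_state(params)
  best_params <- params
  best_dev <- Inf
  bad <- 0L
  epoch_log <- numeric(0)
  nfit <- length(yfit)
  with_substream(config$seed, "train_loop", {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nfit)
      starts <- seq(1, nfit, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, nfit)]
        lg <- model_loss_grad(kind, params,
                              Xfit[idx, , , drop = FALSE], yfit[idx],
                              model_config, training = TRUE)
        if (!is.finite(lg$loss))
          stop_trop("trop_divergence_error",
                    "training diverged at epoch %d (last finite dev MSE %.4g)",
                    epoch, best_dev)
        upd <- adamw_step(params, lg$grads, state, config$learning_rate,
                          config$weight_decay)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      epoch_log[epoch] <- ep_loss / nfit
      dev_pred <- model_loss_grad(kind, params, Xdev, ydev, model_config,
                                  training = FALSE)
      dev_mse <- mean((dev_pred$pred - ydev)^2)
      if (dev_mse < best_dev - 1e-12) {
        best_dev <- dev_mse
        best_params <- params
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  })
  list(kind = kind, config = model_config, train_config = config,
       params = best_params,
       log = list(epoch_mse = epoch_log, best_dev_mse = best_dev,
                  dev_counties = dev_counties))
}

#' @export
print.trop_model <- function(x, ...) {
  cat(sprintf("<trop_model> kind = %s", x$kind))
  if (!is.null(x$log$best_dev_mse))
    cat(sprintf(", best dev MSE %.4g over %d epochs",
                x$log$best_dev_mse, length(x$log$epoch_mse)))
  cat("\n")
  invisible(x)
}

predict_changes <- function(model, windows) {
  switch(model$kind,
    transformer = trop_forward_batch(windows$inputs, model$config,
                                     model$params, FALSE)$pred,
    rnn = rnn_forward_batch(windows$inputs, model$config, model$params,
                            FALSE)$pred,
    ridge = ridge_predict(model$fit, windows),
    baseline_last = rep(0, length(windows)),
    baseline_mean = stop_trop("trop_argument_error",
      "baseline_mean predicts levels, not changes; use forecast()"),
    stop_trop("trop_argument_error", "unknown model kind %s", model$kind))
}

#' Wrap a heuristic baseline as a model object
#'
#' \code{"last"} forecasts zero change (the anchor level persists);
#' \code{"mean"} forecasts the mean of the last \code{k} observed levels
#' as the next level. For \code{"mean"}, the per-county level history up
#' to each window's anchor year must be supplied at forecast time via
#' the panel.
#'
#' @param kind \code{"last"} or \code{"mean"}.
#' @param k Trailing observations for \code{"mean"} (default 4).
#' @param panel The \code{county_panel} providing level histories.
#' @export
baseline_model <- function(kind = c("last", "mean"), k = 4, panel = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = paste0("baseline_", kind), k = k, panel = panel),
            class = "trop_model")
}

#' Forecast reconstructed levels for a window set
#'
#' Predicts each window's next-year change and reconstructs the level
#' forecast from the window's anchor: \eqn{\hat Y_{t+1} = Y_t + \hat
#' P_t}.
#'
#' @param model A \code{trop_model}.
#' @param windows A \code{window_set}.
#' @return Data frame: \code{fips}, \code{year}, \code{anchor_level},
#'   \code{predicted_change}, \code{predicted_level}, \code{truth_level}.
#' @export
forecast <- function(model, windows) {
  anch <- windows$anchors
  if (model$kind == "baseline_mean") {
    assert_that(!is.null(model$panel), "trop_argument_error",
                "baseline mean(k) needs a panel with level histories")
    lev <- vapply(seq_len(nrow(anch)), function(i) {
      ci <- match(anch$fips[i], model$panel$counties)
      yi <- match(anch$anchor_year[i], model$panel$years)
      assert_that(!is.na(ci) && !is.na(yi), "trop_argument_error",
                  "window %s/%d not found in baseline panel",
                  anch$fips[i], anch$anchor_year[i])
      baseline_predict(model$panel$rates[ci, seq_len(yi)], "mean",
                       k = model$k)
    }, numeric(1))
    chg <- lev - anch$anchor_level
  } else {
    chg <- predict_changes(model, windows)
    lev <- reconstruct(anch$anchor_level, chg)
  }
  data.frame(fips = anch$fips, year = anch$target_year,
             anchor_level = anch$anchor_level, predicted_change = chg,
             predicted_level = lev, truth_level = anch$truth_level,
             stringsAsFactors = FALSE)
}

#' MAPE and MAE of level forecasts
#'
#' \code{mae = mean(|truth - predicted|)} in deaths per 100,000;
#' \code{mape = 100 * mean(|truth - predicted| / truth)} in percent.
#' Windows with zero truth level are excluded from MAPE (with a count)
#' but kept in MAE.
#'
#' @param truth Observed levels.
#' @param predicted Forecast levels.
#' @return List with \code{mape}, \code{mae}, \code{n},
#'   \code{n_zero_truth}.
#' @export
score <- function(truth, predicted) {
  assert_that(length(truth) == length(predicted), "trop_argument_error",
              "truth and predicted lengths differ")
  abs_err <- abs(truth - predicted)
  nz <- truth != 0
  if (any(!nz))
    warning(sprintf("score: %d zero-truth windows excluded from MAPE",
                    sum(!nz)))
  list(mape = 100 * mean(abs_err[nz] / truth[nz]), mae = mean(abs_err),
       n = length(truth), n_zero_truth = sum(!nz))
}

#' Paired t-test on per-window absolute errors of two models
#'
#' Classical paired t statistic on the per-window error differences,
#' two-sided. With zero variance in the differences (e.g. identical
#' error vectors) the test is degenerate and no p-value is emitted.
#'
#' @param errors_a,errors_b Equal-length vectors of absolute errors,
#'   paired by window.
#' @return List with \code{t}, \code{df}, \code{p} (both NA with
#'   \code{degenerate = TRUE} in the degenerate case).
#' @export
paired_t_test <- function(errors_a, errors_b) {
  assert_that(length(errors_a) == length(errors_b) &&
                length(errors_a) >= 2, "trop_argument_error",
              "need two equal-length error vectors of length >= 2")
  d <- errors_a - errors_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  ht <- stats::t.test(errors_a, errors_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Evaluate forecasts into a per-window report
#'
#' @param forecasts Data frame from [forecast()] (optionally several,
#'   named, for pairwise comparisons).
#' @return An \code{evaluation_report}: per-window table, overall
#'   \code{mape}/\code{mae}, per-year breakdown with normal-approximation
#'   95\% confidence intervals, and paired-t comparisons between the
#'   supplied models.
#' @export
evaluate_forecasts <- function(forecasts) {
  if (is.data.frame(forecasts)) forecasts <- list(model = forecasts)
  assert_that(length(forecasts) >= 1, "trop_argument_error",
              "no forecasts supplied")
  per_model <- lapply(forecasts, function(fc) {
    fc$abs_error <- abs(fc$truth_level - fc$predicted_level)
    fc$abs_pct_error <- ifelse(fc$truth_level != 0,
                               100 * fc$abs_error / fc$truth_level, NA)
    fc
  })
  aggregates <- lapply(per_model, function(fc) {
    sc <- score(fc$truth_level, fc$predicted_level)
    by_year <- do.call(rbind, lapply(split(fc, fc$year), function(g) {
      scy <- score(g$truth_level, g$predicted_level)
      se <- stats::sd(g$abs_error) / sqrt(nrow(g))
      tq <- stats::qt(0.975, df = max(nrow(g) - 1, 1))
      data.frame(year = g$year[1], n = nrow(g), mae = scy$mae,
                 mape = scy$mape, mae_ci_lo = scy$mae - tq * se,
                 mae_ci_hi = scy$mae + tq * se)
    }))
    rownames(by_year) <- NULL
    list(mape = sc$mape, mae = sc$mae, n = sc$n,
         n_zero_truth = sc$n_zero_truth, by_year = by_year)
  })
  comparisons <- list()
  nms <- names(per_model)
  if (length(per_model) >= 2) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i >= j) next
      key <- paste(nms[i], "vs", nms[j])
      comparisons[[key]] <- paired_t_test(per_model[[i]]$abs_error,
                                          per_model[[j]]$abs_error)
    }
  }
  structure(list(per_window = per_model, aggregates = aggregates,
                 comparisons = comparisons),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x$aggregates)) {
    a <- x$aggregates[[nm]]
    cat(sprintf("  %-14s MAPE %6.2f%%  MAE %6.3f  (n = %d)\n",
                nm, a$mape, a$mae, a$n))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (isTRUE(cmp$degenerate)) next
    cat(sprintf("  %s: t = %.3f, p = %.3g\n", nm, cmp$t, cmp$p))
  }
  invisible(x)
}

#' Per-year error breakdown and error-vs-volume export
#'
#' @param report An \code{evaluation_report}.
#' @param tweet_volumes Optional data frame \code{fips}, \code{volume};
#'   when given, per-window (volume, error) pairs are returned for
#'   external smoothing.
#' @return List with \code{by_year} (per model) and optional
#'   \code{volume_error} pairs.
#' @export
error_breakdowns <- function(report, tweet_volumes = NULL) {
  out <- list(by_year = lapply(report$aggregates, `[[`, "by_year"))
  if (!is.null(tweet_volumes)) {
    out$volume_error <- lapply(report$per_window, function(fc) {
      vi <- match(fc$fips, pad_fips(tweet_volumes$fips))
      data.frame(fips = fc$fips, volume = tweet_volumes$volume[vi],
                 abs_error = fc$abs_error)
    })
  }
  out
}

#' Re-run training across history lengths
#'
#' Driver for the history-length sweep: trains and evaluates the given
#' model kind at each history in \code{histories} and reports test MAE /
#' MAPE per history.
#'
#' @param sequences Output of [build_sequences()].
#' @param histories Integer vector of history lengths.
#' @param train_years,test_years Target years for the train and test
#'   window sets.
#' @param model_kind,config,model_config_fn As in [train()];
#'   \code{model_config_fn(input_dim)} builds the model config.
#' @return Data frame with history, mae, mape.
#' @export
history_sweep <- function(sequences, histories, train_years, test_years,
                          model_kind, config, model_config_fn) {
  do.call(rbind, lapply(histories, function(h) {
    wtr <- make_windows(sequences, h, train_years)
    wte <- make_windows(sequences, h, test_years)
    m <- train(model_kind, wtr, config,
               model_config = model_config_fn(dim(wtr$inputs)[3]))
    fc <- forecast(m, wte)
    sc <- score(fc$truth_level, fc$predicted_level)
    data.frame(history = h, mae = sc$mae, mape = sc$mape)
  }))
}
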