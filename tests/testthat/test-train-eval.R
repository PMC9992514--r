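make_random_windows <- function(n = 10, h = 2, d = 3, seed = 5,
                                target_fn = NULL) {
  set.seed(seed)
  X <- array(rnorm(n * h * d), c(n, h, d))
  y <- if (is.null(target_fn)) rnorm(n) else target_fn(X)
  anchors <- data.frame(fips = formatC(seq_len(n), width = 5, flag = "0"),
                        anchor_year = 2014L, anchor_level = 10,
                        target_year = 2015L, truth_level = 10 + y)
  trop:::new_window_set(X, y, anchors)
}

test_that("the transformer can overfit a tiny training set", {
  ws <- make_random_windows(n = 16, h = 2, d = 2, seed = 6,
                            target_fn = function(X)
                              0.6 * X[, 1, 1] - X[, 2, 2] +
                                0.4 * X[, 2, 1] * X[, 1, 2])
  cfg <- trop_config(2, n_heads = 2, model_width = 8, ff_hidden = 16,
                     dropout = 0, seed = 1)
  tc <- train_config(learning_rate = 1e-2, weight_decay = 0,
                     max_epochs = 1500, patience = 1500,
                     dev_fraction = 0.2, seed = 1)
  m <- train("transformer", ws, tc, model_config = cfg)
  # training loss decreases and the final train MSE is far below the
  # target variance (capacity / optimization sanity)
  log <- m$log$epoch_mse
  expect_lt(log[length(log)], log[1])
  idx <- !(ws$anchors$fips %in% m$log$dev_counties)
  expect_lt(log[length(log)], 0.1 * var(ws$targets[idx]))
})

test_that("training is deterministic given its seed", {
  ws <- make_random_windows(n = 12, h = 2, d = 2, seed = 7)
  cfg <- rnn_config(2, hidden_size = 4, dropout = 0.1, seed = 2)
  tc <- train_config(max_epochs = 30, patience = 30, seed = 2)
  m1 <- train("rnn", ws, tc, model_config = cfg)
  m2 <- train("rnn", ws, tc, model_config = cfg)
  expect_identical(m1$params, m2$params)
})

test_that("hyperparameter search samples the documented grids", {
  sp <- search_space(n_trials = 40, univariate = FALSE, seed = 3)
  trials <- trop:::with_substream(sp$seed, "hyper_search",
    lapply(seq_len(sp$n_trials), function(i) trop:::sample_trial(sp)))
  drops <- vapply(trials, `[[`, numeric(1), "dropout")
  hiddens <- vapply(trials, `[[`, numeric(1), "hidden")
  lrs <- vapply(trials, `[[`, numeric(1), "learning_rate")
  wds <- vapply(trials, `[[`, numeric(1), "weight_decay")
  expect_true(all(drops %in% seq(0.10, 0.50, by = 0.05)))
  expect_true(all(hiddens %in% seq(32, 256, by = 16)))
  expect_true(all(lrs >= 5e-5 & lrs <= 5e-3))
  expect_true(all(wds >= 0 & wds <= 1))
  spu <- search_space(univariate = TRUE)
  expect_equal(spu$hidden_grid, seq(1L, 16L, by = 2L))
})

test_that("search returns the dev-best sampled configuration", {
  ws <- make_random_windows(n = 20, h = 2, d = 2, seed = 9)
  sp <- search_space(n_trials = 2, seed = 4)
  sp$hidden_grid <- c(8L, 16L)   # small for speed
  tc <- train_config(max_epochs = 15, patience = 15, seed = 4)
  m <- train("rnn", ws, tc, model_config = rnn_config(2, seed = 4),
             search = sp)
  expect_length(m$log$trials, 2)
  devs <- vapply(m$log$trials, function(t) t[["dev_mse"]], numeric(1))
  expect_equal(m$log$best_dev_mse, min(devs))
})

test_that("forecasts reconstruct levels from anchors", {
  ws <- make_random_windows(n = 6, h = 2, d = 1, seed = 10)
  # a perfect model: inject oracle changes through the ridge surface
  fc_last <- forecast(baseline_model("last"), ws)
  expect_equal(fc_last$predicted_level, ws$anchors$anchor_level)
  expect_equal(fc_last$predicted_change, rep(0, 6))

  # arithmetic of reconstruction
  expect_equal(reconstruct(10, 1.5), 11.5)

  # oracle changes give exact truth
  oracle_fc <- data.frame(fips = ws$anchors$fips,
                          year = ws$anchors$target_year,
                          anchor_level = ws$anchors$anchor_level,
                          predicted_change = ws$targets,
                          predicted_level = reconstruct(
                            ws$anchors$anchor_level, ws$targets),
                          truth_level = ws$anchors$truth_level)
  expect_equal(oracle_fc$predicted_level, ws$anchors$truth_level)
})

test_that("MAPE and MAE follow their definitions", {
  s <- score(c(10, 20), c(12, 19))
  expect_equal(s$mae, 1.5)
  expect_equal(s$mape, 12.5)
  s0 <- score(c(5, 5), c(5, 5))
  expect_equal(s0$mae, 0); expect_equal(s0$mape, 0)
  s10 <- score(c(3, 7, 11), 1.1 * c(3, 7, 11))
  expect_equal(s10$mape, 10, tolerance = 1e-12)
  # mae is symmetric, mape is not
  a <- c(10, 20); b <- c(11, 18)
  expect_equal(score(a, b)$mae, score(b, a)$mae)
  expect_false(isTRUE(all.equal(score(a, b)$mape, score(b, a)$mape)))
  # zero-truth windows excluded from MAPE with a warning, kept in MAE
  expect_warning(sz <- score(c(0, 10), c(1, 12)), "zero-truth")
  expect_equal(sz$mae, 1.5)
  expect_equal(sz$mape, 20)
  expect_equal(sz$n_zero_truth, 1)
})

test_that("paired t-test matches hand arithmetic and flags degeneracy", {
  # differences (1, 2, 3): mean 2, sd 1, t = 2 / (1 / sqrt(3))
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p))
})

test_that("paired t-test p-values are calibrated under the null", {
  set.seed(99)
  n_rep <- 1000
  ps <- replicate(n_rep, {
    a <- abs(rnorm(30)); b <- abs(rnorm(30))
    paired_t_test(a, b)$p
  })
  # approximately uniform: rejection rate at 0.05 within Monte-Carlo
  # error, and no gross mass distortion across quartiles
  rej <- mean(ps < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.005)
  expect_lt(max(abs(quantile(ps, c(0.25, 0.5, 0.75)) -
                      c(0.25, 0.5, 0.75))), 0.06)
})

test_that("per-year breakdowns aggregate consistently", {
  fc <- data.frame(fips = rep(c("00001", "00002"), 2),
                   year = rep(c(2016L, 2017L), each = 2),
                   anchor_level = 10,
                   predicted_change = 0,
                   predicted_level = c(10, 11, 12, 13),
                   truth_level = c(11, 11, 13, 15))
  rep1 <- evaluate_forecasts(fc)
  bd <- error_breakdowns(rep1)$by_year$model
  expect_equal(nrow(bd), 2)
  # equal window counts: overall MAE is the mean of the yearly MAEs
  expect_equal(rep1$aggregates$model$mae, mean(bd$mae))
  # single-year report equals the overall
  rep2 <- evaluate_forecasts(fc[fc$year == 2016, ])
  bd2 <- error_breakdowns(rep2)$by_year$model
  expect_equal(bd2$mae, rep2$aggregates$model$mae)
  # volume pairs join on fips
  vol <- data.frame(fips = c("00001", "00002"), volume = c(100, 5000))
  ve <- error_breakdowns(rep1, vol)$volume_error$model
  expect_equal(ve$volume, rep(c(100, 5000), 2))
})

test_that("planted heteroskedasticity shows up in the year breakdown", {
  set.seed(123)
  worse_year2 <- replicate(20, {
    n <- 60
    fc <- data.frame(fips = rep(formatC(1:n, width = 5, flag = "0"), 2),
                     year = rep(c(2016L, 2017L), each = n),
                     anchor_level = 10, predicted_change = 0,
                     predicted_level = 10,
                     truth_level = 10 + c(rnorm(n, 0, 1), rnorm(n, 0, 2)))
    bd <- error_breakdowns(evaluate_forecasts(fc))$by_year$model
    bd$mae[bd$year == 2017] > bd$mae[bd$year == 2016]
  })
  expect_gt(mean(worse_year2), 0.9)
})
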