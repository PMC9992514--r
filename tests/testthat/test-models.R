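test_that("transformer inference is deterministic and shape-checked", {
  cfg <- trop_config(21, seed = 7)
  params <- trop:::trop_init(cfg)
  set.seed(1)
  win <- matrix(rnorm(3 * 21), 3, 21)
  p1 <- trop_forward(win, cfg, params)
  p2 <- trop_forward(win, cfg, params)
  expect_identical(p1, p2)
  expect_length(p1, 1)
  expect_error(trop_forward(win[, 1:5], cfg, params),
               class = "trop_argument_error")
})

test_that("a zeroed transformer reduces to its head bias", {
  cfg <- trop_config(4, n_heads = 2, model_width = 6, ff_hidden = 5,
                     dropout = 0, seed = 1)
  params <- trop:::trop_init(cfg)
  params <- lapply(params, function(x) x * 0)
  params$b_head <- 1.75
  # layer norm gains restored so the zero path stays well-defined
  params$L1.ln1_g <- rep(1, 6); params$L1.ln2_g <- rep(1, 6)
  win <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(trop_forward(win, cfg, params), 1.75, tolerance = 1e-12)
})

test_that("recurrent forecaster pools with normalized attention", {
  cfg <- rnn_config(5, hidden_size = 4, seed = 3)
  params <- trop:::rnn_init(cfg)
  set.seed(2)
  win <- matrix(rnorm(4 * 5), 4, 5)
  out <- rnn_forward(win, cfg, params)
  expect_length(out$pred, 1)
  expect_equal(sum(out$attention), 1, tolerance = 1e-10)

  # length-1 sequence: the single step carries all the weight
  out1 <- rnn_forward(win[1, , drop = FALSE], cfg, params)
  expect_equal(sum(out1$attention), 1, tolerance = 1e-12)

  # bidirectional pooled width is 2H: the head weight vector has 8 rows
  expect_equal(nrow(params$W_head), 8)

  # deterministic at inference
  expect_identical(rnn_forward(win, cfg, params)$pred, out$pred)
})

test_that("batch predictions are invariant to window order", {
  cfg <- trop_config(3, n_heads = 2, model_width = 4, ff_hidden = 6,
                     seed = 5)
  params <- trop:::trop_init(cfg)
  set.seed(8)
  X <- array(rnorm(6 * 3 * 3), c(6, 3, 3))
  p <- trop:::trop_forward_batch(X, cfg, params)$pred
  perm <- c(4, 1, 6, 2, 5, 3)
  pp <- trop:::trop_forward_batch(X[perm, , , drop = FALSE], cfg,
                                  params)$pred
  expect_equal(pp, p[perm], tolerance = 1e-12)

  rcfg <- rnn_config(3, hidden_size = 3, seed = 5)
  rpar <- trop:::rnn_init(rcfg)
  rp <- trop:::rnn_forward_batch(X, rcfg, rpar)$pred
  rpp <- trop:::rnn_forward_batch(X[perm, , , drop = FALSE], rcfg,
                                  rpar)$pred
  expect_equal(rpp, rp[perm], tolerance = 1e-12)
})

test_that("gradient-descent ridge agrees with the closed form", {
  set.seed(13)
  n <- 50; h <- 3; d <- 4
  X <- array(rnorm(n * h * d), c(n, h, d))
  y <- rnorm(n)
  anchors <- data.frame(fips = formatC(1:n, width = 5, flag = "0"),
                        anchor_year = 2014L, anchor_level = 10,
                        target_year = 2015L, truth_level = 10 + y)
  ws <- trop:::new_window_set(X, y, anchors)
  fit <- ridge_fit(ws, ridge_config(l2_penalty = 1.0))
  Xa <- cbind(1, trop:::flatten_windows(ws))
  pen <- diag(c(0, rep(1, h * d)))
  closed <- solve(t(Xa) %*% Xa + pen, t(Xa) %*% y)
  expect_lt(max(abs(fit$weights - drop(closed))), 1e-4)
})

test_that("ridge recovers a noiseless linear rule and shrinks to the mean", {
  set.seed(14)
  n <- 40; h <- 2; d <- 2
  X <- array(rnorm(n * h * d), c(n, h, d))
  w_true <- c(0.5, -1, 2, 0.25)
  y <- drop(trop:::flatten_windows(
    trop:::new_window_set(X, rep(0, n),
      data.frame(fips = as.character(1:n), anchor_year = 1L,
                 anchor_level = 0, target_year = 2L,
                 truth_level = 0))) %*% w_true) + 3
  anchors <- data.frame(fips = as.character(1:n), anchor_year = 1L,
                        anchor_level = 0, target_year = 2L,
                        truth_level = y)
  ws <- trop:::new_window_set(X, y, anchors)
  fit0 <- ridge_fit(ws, ridge_config(l2_penalty = 0))
  expect_lt(max(abs(fit0$weights - c(3, w_true))), 1e-3)

  fit_big <- ridge_fit(ws, ridge_config(l2_penalty = 1e8))
  expect_lt(max(abs(fit_big$weights[-1])), 1e-3)
  expect_equal(unname(fit_big$weights[1]), mean(y), tolerance = 1e-3)
})

test_that("heuristic baselines return last value and trailing means", {
  expect_equal(baseline_predict(c(3, 5, 7), "last"), 7)
  expect_equal(baseline_predict(c(2, 4, 6, 8), "mean", k = 4), 5)
  expect_equal(baseline_predict(rep(9, 5), "last") - 9, 0)
  expect_error(baseline_predict(c(1, 2), "mean", k = 4),
               class = "trop_argument_error")
})

test_that("models round-trip through the portable serialization", {
  cfg <- trop_config(3, n_heads = 2, model_width = 4, ff_hidden = 6,
                     seed = 9)
  model <- structure(list(kind = "transformer", config = cfg,
                          params = trop:::trop_init(cfg),
                          log = list()), class = "trop_model")
  set.seed(3)
  win <- matrix(rnorm(9), 3, 3)
  before <- trop_forward(win, cfg, model$params)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_model(model, path)
  back <- load_model(path)
  after <- trop_forward(win, back$config, back$params)
  expect_identical(before, after)
})
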