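#' Recurrent forecaster configuration
#'
#' A gated recurrent network over the differenced window: GRU (default)
#' or LSTM cells, run bidirectionally with the forward and backward
#' hidden states concatenated at each step, pooled across time by an
#' additive neural attention mechanism (weights normalized to sum to 1),
#' and decoded by an affine head into the predicted next-year change.
#'
#' @param input_dim Per-year feature dimension.
#' @param hidden_size Hidden width per direction.
#' @param cell \code{"gru"} (default) or \code{"lstm"}.
#' @param bidirectional Concatenate a reversed-direction pass (default
#'   TRUE).
#' @param attention_pooling Pool hidden states by learned attention
#'   (default TRUE); otherwise the last step's representation is used.
#' @param dropout Dropout on the pooled vector during training.
#' @param seed Parameter-initialization seed.
#' @export
rnn_config <- function(input_dim, hidden_size = 32, cell = c("gru", "lstm"),
                       bidirectional = TRUE, attention_pooling = TRUE,
                       dropout = 0.20, seed = 1) {
  cell <- match.arg(cell)
  assert_that(hidden_size >= 1, "trop_argument_error",
              "hidden_size must be >= 1")
  structure(list(input_dim = input_dim, hidden_size = hidden_size,
                 cell = cell, bidirectional = isTRUE(bidirectional),
                 attention_pooling = isTRUE(attention_pooling),
                 dropout = dropout, seed = as.integer(seed)),
            class = "rnn_config")
}

rnn_gate_names <- function(cell) {
  if (cell == "gru") c("z", "r", "n") else c("i", "f", "g", "o")
}

rnn_init <- function(config) {
  d <- config$input_dim; H <- config$hidden_size
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  P <- H * length(dirs)
  with_substream(config$seed, "rnn_init", {
    p <- list()
    for (dir in dirs) for (gt in rnn_gate_names(config$cell)) {
      p[[paste0(dir, ".W_", gt)]] <- init_mat(d, H)
      p[[paste0(dir, ".U_", gt)]] <- init_mat(H, H)
      p[[paste0(dir, ".b_", gt)]] <- init_vec(H)
    }
    if (config$attention_pooling) {
      p$W_a <- init_mat(P, H)
      p$b_a <- init_vec(H, P)
      p$v_a <- init_vec(H)
    }
    p$W_head <- init_mat(P, 1)
    p$b_head <- 0
    p
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_dir_fwd <- function(X, p, pre, order) {
  N <- nrow(X[[1]]); H <- ncol(p[[paste0(pre, ".U_z")]])
  h <- matrix(0, N, H)
  states <- vector("list", length(X))
  for (t in order) {
    z <- sigmoid(sweep(X[[t]] %*% p[[paste0(pre, ".W_z")]] +
                         h %*% p[[paste0(pre, ".U_z")]], 2,
                       p[[paste0(pre, ".b_z")]], "+"))
    r <- sigmoid(sweep(X[[t]] %*% p[[paste0(pre, ".W_r")]] +
                         h %*% p[[paste0(pre, ".U_r")]], 2,
                       p[[paste0(pre, ".b_r")]], "+"))
    n <- tanh(sweep(X[[t]] %*% p[[paste0(pre, ".W_n")]] +
                      (r * h) %*% p[[paste0(pre, ".U_n")]], 2,
                    p[[paste0(pre, ".b_n")]], "+"))
    hn <- (1 - z) * n + z * h
    states[[t]] <- list(z = z, r = r, n = n, h_prev = h, h = hn)
    h <- hn
  }
  states
}

gru_dir_bwd <- function(X, states, dH, p, pre, order) {
  N <- nrow(X[[1]])
  Hh <- ncol(states[[order[1]]]$h)
  g <- list()
  for (gt in c("z", "r", "n")) {
    g[[paste0(pre, ".W_", gt)]] <- p[[paste0(pre, ".W_", gt)]] * 0
    g[[paste0(pre, ".U_", gt)]] <- p[[paste0(pre, ".U_", gt)]] * 0
    g[[paste0(pre, ".b_", gt)]] <- p[[paste0(pre, ".b_", gt)]] * 0
  }
  dX <- lapply(X, function(M) M * 0)
  carry <- matrix(0, N, Hh)
  for (t in rev(order)) {
    st <- states[[t]]
    dh <- dH[[t]] + carry
    dz <- dh * (st$h_prev - st$n); dzp <- dz * st$z * (1 - st$z)
    dn <- dh * (1 - st$z); dnp <- dn * (1 - st$n^2)
    dh_prev <- dh * st$z
    g[[paste0(pre, ".W_n")]] <- g[[paste0(pre, ".W_n")]] +
      crossprod(X[[t]], dnp)
    g[[paste0(pre, ".U_n")]] <- g[[paste0(pre, ".U_n")]] +
      crossprod(st$r * st$h_prev, dnp)
    g[[paste0(pre, ".b_n")]] <- g[[paste0(pre, ".b_n")]] + colSums(dnp)
    drh <- dnp %*% t(p[[paste0(pre, ".U_n")]])
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    drp <- dr * st$r * (1 - st$r)
    g[[paste0(pre, ".W_r")]] <- g[[paste0(pre, ".W_r")]] +
      crossprod(X[[t]], drp)
    g[[paste0(pre, ".U_r")]] <- g[[paste0(pre, ".U_r")]] +
      crossprod(st$h_prev, drp)
    g[[paste0(pre, ".b_r")]] <- g[[paste0(pre, ".b_r")]] + colSums(drp)
    dh_prev <- dh_prev + drp %*% t(p[[paste0(pre, ".U_r")]])
    g[[paste0(pre, ".W_z")]] <- g[[paste0(pre, ".W_z")]] +
      crossprod(X[[t]], dzp)
    g[[paste0(pre, ".U_z")]] <- g[[paste0(pre, ".U_z")]] +
      crossprod(st$h_prev, dzp)
    g[[paste0(pre, ".b_z")]] <- g[[paste0(pre, ".b_z")]] + colSums(dzp)
    dh_prev <- dh_prev + dzp %*% t(p[[paste0(pre, ".U_z")]])
    dX[[t]] <- dX[[t]] + dnp %*% t(p[[paste0(pre, ".W_n")]]) +
      drp %*% t(p[[paste0(pre, ".W_r")]]) +
      dzp %*% t(p[[paste0(pre, ".W_z")]])
    carry <- dh_prev
  }
  list(grads = g, dX = dX)
}

lstm_dir_fwd <- function(X, p, pre, order) {
  N <- nrow(X[[1]]); H <- ncol(p[[paste0(pre, ".U_i")]])
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  states <- vector("list", length(X))
  gate <- function(t, gt, act, h) {
    act(sweep(X[[t]] %*% p[[paste0(pre, ".W_", gt)]] +
                h %*% p[[paste0(pre, ".U_", gt)]], 2,
              p[[paste0(pre, ".b_", gt)]], "+"))
  }
  for (t in order) {
    i <- gate(t, "i", sigmoid, h)
    f <- gate(t, "f", sigmoid, h)
    o <- gate(t, "o", sigmoid, h)
    gg <- gate(t, "g", tanh, h)
    cn <- f * cc + i * gg
    tc <- tanh(cn)
    hn <- o * tc
    states[[t]] <- list(i = i, f = f, o = o, g = gg, c_prev = cc,
                        h_prev = h, c = cn, tc = tc, h = hn)
    h <- hn; cc <- cn
  }
  states
}

lstm_dir_bwd <- function(X, states, dH, p, pre, order) {
  N <- nrow(X[[1]]); Hh <- ncol(states[[order[1]]]$h)
  g <- list()
  for (gt in c("i", "f", "g", "o")) {
    g[[paste0(pre, ".W_", gt)]] <- p[[paste0(pre, ".W_", gt)]] * 0
    g[[paste0(pre, ".U_", gt)]] <- p[[paste0(pre, ".U_", gt)]] * 0
    g[[paste0(pre, ".b_", gt)]] <- p[[paste0(pre, ".b_", gt)]] * 0
  }
  dX <- lapply(X, function(M) M * 0)
  carry_h <- matrix(0, N, Hh); carry_c <- matrix(0, N, Hh)
  for (t in rev(order)) {
    st <- states[[t]]
    dh <- dH[[t]] + carry_h
    dc <- carry_c + dh * st$o * (1 - st$tc^2)
    dpre <- list(o = dh * st$tc * st$o * (1 - st$o),
                 i = dc * st$g * st$i * (1 - st$i),
                 f = dc * st$c_prev * st$f * (1 - st$f),
                 g = dc * st$i * (1 - st$g^2))
    carry_c <- dc * st$f
    dh_prev <- matrix(0, N, Hh)
    for (gt in names(dpre)) {
      g[[paste0(pre, ".W_", gt)]] <- g[[paste0(pre, ".W_", gt)]] +
        crossprod(X[[t]], dpre[[gt]])
      g[[paste0(pre, ".U_", gt)]] <- g[[paste0(pre, ".U_", gt)]] +
        crossprod(st$h_prev, dpre[[gt]])
      g[[paste0(pre, ".b_", gt)]] <- g[[paste0(pre, ".b_", gt)]] +
        colSums(dpre[[gt]])
      dh_prev <- dh_prev + dpre[[gt]] %*% t(p[[paste0(pre, ".U_", gt)]])
      dX[[t]] <- dX[[t]] + dpre[[gt]] %*% t(p[[paste0(pre, ".W_", gt)]])
    }
    carry_h <- dh_prev
  }
  list(grads = g, dX = dX)
}

rnn_forward_batch <- function(X, config, params, training = FALSE) {
  Xl <- windows_to_seqlist(X)
  Tn <- length(Xl); N <- nrow(Xl[[1]])
  dir_fwd <- if (config$cell == "gru") gru_dir_fwd else lstm_dir_fwd
  sf <- dir_fwd(Xl, params, "f", seq_len(Tn))
  sb <- if (config$bidirectional) dir_fwd(Xl, params, "b", rev(seq_len(Tn)))
  G <- lapply(seq_len(Tn), function(t) {
    if (config$bidirectional) cbind(sf[[t]]$h, sb[[t]]$h) else sf[[t]]$h
  })
  if (config$attention_pooling) {
    U <- lapply(G, function(Gt) tanh(sweep(Gt %*% params$W_a, 2,
                                           params$b_a, "+")))
    E <- vapply(U, function(Ut) drop(Ut %*% params$v_a), numeric(N))
    E <- matrix(E, N)
    alpha <- softmax_rows(E)
    pooled <- Reduce(`+`, lapply(seq_len(Tn), function(t)
      G[[t]] * alpha[, t]))
  } else {
    U <- NULL; alpha <- NULL
    pooled <- G[[Tn]]
  }
  dropc <- seq_dropout_fwd(list(pooled), config$dropout, training)
  pooled_d <- dropc$Y[[1]]
  pred <- drop(pooled_d %*% params$W_head) + params$b_head
  list(pred = pred, Xl = Xl, sf = sf, sb = sb, G = G, U = U,
       alpha = alpha, pooled = pooled, pooled_d = pooled_d,
       drop_mask = dropc$mask)
}

rnn_loss_grad <- function(params, X, y, config, training = FALSE) {
  fw <- rnn_forward_batch(X, config, params, training)
  N <- length(y); Tn <- length(fw$Xl); H <- config$hidden_size
  res <- fw$pred - y
  loss <- mean(res^2)
  g <- params_zero_like(params)
  dpred <- 2 * res / N
  g$W_head <- crossprod(fw$pooled_d, matrix(dpred, ncol = 1))
  g$b_head <- sum(dpred)
  dpooled_d <- matrix(dpred, ncol = 1) %*% t(params$W_head)
  dpooled <- seq_dropout_bwd(list(dpooled_d), fw$drop_mask)[[1]]
  dG <- lapply(fw$G, function(Gt) Gt * 0)
  if (config$attention_pooling) {
    alpha <- fw$alpha
    dalpha <- matrix(0, N, Tn)
    for (t in seq_len(Tn)) {
      dG[[t]] <- dG[[t]] + dpooled * alpha[, t]
      dalpha[, t] <- rowSums(dpooled * fw$G[[t]])
    }
    dE <- alpha * (dalpha - rowSums(dalpha * alpha))
    for (t in seq_len(Tn)) {
      Ut <- fw$U[[t]]
      g$v_a <- g$v_a + drop(crossprod(Ut, dE[, t]))
      dU <- outer(dE[, t], params$v_a)
      dUpre <- dU * (1 - Ut^2)
      g$W_a <- g$W_a + crossprod(fw$G[[t]], dUpre)
      g$b_a <- g$b_a + colSums(dUpre)
      dG[[t]] <- dG[[t]] + dUpre %*% t(params$W_a)
    }
  } else {
    dG[[Tn]] <- dG[[Tn]] + dpooled
  }
  dHf <- lapply(dG, function(M) M[, seq_len(H), drop = FALSE])
  dir_bwd <- if (config$cell == "gru") gru_dir_bwd else lstm_dir_bwd
  bf <- dir_bwd(fw$Xl, fw$sf, dHf, params, "f", seq_len(Tn))
  for (nm in names(bf$grads)) g[[nm]] <- bf$grads[[nm]]
  if (config$bidirectional) {
    dHb <- lapply(dG, function(M) M[, H + seq_len(H), drop = FALSE])
    bb <- dir_bwd(fw$Xl, fw$sb, dHb, params, "b", rev(seq_len(Tn)))
    for (nm in names(bb$grads)) g[[nm]] <- bb$grads[[nm]]
  }
  list(loss = loss, grads = g, pred = fw$pred)
}

#' Forward pass of the recurrent forecaster
#'
#' Maps one history window to the predicted next-year change. Also
#' returns the attention weights over the steps (rows sum to 1).
#'
#' @param window History x input_dim numeric matrix.
#' @param config An \code{rnn_config}.
#' @param params Parameter list.
#' @param training_mode Apply dropout (default FALSE).
#' @return List with \code{pred} (scalar) and \code{attention} (per-step
#'   pooling weights, or NULL when attention pooling is off).
#' @export
rnn_forward <- function(window, config, params, training_mode = FALSE) {
  window <- as.matrix(window)
  assert_that(ncol(window) == config$input_dim, "trop_argument_error",
              "window has %d features, config expects %d",
              ncol(window), config$input_dim)
  X <- array(window, c(1, nrow(window), ncol(window)))
  fw <- rnn_forward_batch(X, config, params, training_mode)
  list(pred = fw$pred,
       attention = if (!is.null(fw$alpha)) drop(fw$alpha) else NULL)
}
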