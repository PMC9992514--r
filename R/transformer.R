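#' Transformer forecaster configuration
#'
#' A deliberately small one-layer encoder sized for short yearly panels:
#' a learned affine input projection lifts the per-year feature vector to
#' an even model width divisible by the head count (21 features with 3
#' heads project to width 24), fixed sinusoidal positions are added, one
#' multi-head self-attention block and one feed-forward block (each with
#' residual connection and post-residual layer normalization) encode the
#' window, and an affine head on the last year's representation emits the
#' predicted next-year change.
#'
#' @param input_dim Per-year feature dimension (1 univariate, 1 + D
#'   multivariate, 1 + D + 7 with SES).
#' @param n_heads Self-attention heads (default 3).
#' @param n_layers Encoder layers (default 1).
#' @param ff_hidden Feed-forward hidden size (default 128).
#' @param dropout Dropout probability applied to the attention and
#'   feed-forward outputs during training (default 0.20).
#' @param model_width Optional explicit model width; defaults to the
#'   smallest even multiple of \code{n_heads} strictly above
#'   \code{input_dim}.
#' @param seed Parameter-initialization seed.
#' @return A \code{trop_config} list.
#' @export
trop_config <- function(input_dim, n_heads = 3, n_layers = 1,
                        ff_hidden = 128, dropout = 0.20,
                        model_width = NULL, seed = 1) {
  assert_that(dropout >= 0 && dropout < 1, "trop_argument_error",
              "dropout must be in [0, 1)")
  if (is.null(model_width)) {
    model_width <- n_heads * ceiling((input_dim + 1) / n_heads)
    while (model_width %% 2 != 0) model_width <- model_width + n_heads
  }
  assert_that(model_width %% n_heads == 0 && model_width %% 2 == 0,
              "trop_configuration_error",
              "model width %d must be even and divisible by %d heads",
              model_width, n_heads)
  structure(list(input_dim = input_dim, n_heads = n_heads,
                 n_layers = n_layers, ff_hidden = ff_hidden,
                 dropout = dropout, model_width = model_width,
                 seed = as.integer(seed)),
            class = "trop_config")
}

trop_init <- function(config) {
  w <- config$model_width; f <- config$ff_hidden; d <- config$input_dim
  with_substream(config$seed, "trop_init", {
    p <- list(W_in = init_mat(d, w), b_in = init_vec(w, d))
    for (l in seq_len(config$n_layers)) {
      p[[paste0("L", l, ".W_q")]] <- init_mat(w, w)
      p[[paste0("L", l, ".b_q")]] <- init_vec(w)
      p[[paste0("L", l, ".W_k")]] <- init_mat(w, w)
      p[[paste0("L", l, ".b_k")]] <- init_vec(w)
      p[[paste0("L", l, ".W_v")]] <- init_mat(w, w)
      p[[paste0("L", l, ".b_v")]] <- init_vec(w)
      p[[paste0("L", l, ".W_o")]] <- init_mat(w, w)
      p[[paste0("L", l, ".b_o")]] <- init_vec(w)
      p[[paste0("L", l, ".ln1_g")]] <- rep(1, w)
      p[[paste0("L", l, ".ln1_b")]] <- rep(0, w)
      p[[paste0("L", l, ".W_f1")]] <- init_mat(w, f)
      p[[paste0("L", l, ".b_f1")]] <- init_vec(f, w)
      p[[paste0("L", l, ".W_f2")]] <- init_mat(f, w)
      p[[paste0("L", l, ".b_f2")]] <- init_vec(w, f)
      p[[paste0("L", l, ".ln2_g")]] <- rep(1, w)
      p[[paste0("L", l, ".ln2_b")]] <- rep(0, w)
    }
    p$W_head <- init_mat(w, 1)
    p$b_head <- 0
    p
  })
}

# windows array (N x T x d) -> list of T matrices N x d
windows_to_seqlist <- function(X) {
  N <- dim(X)[1]; Tn <- dim(X)[2]; d <- dim(X)[3]
  lapply(seq_len(Tn), function(t) matrix(X[, t, ], N, d))
}

layer_params <- function(params, l) {
  pre <- paste0("L", l, ".")
  nm <- names(params)[startsWith(names(params), pre)]
  out <- params[nm]
  names(out) <- sub(pre, "", nm)
  out
}

trop_forward_batch <- function(X, config, params, training = FALSE) {
  Xl <- windows_to_seqlist(X)
  Tn <- length(Xl)
  H <- seq_linear_fwd(Xl, params$W_in, params$b_in)
  pe <- positional_encoding(Tn, config$model_width)
  Hp <- lapply(seq_len(Tn), function(t) sweep(H[[t]], 2, pe[t, ], "+"))
  caches <- vector("list", config$n_layers)
  Z <- Hp
  for (l in seq_len(config$n_layers)) {
    lp <- layer_params(params, l)
    mha <- seq_mha_fwd(Z, lp, config$n_heads)
    drop1 <- seq_dropout_fwd(mha$Y, config$dropout, training)
    A1 <- mapply(`+`, Z, drop1$Y, SIMPLIFY = FALSE)
    ln1 <- seq_layernorm_fwd(A1, lp$ln1_g, lp$ln1_b)
    FFh <- seq_linear_fwd(ln1$Y, lp$W_f1, lp$b_f1)
    FFr <- lapply(FFh, function(M) pmax(M, 0))
    FF2 <- seq_linear_fwd(FFr, lp$W_f2, lp$b_f2)
    drop2 <- seq_dropout_fwd(FF2, config$dropout, training)
    A2 <- mapply(`+`, ln1$Y, drop2$Y, SIMPLIFY = FALSE)
    ln2 <- seq_layernorm_fwd(A2, lp$ln2_g, lp$ln2_b)
    caches[[l]] <- list(Zin = Z, mha = mha, drop1 = drop1, ln1 = ln1,
                        FFh = FFh, FFr = FFr, drop2 = drop2, ln2 = ln2)
    Z <- ln2$Y
  }
  pred <- drop(Z[[Tn]] %*% params$W_head) + params$b_head
  list(pred = pred, Xl = Xl, caches = caches, Z = Z)
}

# MSE loss + full analytic gradient for one batch
trop_loss_grad <- function(params, X, y, config, training = FALSE) {
  fw <- trop_forward_batch(X, config, params, training)
  N <- length(y); Tn <- dim(X)[2]
  res <- fw$pred - y
  loss <- mean(res^2)
  g <- params_zero_like(params)
  dpred <- 2 * res / N
  Zlast <- fw$Z[[Tn]]
  g$W_head <- crossprod(Zlast, matrix(dpred, ncol = 1))
  g$b_head <- sum(dpred)
  dZ <- lapply(seq_len(Tn), function(t)
    matrix(0, nrow(Zlast), ncol(Zlast)))
  dZ[[Tn]] <- matrix(dpred, ncol = 1) %*% t(params$W_head)
  for (l in rev(seq_len(config$n_layers))) {
    cc <- fw$caches[[l]]
    lp <- layer_params(params, l)
    ln2b <- seq_layernorm_bwd(cc$ln2, dZ, lp$ln2_g)
    g[[paste0("L", l, ".ln2_g")]] <- ln2b$dgamma
    g[[paste0("L", l, ".ln2_b")]] <- ln2b$dbeta
    dA2 <- ln2b$dH
    dFF2 <- seq_dropout_bwd(dA2, cc$drop2$mask)
    f2b <- seq_linear_bwd(cc$FFr, dFF2, lp$W_f2)
    g[[paste0("L", l, ".W_f2")]] <- f2b$dW
    g[[paste0("L", l, ".b_f2")]] <- f2b$db
    dFFr <- mapply(function(dh, pre) dh * (pre > 0), f2b$dH, cc$FFh,
                   SIMPLIFY = FALSE)
    f1b <- seq_linear_bwd(cc$ln1$Y, dFFr, lp$W_f1)
    g[[paste0("L", l, ".W_f1")]] <- f1b$dW
    g[[paste0("L", l, ".b_f1")]] <- f1b$db
    dZ1 <- mapply(`+`, dA2, f1b$dH, SIMPLIFY = FALSE)
    ln1b <- seq_layernorm_bwd(cc$ln1, dZ1, lp$ln1_g)
    g[[paste0("L", l, ".ln1_g")]] <- ln1b$dgamma
    g[[paste0("L", l, ".ln1_b")]] <- ln1b$dbeta
    dA1 <- ln1b$dH
    dM <- seq_dropout_bwd(dA1, cc$drop1$mask)
    mhab <- seq_mha_bwd(cc$Zin, cc$mha, dM, lp)
    for (nm in names(mhab$grads))
      g[[paste0("L", l, ".", nm)]] <- mhab$grads[[nm]]
    dZ <- mapply(`+`, dA1, mhab$dH, SIMPLIFY = FALSE)
  }
  inb <- seq_linear_bwd(fw$Xl, dZ, params$W_in)
  g$W_in <- inb$dW
  g$b_in <- inb$db
  list(loss = loss, grads = g, pred = fw$pred)
}

#' Forward pass of the transformer forecaster
#'
#' Maps one history window (history x input_dim matrix of differenced
#' per-year vectors) to the predicted next-year outcome change. With
#' \code{training_mode = FALSE} the pass has no stochastic elements and
#' is bit-reproducible.
#'
#' @param window History x input_dim numeric matrix.
#' @param config A \code{trop_config}.
#' @param params Parameter list from training (or \code{trop_init}).
#' @param training_mode Apply dropout (default FALSE).
#' @return Scalar predicted change.
#' @export
trop_forward <- function(window, config, params, training_mode = FALSE) {
  window <- as.matrix(window)
  assert_that(ncol(window) == config$input_dim, "trop_argument_error",
              "window has %d features, config expects %d",
              ncol(window), config$input_dim)
  X <- array(window, c(1, nrow(window), ncol(window)))
  trop_forward_batch(X, config, params, training_mode)$pred
}
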