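# Shared neural-network primitives. Batches of windows are represented as
# a list of T matrices (one per sequence position), each N x width, which
# keeps every operation a plain BLAS call for short yearly sequences.

#' Fixed sinusoidal positional encoding
#'
#' Parameter-free table added to the inputs so the attention layer can
#' distinguish sequence positions: \code{entry(pos, 2i) = sin(pos /
#' 10000^(2i/width))}, \code{entry(pos, 2i+1) = cos(...)}, positions
#' starting at 0.
#'
#' @param seq_len Number of positions (rows).
#' @param width Even embedding width (columns).
#' @return A \code{seq_len} x \code{width} matrix with entries in [-1, 1].
#' @export
positional_encoding <- function(seq_len, width) {
  assert_that(width %% 2 == 0, "trop_argument_error",
              "positional encoding width must be even, got %d", width)
  pos <- seq_len(seq_len) - 1
  i <- seq_len(width / 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / width))
  pe <- matrix(0, seq_len, width)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / sqrt(d_k)) V} with the softmax taken over key
#' positions; each attention-weight row sums to 1.
#'
#' @param Q Queries (n_q x d_k).
#' @param K Keys (n_k x d_k).
#' @param V Values (n_k x d_v).
#' @return List with \code{output} (n_q x d_v) and \code{weights}
#'   (n_q x n_k).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  assert_that(ncol(Q) == ncol(K), "trop_argument_error",
              "query width %d != key width %d", ncol(Q), ncol(K))
  assert_that(nrow(K) == nrow(V), "trop_argument_error",
              "key rows %d != value rows %d", nrow(K), nrow(V))
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention over one sequence
#'
#' Projects the inputs to queries, keys and values, runs \code{h}
#' independent scaled dot-product attention heads on disjoint column
#' blocks, concatenates the head outputs and mixes them with the output
#' matrix \code{W_o}. Output width equals input width.
#'
#' @param inputs Sequence matrix (seq_len x width), width divisible by
#'   \code{h}.
#' @param params List with \code{W_q, W_k, W_v, W_o} (width x width) and
#'   optional biases \code{b_q, b_k, b_v, b_o}.
#' @param h Number of heads.
#' @return List with \code{output} (seq_len x width) and per-head
#'   \code{weights}.
#' @export
multi_head_attention <- function(inputs, params, h) {
  X <- as.matrix(inputs)
  w <- ncol(X)
  assert_that(w %% h == 0, "trop_configuration_error",
              "model width %d is not divisible by %d heads", w, h)
  dh <- w / h
  add_b <- function(M, b) if (is.null(b)) M else sweep(M, 2, b, "+")
  Q <- add_b(X %*% params$W_q, params$b_q)
  K <- add_b(X %*% params$W_k, params$b_k)
  V <- add_b(X %*% params$W_v, params$b_v)
  outs <- vector("list", h); wts <- vector("list", h)
  for (k in seq_len(h)) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    att <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE],
                                V[, cols, drop = FALSE])
    outs[[k]] <- att$output
    wts[[k]] <- att$weights
  }
  O <- do.call(cbind, outs)
  list(output = add_b(O %*% params$W_o, params$b_o), weights = wts)
}

# ---- internal batched layers (lists of T matrices, each N x width) ----

seq_linear_fwd <- function(H, W, b) {
  lapply(H, function(M) sweep(M %*% W, 2, b, "+"))
}

seq_linear_bwd <- function(H, dY, W) {
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dH <- vector("list", length(H))
  for (t in seq_along(H)) {
    dW <- dW + crossprod(H[[t]], dY[[t]])
    db <- db + colSums(dY[[t]])
    dH[[t]] <- dY[[t]] %*% t(W)
  }
  list(dH = dH, dW = dW, db = db)
}

seq_layernorm_fwd <- function(H, gamma, beta, eps = 1e-5) {
  xhat <- vector("list", length(H)); sdv <- vector("list", length(H))
  Y <- vector("list", length(H))
  for (t in seq_along(H)) {
    X <- H[[t]]
    mu <- rowMeans(X)
    Xc <- X - mu
    s <- sqrt(rowMeans(Xc^2) + eps)
    xh <- Xc / s
    xhat[[t]] <- xh; sdv[[t]] <- s
    Y[[t]] <- sweep(xh, 2, gamma, "*")
    Y[[t]] <- sweep(Y[[t]], 2, beta, "+")
  }
  list(Y = Y, xhat = xhat, sd = sdv)
}

seq_layernorm_bwd <- function(cache, dY, gamma) {
  Tn <- length(dY)
  dgamma <- numeric(length(gamma)); dbeta <- numeric(length(gamma))
  dH <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xh <- cache$xhat[[t]]; s <- cache$sd[[t]]
    dgamma <- dgamma + colSums(dY[[t]] * xh)
    dbeta <- dbeta + colSums(dY[[t]])
    dxh <- sweep(dY[[t]], 2, gamma, "*")
    dH[[t]] <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / s
  }
  list(dH = dH, dgamma = dgamma, dbeta = dbeta)
}

# batched multi-head self-attention over T positions
seq_mha_fwd <- function(H, params, h) {
  Tn <- length(H); N <- nrow(H[[1]]); w <- ncol(H[[1]])
  dh <- w / h
  Q <- seq_linear_fwd(H, params$W_q, params$b_q)
  K <- seq_linear_fwd(H, params$W_k, params$b_k)
  V <- seq_linear_fwd(H, params$W_v, params$b_v)
  A <- vector("list", h)                 # per head: N x T x T weights
  O <- lapply(seq_len(Tn), function(t) matrix(0, N, w))
  for (k in seq_len(h)) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    S <- array(0, c(N, Tn, Tn))
    for (i in seq_len(Tn)) for (j in seq_len(Tn))
      S[, i, j] <- rowSums(Q[[i]][, cols, drop = FALSE] *
                           K[[j]][, cols, drop = FALSE]) / sqrt(dh)
    Ak <- array(0, c(N, Tn, Tn))
    for (i in seq_len(Tn)) Ak[, i, ] <- softmax_rows(matrix(S[, i, ], N, Tn))
    A[[k]] <- Ak
    for (i in seq_len(Tn)) {
      acc <- matrix(0, N, dh)
      for (j in seq_len(Tn))
        acc <- acc + V[[j]][, cols, drop = FALSE] * Ak[, i, j]
      O[[i]][, cols] <- acc
    }
  }
  Y <- seq_linear_fwd(O, params$W_o, params$b_o)
  list(Y = Y, Q = Q, K = K, V = V, A = A, O = O, h = h, dh = dh)
}

seq_mha_bwd <- function(H, cache, dY, params) {
  Tn <- length(H); N <- nrow(H[[1]]); w <- ncol(H[[1]])
  h <- cache$h; dh <- cache$dh
  outb <- seq_linear_bwd(cache$O, dY, params$W_o)
  dO <- outb$dH
  dQ <- lapply(seq_len(Tn), function(t) matrix(0, N, w))
  dK <- lapply(seq_len(Tn), function(t) matrix(0, N, w))
  dV <- lapply(seq_len(Tn), function(t) matrix(0, N, w))
  for (k in seq_len(h)) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    Ak <- cache$A[[k]]
    dA <- array(0, c(N, Tn, Tn))
    for (i in seq_len(Tn)) for (j in seq_len(Tn))
      dA[, i, j] <- rowSums(dO[[i]][, cols, drop = FALSE] *
                            cache$V[[j]][, cols, drop = FALSE])
    for (i in seq_len(Tn)) for (j in seq_len(Tn))
      dV[[j]][, cols] <- dV[[j]][, cols, drop = FALSE] +
        dO[[i]][, cols, drop = FALSE] * Ak[, i, j]
    # softmax backward over the key axis
    dS <- array(0, c(N, Tn, Tn))
    for (i in seq_len(Tn)) {
      Ai <- matrix(Ak[, i, ], N, Tn); dAi <- matrix(dA[, i, ], N, Tn)
      dS[, i, ] <- Ai * (dAi - rowSums(dAi * Ai))
    }
    for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
      sc <- dS[, i, j] / sqrt(dh)
      dQ[[i]][, cols] <- dQ[[i]][, cols, drop = FALSE] +
        cache$K[[j]][, cols, drop = FALSE] * sc
      dK[[j]][, cols] <- dK[[j]][, cols, drop = FALSE] +
        cache$Q[[i]][, cols, drop = FALSE] * sc
    }
  }
  qb <- seq_linear_bwd(H, dQ, params$W_q)
  kb <- seq_linear_bwd(H, dK, params$W_k)
  vb <- seq_linear_bwd(H, dV, params$W_v)
  dH <- mapply(function(a, b, c) a + b + c, qb$dH, kb$dH, vb$dH,
               SIMPLIFY = FALSE)
  list(dH = dH,
       grads = list(W_q = qb$dW, b_q = qb$db, W_k = kb$dW, b_k = kb$db,
                    W_v = vb$dW, b_v = vb$db, W_o = outb$dW, b_o = outb$db))
}

seq_dropout_fwd <- function(H, p, training) {
  if (!training || p <= 0) return(list(Y = H, mask = NULL))
  mask <- lapply(H, function(M)
    matrix(stats::rbinom(length(M), 1, 1 - p), nrow(M)) / (1 - p))
  list(Y = mapply(function(M, m) M * m, H, mask, SIMPLIFY = FALSE),
       mask = mask)
}

seq_dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) return(dY)
  mapply(function(d, m) d * m, dY, mask, SIMPLIFY = FALSE)
}

# uniform fan-in initialization, the default of the usual training stacks
init_mat <- function(nr, nc) {
  b <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

init_vec <- function(n, fan_in = n) {
  b <- 1 / sqrt(max(fan_in, 1))
  stats::runif(n, -b, b)
}

# flat parameter-list helpers (used by the AdamW loop and gradient checks)
params_axpy <- function(p, g, a) {
  for (nm in names(g)) p[[nm]] <- p[[nm]] + a * g[[nm]]
  p
}

params_zero_like <- function(p) lapply(p, function(x) x * 0)
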