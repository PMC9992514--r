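# Non-negative matrix factorization for topic compression.
#
# The stacked county-year x K topic matrix V (restricted to the training
# years) is factorized as V ~ W H with W >= 0 (n x D coefficients) and
# H >= 0 (D x K components). Initialization is deterministic NNDSVD
# (non-negative double SVD); optimization is Lee-Seung multiplicative
# updates on the Frobenius objective. New county-years are transformed by
# non-negative least squares against the frozen components.

nndsvd_init <- function(V, D, eps = 1e-9) {
  sv <- svd(V, nu = D, nv = D)
  n <- nrow(V); K <- ncol(V)
  W <- matrix(0, n, D); H <- matrix(0, D, K)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  for (j in seq_len(D)[-1]) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  W[W < eps] <- eps
  H[H < eps] <- eps
  list(W = W, H = H)
}

#' Fit a non-negative topic reducer on the training years
#'
#' Learns a D-component NMF of the stacked county-year topic matrix,
#' restricted to \code{fit_years} so that no information from later years
#' leaks into the representation. Deterministic given the inputs (the
#' initialization is SVD-based; \code{seed} is recorded for provenance).
#'
#' @param panel A \code{county_panel} with full (imputed) topic data.
#' @param fit_years Years used for fitting; must be a subset of the
#'   panel's years.
#' @param D Reduced dimension (default 20).
#' @param seed Integer recorded in the reducer metadata.
#' @param max_iter Maximum multiplicative-update iterations (default 500).
#' @param tol Relative-improvement stopping tolerance on the Frobenius
#'   error (default 1e-4).
#' @return A \code{topic_reducer}: list with \code{components} (D x K,
#'   non-negative), \code{D}, \code{fit_years}, \code{seed},
#'   \code{n_iter}, \code{frobenius_error}.
#' @export
fit_topic_reducer <- function(panel, fit_years, D = 20, seed = 1,
                              max_iter = 500, tol = 1e-4) {
  assert_that(all(fit_years %in% panel$years), "trop_argument_error",
              "fit_years must be panel years")
  K <- dim(panel$topics)[3]
  assert_that(D < K, "trop_argument_error", "D (%d) must be < K (%d)", D, K)
  yi <- match(fit_years, panel$years)
  V <- do.call(rbind, lapply(yi, function(j)
    matrix(panel$topics[, j, ], ncol = K)))
  assert_that(all(V >= 0), "trop_domain_error",
              "topic loadings must be non-negative for NMF")
  assert_that(nrow(V) >= D, "trop_argument_error",
              "need at least D stacked rows to fit %d components", D)

  init <- nndsvd_init(V, D)
  W <- init$W; H <- init$H
  err_prev <- Inf
  eps <- 1e-12
  it <- 0L
  for (it in seq_len(max_iter)) {
    # Lee-Seung multiplicative updates (Frobenius loss)
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    WH <- W %*% H
    W <- W * ((V %*% t(H)) / (WH %*% t(H) + eps))
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps))
        break
      err_prev <- err
    }
  }
  err <- sqrt(sum((V - W %*% H)^2))
  structure(list(components = H, D = D, K = K,
                 fit_years = as.integer(fit_years), seed = as.integer(seed),
                 n_iter = it, frobenius_error = err),
            class = "topic_reducer")
}

#' @export
print.topic_reducer <- function(x, ...) {
  cat(sprintf("<topic_reducer> %d components x %d topics, fit on years %s (%d iter, err %.4g)\n",
              x$D, x$K, paste(range(x$fit_years), collapse = "-"),
              x$n_iter, x$frobenius_error))
  invisible(x)
}

# batched non-negative least squares: min ||X - t(H) C||^2 col-wise with
# C >= 0, solved by accelerated projected gradient (FISTA) on the normal
# equations G = H H', B = H X; all columns iterate together as one D x n
# matrix so the transform stays a handful of BLAS calls.
nnls_batch <- function(G, B, max_iter = 3000, tol = 1e-9) {
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(B * 0)
  C <- pmax(B / L, 0)
  Z <- C
  tk <- 1
  for (it in seq_len(max_iter)) {
    Cn <- pmax(Z - (G %*% Z - B) / L, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Cn + ((tk - 1) / tn) * (Cn - C)
    delta <- max(abs(Cn - C))
    C <- Cn; tk <- tn
    if (delta < tol * (1 + max(abs(C)))) break
  }
  C
}

#' Project topic vectors onto fitted NMF components
#'
#' Replaces the panel's K-dimensional topic array by the D-dimensional
#' non-negative coefficients of each county-year vector on the frozen
#' components, solved by non-negative least squares.
#'
#' @param panel A \code{county_panel}.
#' @param reducer A \code{topic_reducer} from [fit_topic_reducer()].
#' @return The panel with \code{topics} of shape counties x years x D.
#' @export
reduce_topics <- function(panel, reducer) {
  K <- dim(panel$topics)[3]
  assert_that(K == reducer$K, "trop_argument_error",
              "panel has %d topics but reducer was fit on %d", K, reducer$K)
  H <- reducer$components
  G <- tcrossprod(H)            # D x D
  nC <- length(panel$counties); nY <- length(panel$years)
  out <- array(0, c(nC, nY, reducer$D),
               dimnames = list(panel$counties, panel$years,
                               paste0("c", seq_len(reducer$D) - 1)))
  for (j in seq_len(nY)) {
    Xj <- matrix(panel$topics[, j, ], ncol = K)
    B <- H %*% t(Xj)            # D x nC
    out[, j, ] <- t(nnls_batch(G, B))
  }
  panel$topics <- out
  panel$meta$reducer <- reducer[c("D", "K", "fit_years", "seed")]
  panel
}

#' Persist a topic reducer as a portable CSV/JSON pair
#'
#' @param reducer A \code{topic_reducer}.
#' @param basename Path prefix; writes \code{<basename>_components.csv}
#'   and \code{<basename>_meta.json}.
#' @export
save_topic_reducer <- function(reducer, basename) {
  utils::write.csv(as.data.frame(reducer$components),
                   paste0(basename, "_components.csv"), row.names = FALSE)
  jsonlite::write_json(reducer[c("D", "K", "fit_years", "seed", "n_iter",
                                 "frobenius_error")],
                       paste0(basename, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' @rdname save_topic_reducer
#' @export
load_topic_reducer <- function(basename) {
  comp <- as.matrix(utils::read.csv(paste0(basename, "_components.csv")))
  meta <- jsonlite::read_json(paste0(basename, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(components = unname(comp), D = meta$D, K = meta$K,
                 fit_years = as.integer(meta$fit_years),
                 seed = as.integer(meta$seed), n_iter = meta$n_iter,
                 frobenius_error = meta$frobenius_error),
            class = "topic_reducer")
}
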