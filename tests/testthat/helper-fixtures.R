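# Small in-code fixtures shared across tests.

toy_mortality_df <- function() {
  data.frame(
    fips = c("00001", "00001", "00002"),
    year = c(2011L, 2012L, 2011L),
    population = c(1e5, 1e5, 2e5),
    crude_rate = c(10, 12, 8),
    pop_t1 = c(3e4, 3e4, 7e4),
    pop_t2 = c(4e4, 4e4, 6e4),
    pop_t3 = c(3e4, 3e4, 7e4))
}

write_toy_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# tiny fully-populated panel built directly (nC counties, years, K topics)
make_tiny_panel <- function(nC = 4, years = 2011:2017, K = 6,
                            seed = 1, ses = FALSE) {
  set.seed(seed)
  nY <- length(years)
  counties <- formatC(seq_len(nC), width = 5, flag = "0")
  rates <- matrix(runif(nC * nY, 5, 40), nC, nY,
                  dimnames = list(counties, years))
  topics <- array(runif(nC * nY * K, 0, 5), c(nC, nY, K),
                  dimnames = list(counties, years,
                                  sprintf("t%04d", seq_len(K) - 1)))
  sarr <- NULL
  if (ses) {
    sarr <- array(runif(nC * nY * 7, 1, 50), c(nC, nY, 7),
                  dimnames = list(counties, years, NULL))
  }
  obs <- matrix(TRUE, nC, nY, dimnames = list(counties, years))
  terc <- array(rep(round(matrix(runif(nC * 3, 1e4, 5e4), nC)), nY),
                c(nC, 3, nY))
  terc <- aperm(terc, c(1, 3, 2))
  pop <- matrix(rowSums(terc[, 1, ]) + 1000, nC, nY)
  trop:::new_county_panel(counties, years, rates, topics, sarr, obs,
                          population = pop, terciles = terc)
}

# numeric central-difference gradient of fn over a parameter list
numeric_grad <- function(fn, params, eps = 1e-6) {
  g <- lapply(params, function(x) x * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      g[[nm]][i] <- (fn(p1) - fn(p2)) / (2 * eps)
    }
  }
  g
}

max_rel_grad_err <- function(analytic, numeric) {
  max(vapply(names(analytic), function(nm) {
    a <- as.numeric(analytic[[nm]]); b <- as.numeric(numeric[[nm]])
    denom <- max(1e-6, max(abs(b)))
    max(abs(a - b)) / denom
  }, numeric(1)))
}
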