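# builds a panel where outcome change is an exact function of topic change
make_assoc_panel <- function(nC = 50, K = 3, beta = 0.5, seed = 1) {
  set.seed(seed)
  years <- 2013:2016
  counties <- formatC(seq_len(nC), width = 5, flag = "0")
  topics <- array(runif(nC * 4 * K, 1, 3), c(nC, 4, K))
  rates <- matrix(20, nC, 4)
  xz <- scale(topics[, 2, 1] - topics[, 1, 1])  # change 2013 -> 2014
  # outcome change 2014 -> 2015 is exactly beta * standardized topic change,
  # scaled back to the outcome's own spread
  rates[, 2] <- 20 + rnorm(nC, 0, 0.5)          # prior level, noise only
  ychg <- beta * as.numeric(xz)
  rates[, 3] <- rates[, 2] + ychg
  rates[, 4] <- rates[, 3] + rnorm(nC, 0, 0.5)
  dimnames(rates) <- list(counties, years)
  trop:::new_county_panel(counties, years, rates, topics, NULL,
                          matrix(TRUE, nC, 4,
                                 dimnames = list(counties, years)))
}

test_that("an exact linear relation yields beta equal to the slope", {
  panel <- make_assoc_panel(beta = 0.5)
  res <- topic_change_association(panel, c(2013, 2014), c(2014, 2015))
  r1 <- res[res$topic_id == 0, ]
  # outcome change IS 0.5 * standardized topic change, so after
  # z-scoring the outcome the standardized coefficient is exactly 1
  expect_equal(r1$beta, 1, tolerance = 1e-8)
  expect_lt(r1$p_value, 1e-20)
  # unrelated topics stay unconvincing
  expect_gt(min(res$p_value[res$topic_id != 0]), 1e-4)
})

test_that("betas match a closed-form normal-equations oracle", {
  set.seed(33)
  panel <- make_assoc_panel(nC = 40, K = 4, beta = 0.3, seed = 2)
  panel$rates[, 3] <- panel$rates[, 2] + rnorm(40)   # add noise
  res <- topic_change_association(panel, c(2013, 2014), c(2014, 2015))
  yz <- as.numeric(scale(panel$rates[, 3] - panel$rates[, 2]))
  cz <- as.numeric(scale(panel$rates[, 2]))
  for (k in 1:4) {
    xz <- as.numeric(scale(panel$topics[, 2, k] - panel$topics[, 1, k]))
    X <- cbind(1, xz, cz)
    coefs <- solve(t(X) %*% X, t(X) %*% yz)
    expect_equal(res$beta[res$topic_id == k - 1], coefs[2],
                 tolerance = 1e-10)
  }
})

test_that("beta is invariant to positive rescaling of raw loadings and to
           county order", {
  panel <- make_assoc_panel(nC = 30, K = 2, seed = 4)
  panel$rates[, 3] <- panel$rates[, 2] + rnorm(30)
  r1 <- topic_change_association(panel, c(2013, 2014), c(2014, 2015))
  p2 <- panel; p2$topics[, , 1] <- p2$topics[, , 1] * 37.5
  r2 <- topic_change_association(p2, c(2013, 2014), c(2014, 2015))
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)

  perm <- sample(30)
  p3 <- trop:::subset_panel(panel, perm)
  r3 <- topic_change_association(p3, c(2013, 2014), c(2014, 2015))
  expect_equal(r3$beta, r1$beta, tolerance = 1e-10)
})

test_that("pure-noise topics rarely look strong", {
  hits <- replicate(100, {
    nC <- 200
    ychg <- rnorm(nC)
    xchg <- rnorm(nC)
    cz <- rnorm(nC)
    fit <- summary(lm(scale(ychg) ~ scale(xchg) + scale(cz)))$coefficients
    abs(fit[2, "Estimate"]) < 0.2 && fit[2, "Pr(>|t|)"] > 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("constant topic changes are skipped as degenerate", {
  panel <- make_assoc_panel(nC = 20, K = 2, seed = 5)
  panel$topics[, , 2] <- 1.5   # constant in every year
  res <- topic_change_association(panel, c(2013, 2014), c(2014, 2015))
  expect_true(res$degenerate[res$topic_id == 1])
  expect_false(res$degenerate[res$topic_id == 0])
  expect_true(is.na(res$q_value[res$topic_id == 1]))
})

test_that("multiple year pairs run separately and label target years", {
  panel <- make_assoc_panel(nC = 25, K = 2, seed = 6)
  res <- topic_change_association(panel,
                                  topic_years = list(c(2013, 2014),
                                                     c(2014, 2015)),
                                  outcome_years = list(c(2014, 2015),
                                                       c(2015, 2016)))
  expect_equal(sort(unique(res$target_year)), c(2015, 2016))
  expect_equal(sum(res$target_year == 2015), 2)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "trop_argument_error")
})

test_that("BH equals a brute-force step-up oracle on grid lists", {
  # oracle: q_(i) = min_{j >= i} p_(j) m / j, capped at 1
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- ps * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m); out[ord] <- q
    out
  }
  set.seed(77)
  grid <- seq(0.01, 0.99, by = 0.01)
  for (len in 1:6) {
    for (rep in 1:60) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
  # monotone: smaller p never gets the larger q
  p <- sample(grid, 30, replace = TRUE)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("significant_topics partitions and ranks by effect size", {
  res <- data.frame(topic_id = 0:4, target_year = 2016,
                    beta = c(0.5, -0.8, 0.2, -0.1, 0.9),
                    p_value = c(1e-5, 1e-6, 0.2, 0.8, 1e-7),
                    q_value = c(0.001, 0.001, 0.5, 0.9, 0.001),
                    direction = sign(c(0.5, -0.8, 0.2, -0.1, 0.9)),
                    n = 100, degenerate = FALSE)
  sig <- significant_topics(res, alpha = 0.05)
  expect_equal(sig$positive$topic_id, c(4, 0))
  expect_equal(sig$negative$topic_id, 1)
  res$q_value <- 1
  empty <- significant_topics(res)
  expect_equal(nrow(empty$positive) + nrow(empty$negative), 0)
})
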