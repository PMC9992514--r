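test_that("age adjustment is a no-op under a uniform age structure", {
  panel <- make_tiny_panel(nC = 6, years = 2011:2013)
  for (j in seq_along(panel$years)) panel$terciles[, j, ] <-
    matrix(rep(c(2e4, 3e4, 2e4), each = 6), 6)
  adj <- age_adjust(panel, "standard")
  expect_equal(adj$rates, panel$rates, tolerance = 1e-10)
})

test_that("standard-mode adjustment preserves each year's mean rate", {
  panel <- make_tiny_panel(nC = 8, years = 2011:2014, seed = 3)
  adj <- age_adjust(panel, "standard")
  expect_equal(colMeans(adj$rates), colMeans(panel$rates),
               tolerance = 1e-12)
  expect_equal(adj$meta$crude_rates, panel$rates)
})

test_that("adjusted rates match an independent least-squares oracle", {
  # 5 counties, hand-set terciles and rates; oracle solves the normal
  # equations directly and applies both residual conventions
  counties <- formatC(1:5, width = 5, flag = "0")
  years <- 2011:2012
  rates <- matrix(c(10, 14, 22, 8, 30,
                    12, 15, 25, 9, 28), 5, 2,
                  dimnames = list(counties, years))
  terc <- array(0, c(5, 2, 3))
  terc[, 1, ] <- matrix(c(1e4, 2e4, 3e4,
                          2e4, 2e4, 2e4,
                          3e4, 1e4, 2e4,
                          1e4, 1e4, 1e4,
                          4e4, 3e4, 2e4), 5, 3, byrow = TRUE)
  terc[, 2, ] <- terc[, 1, ] * 1.05
  panel <- trop:::new_county_panel(
    counties, years, rates,
    array(1, c(5, 2, 2)), NULL,
    matrix(TRUE, 5, 2), population = matrix(1e5, 5, 2), terciles = terc)

  for (mode in c("standard", "literal")) {
    adj <- age_adjust(panel, mode)
    for (j in 1:2) {
      X <- cbind(1, terc[, j, ])
      beta <- solve(t(X) %*% X, t(X) %*% rates[, j])
      fitted <- drop(X %*% beta)
      resid <- rates[, j] - fitted
      expected <- if (mode == "standard") resid + mean(rates[, j])
                  else fitted + mean(rates[, j])
      expect_equal(unname(adj$rates[, j]), unname(expected),
                   tolerance = 1e-8)
    }
  }
})

test_that("activity filtering drops counties below the overall user floor", {
  panel <- make_tiny_panel(nC = 3, years = 2011:2013)
  counts <- data.frame(fips = rep(panel$counties, each = 1),
                       year = NA_integer_,
                       n_users = c(150, 99, 200))
  out <- filter_by_activity(panel, counts)
  expect_equal(out$counties, panel$counties[c(1, 3)])

  # all above threshold: unchanged
  counts$n_users <- c(150, 120, 200)
  out2 <- filter_by_activity(panel, counts)
  expect_equal(out2$counties, panel$counties)
  expect_equal(out2$rates, panel$rates)

  # per-year shortfall only unsets the observation mask
  counts3 <- rbind(counts,
                   data.frame(fips = panel$counties[1], year = 2012L,
                              n_users = 40))
  out3 <- filter_by_activity(panel, counts3)
  expect_equal(out3$counties, panel$counties)
  expect_false(out3$topic_observed[1, 2])
  expect_true(all(out3$topic_observed[-1, ]))

  expect_error(filter_by_activity(panel, counts[-1, ]),
               class = "trop_coverage_error")
})

test_that("topic imputation fills with yearly cross-county means and drops
           counties with too many missing years", {
  panel <- make_tiny_panel(nC = 3, years = 2011:2017, K = 2)
  panel$topics[1, 4, ] <- c(1, 3)
  panel$topics[2, 4, ] <- c(3, 5)
  panel$topic_observed[3, 4] <- FALSE
  before <- panel$topics
  out <- impute_topic_years(panel)
  expect_equal(unname(out$topics[3, 4, ]), c(2, 4))
  # observed cells untouched
  expect_equal(out$topics[1:2, , ], before[1:2, , ])

  # > 2 missing years: dropped
  panel2 <- make_tiny_panel(nC = 3, years = 2011:2017, K = 2)
  panel2$topic_observed[2, c(1, 3, 5)] <- FALSE
  out2 <- impute_topic_years(panel2)
  expect_equal(out2$counties, panel2$counties[c(1, 3)])

  # no missing cells: identity
  panel3 <- make_tiny_panel(nC = 3, years = 2011:2013, K = 2)
  out3 <- impute_topic_years(panel3)
  expect_equal(out3$topics, panel3$topics)

  # a year with no observed county is an error
  panel4 <- make_tiny_panel(nC = 2, years = 2011:2013, K = 2)
  panel4$topic_observed[, 2] <- FALSE
  expect_error(impute_topic_years(panel4),
               class = "trop_imputation_error")
})

test_that("feature sequences have the documented per-year dimensions", {
  panel <- make_tiny_panel(nC = 2, years = 2011:2017, K = 20, ses = TRUE)
  expect_equal(ncol(build_sequences(panel, "univariate")[[1]]$values), 1)
  expect_equal(ncol(build_sequences(panel, "multivariate")[[1]]$values), 21)
  expect_equal(ncol(build_sequences(panel, "multivariate_ses")[[1]]$values),
               28)
  panel$ses <- NULL
  expect_error(build_sequences(panel, "multivariate_ses"),
               class = "trop_argument_error")
})
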