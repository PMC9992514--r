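#' Age-adjust crude death rates by within-year regression residuals
#'
#' For each year independently, regresses the crude rate on the county's
#' three age-tercile population counts (with intercept) across counties,
#' and replaces each county's rate by a residual-based adjusted rate.
#' With residual \eqn{r_c = crude_c - fitted_c} and yearly cross-county
#' mean \eqn{\bar O}:
#' \describe{
#'   \item{standard}{\eqn{adj_c = r_c + \bar O}. The part of the rate
#'     explained by age composition is removed; adjustment is a no-op when
#'     all counties share an age structure, and the yearly mean rate is
#'     preserved exactly.}
#'   \item{literal}{\eqn{adj_c = crude_c - r_c + \bar O = fitted_c + \bar O},
#'     retained for audits of the alternative sign reading.}
#' }
#'
#' @param panel A \code{county_panel} carrying tercile populations.
#' @param mode \code{"standard"} (default) or \code{"literal"}.
#' @return The panel with its \code{rates} matrix replaced by adjusted
#'   rates; the crude rates are kept in \code{meta$crude_rates}.
#' @export
age_adjust <- function(panel, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  assert_that(!is.null(panel$terciles) && !anyNA(panel$terciles),
              "trop_argument_error",
              "tercile populations are required for age adjustment")
  nY <- length(panel$years)
  nC <- length(panel$counties)
  assert_that(nC >= 5, "trop_rank_error",
              "need at least 5 counties to fit 4 regression coefficients")
  adj <- panel$rates
  for (j in seq_len(nY)) {
    y <- panel$rates[, j]
    X <- panel$terciles[, j, ]
    fit <- stats::lm.fit(cbind(1, X), y)
    resid <- fit$residuals
    omean <- mean(y)
    adj[, j] <- if (mode == "standard") resid + omean else y - resid + omean
  }
  if (any(adj < 0)) {
    message(sprintf("age_adjust: %d adjusted rates are negative (kept)",
                    sum(adj < 0)))
  }
  panel$meta$crude_rates <- panel$rates
  panel$meta$age_adjust_mode <- mode
  panel$rates <- adj
  panel
}

#' Filter counties by Twitter-activity inclusion criteria
#'
#' A county is retained only if, over the whole panel span, it has at least
#' \code{min_users} users each with at least \code{min_tweets_per_user}
#' tweets. Per-year shortfalls do not drop a county; they only mark that
#' county-year's topic vector as unobserved (to be imputed downstream).
#'
#' @param panel A \code{county_panel}.
#' @param user_counts Data frame with columns \code{fips}, \code{year},
#'   \code{n_users}: the number of users meeting the per-user tweet
#'   minimum. Rows with \code{year = NA} give the whole-span count and are
#'   required for every retained county; per-year rows are optional.
#' @param min_users Minimum qualifying users over the span (default 100).
#' @param min_tweets_per_user Documented per-user tweet minimum already
#'   applied upstream when building \code{n_users} (default 30).
#' @return The filtered panel.
#' @export
filter_by_activity <- function(panel, user_counts, min_users = 100,
                               min_tweets_per_user = 30) {
  assert_that(all(c("fips", "year", "n_users") %in% names(user_counts)),
              "trop_argument_error",
              "user_counts needs columns fips, year, n_users")
  user_counts$fips <- pad_fips(user_counts$fips)
  overall <- user_counts[is.na(user_counts$year), ]
  missing <- setdiff(panel$counties, overall$fips)
  assert_that(length(missing) == 0, "trop_coverage_error",
              "user_counts missing whole-span rows for: %s",
              paste(utils::head(missing, 5), collapse = ", "))
  ok <- overall$fips[overall$n_users >= min_users]
  keep <- panel$counties %in% ok
  out <- subset_panel(panel, which(keep))

  yearly <- user_counts[!is.na(user_counts$year), ]
  if (nrow(yearly)) {
    ci <- match(yearly$fips, out$counties)
    yi <- match(yearly$year, out$years)
    bad <- !is.na(ci) & !is.na(yi) & yearly$n_users < min_users
    out$topic_observed[cbind(ci[bad], yi[bad])] <- FALSE
  }
  out$meta$activity <- list(min_users = min_users,
                            min_tweets_per_user = min_tweets_per_user)
  out
}

subset_panel <- function(panel, idx) {
  assert_that(length(idx) > 0, "trop_empty_panel_error",
              "no counties left after filtering")
  panel$counties <- panel$counties[idx]
  panel$rates <- panel$rates[idx, , drop = FALSE]
  panel$topics <- panel$topics[idx, , , drop = FALSE]
  panel$topic_observed <- panel$topic_observed[idx, , drop = FALSE]
  if (!is.null(panel$ses)) panel$ses <- panel$ses[idx, , , drop = FALSE]
  if (!is.null(panel$population))
    panel$population <- panel$population[idx, , drop = FALSE]
  if (!is.null(panel$terciles))
    panel$terciles <- panel$terciles[idx, , , drop = FALSE]
  panel
}

#' Impute unobserved topic-years from the cross-county yearly mean
#'
#' Each county-year topic vector flagged unobserved is replaced by the
#' unweighted mean of that year's observed vectors. Counties with more
#' than \code{max_missing_years} unobserved years are dropped first.
#'
#' @param panel A \code{county_panel}.
#' @param max_missing_years Maximum tolerated unobserved years per county
#'   (default 2).
#' @return The panel with all topic cells filled; \code{topic_observed}
#'   still records which cells were imputed.
#' @export
impute_topic_years <- function(panel, max_missing_years = 2) {
  nmiss <- rowSums(!panel$topic_observed)
  panel <- subset_panel(panel, which(nmiss <= max_missing_years))
  for (j in seq_along(panel$years)) {
    obs <- panel$topic_observed[, j]
    if (all(obs)) next
    assert_that(any(obs), "trop_imputation_error",
                "year %d has no observed county topic vector", panel$years[j])
    m <- apply(panel$topics[obs, j, , drop = FALSE], 3, mean)
    for (i in which(!obs)) panel$topics[i, j, ] <- m
  }
  panel
}

#' Build per-county model-input feature sequences
#'
#' Produces one ordered sequence of per-year feature vectors per county,
#' with the outcome rate in column 1 followed by the (reduced) topic
#' features and, optionally, the 7 SES covariates. The outcome column
#' always carries the raw level here; differencing is applied during
#' window construction. When \code{difference_features} is on (default),
#' covariate entries of each window step are the year-over-year changes
#' rather than levels.
#'
#' @param panel A \code{county_panel} (topics already reduced for the
#'   multivariate feature sets).
#' @param feature_set One of \code{"univariate"}, \code{"multivariate"},
#'   \code{"multivariate_ses"}.
#' @param difference_features Difference the topic/SES covariates inside
#'   windows (default TRUE).
#' @return A list of \code{feature_sequence} objects (fields \code{fips},
#'   \code{years}, \code{values} years-by-dim level matrix, and the
#'   covariate-differencing flag).
#' @export
build_sequences <- function(panel,
                            feature_set = c("univariate", "multivariate",
                                            "multivariate_ses"),
                            difference_features = TRUE) {
  feature_set <- match.arg(feature_set)
  if (feature_set == "multivariate_ses")
    assert_that(!is.null(panel$ses), "trop_argument_error",
                "feature set multivariate_ses requires SES data in the panel")
  D <- dim(panel$topics)[3]
  lapply(seq_along(panel$counties), function(i) {
    vals <- switch(feature_set,
      univariate = matrix(panel$rates[i, ], ncol = 1,
                          dimnames = list(NULL, "rate")),
      multivariate = cbind(rate = panel$rates[i, ],
                           matrix(panel$topics[i, , ], ncol = D,
                                  dimnames = list(NULL, dimnames(panel$topics)[[3]]))),
      multivariate_ses = cbind(rate = panel$rates[i, ],
                               matrix(panel$topics[i, , ], ncol = D),
                               matrix(panel$ses[i, , ], ncol = 7,
                                      dimnames = list(NULL, ses_columns))))
    structure(list(fips = panel$counties[i], years = panel$years,
                   values = vals,
                   diff_covariates = isTRUE(difference_features)),
              class = "feature_sequence")
  })
}
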