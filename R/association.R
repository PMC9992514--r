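#' Lagged topic-change association with the future outcome change
#'
#' For each topic, regresses the standardized county-level future
#' outcome change on the standardized prior topic change, adjusting for
#' the prior-year outcome (level by default, or prior change), by
#' ordinary least squares across counties. The topic coefficient is the
#' standardized association \eqn{\beta} with a two-sided p-value;
#' p-values are Benjamini-Hochberg adjusted across topics within each
#' target year.
#'
#' @param panel A \code{county_panel}; the full (pre-reduction) topic set
#'   is tested unless the panel has already been reduced.
#' @param topic_years Prior change pair \code{c(y0, y1)}, or a list of
#'   pairs (one per target analysis).
#' @param outcome_years Future change pair \code{c(y1, y2)}, or a list
#'   aligned with \code{topic_years}.
#' @param covariate \code{"level"} (default; prior-year outcome level) or
#'   \code{"change"} (prior outcome change over \code{topic_years}).
#' @param observed_only Restrict to counties whose topic vectors in the
#'   tested pair of years are actually observed (default TRUE). Imputed
#'   vectors are cross-county means, so a county imputed in one year of
#'   the pair would contribute a spurious jump between its own loading
#'   and the yearly mean rather than a real language change.
#' @return Data frame of \code{association_result} rows: topic_id,
#'   target_year, beta, p_value, q_value, direction, n, degenerate.
#' @export
topic_change_association <- function(panel, topic_years, outcome_years,
                                     covariate = c("level", "change"),
                                     observed_only = TRUE) {
  covariate <- match.arg(covariate)
  if (!is.list(topic_years)) topic_years <- list(topic_years)
  if (!is.list(outcome_years)) outcome_years <- list(outcome_years)
  assert_that(length(topic_years) == length(outcome_years),
              "trop_argument_error",
              "topic_years and outcome_years must align")
  out <- do.call(rbind, mapply(function(ty, oy) {
    assoc_one(panel, ty, oy, covariate, observed_only)
  }, topic_years, outcome_years, SIMPLIFY = FALSE))
  rownames(out) <- NULL
  out
}

assoc_one <- function(panel, topic_years, outcome_years, covariate,
                      observed_only = TRUE) {
  yrs <- panel$years
  assert_that(all(c(topic_years, outcome_years) %in% yrs),
              "trop_argument_error",
              "required years missing from panel")
  t0 <- match(topic_years[1], yrs); t1 <- match(topic_years[2], yrs)
  if (observed_only) {
    keep <- panel$topic_observed[, t0] & panel$topic_observed[, t1]
    panel <- subset_panel(panel, which(keep))
  }
  nC <- length(panel$counties)
  assert_that(nC >= 3, "trop_argument_error",
              "association needs at least 3 counties")
  o1 <- match(outcome_years[1], yrs); o2 <- match(outcome_years[2], yrs)
  ychg <- panel$rates[, o2] - panel$rates[, o1]
  assert_that(stats::sd(ychg) > 0, "trop_argument_error",
              "outcome change into %d is constant across counties",
              outcome_years[2])
  yz <- as.numeric(scale(ychg))
  cov_raw <- if (covariate == "level") panel$rates[, o1]
             else panel$rates[, t1] - panel$rates[, t0]
  cz <- as.numeric(scale(cov_raw))
  if (all(!is.finite(cz))) cz <- rep(0, nC)
  K <- dim(panel$topics)[3]
  res <- vector("list", K)
  for (k in seq_len(K)) {
    xchg <- panel$topics[, t1, k] - panel$topics[, t0, k]
    if (stats::sd(xchg) == 0) {
      res[[k]] <- data.frame(topic_id = k - 1L,
                             target_year = outcome_years[2],
                             beta = NA_real_, p_value = NA_real_,
                             n = nC, degenerate = TRUE)
      next
    }
    xz <- as.numeric(scale(xchg))
    fit <- stats::lm(yz ~ xz + cz)
    sm <- summary(fit)$coefficients
    res[[k]] <- data.frame(topic_id = k - 1L,
                           target_year = outcome_years[2],
                           beta = sm["xz", "Estimate"],
                           p_value = sm["xz", "Pr(>|t|)"],
                           n = nC, degenerate = FALSE)
  }
  res <- do.call(rbind, res)
  res$q_value <- NA_real_
  ok <- !res$degenerate
  res$q_value[ok] <- bh_adjust(res$p_value[ok])
  res$direction <- sign(res$beta)
  res[, c("topic_id", "target_year", "beta", "p_value", "q_value",
          "direction", "n", "degenerate")]
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned
#' in the original order.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Adjusted q-values, same order.
#' @export
bh_adjust <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = FALSE),
              "trop_argument_error", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter and rank BH-significant topics
#'
#' Topics with \code{q_value < alpha}, partitioned by the sign of beta
#' (negative = language rising before decreases, positive = before
#' increases), sorted by absolute effect within each partition.
#'
#' @param results Data frame from [topic_change_association()].
#' @param alpha FDR threshold (default 0.05).
#' @return List with \code{positive} and \code{negative} data frames.
#' @export
significant_topics <- function(results, alpha = 0.05) {
  sig <- results[!results$degenerate & !is.na(results$q_value) &
                   results$q_value < alpha, , drop = FALSE]
  pos <- sig[sig$beta > 0, , drop = FALSE]
  neg <- sig[sig$beta < 0, , drop = FALSE]
  list(positive = pos[order(-abs(pos$beta)), , drop = FALSE],
       negative = neg[order(-abs(neg$beta)), , drop = FALSE])
}

#' Write association results as CSV
#'
#' @param results Data frame from [topic_change_association()].
#' @param path Output path.
#' @export
write_association_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(results)
}
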