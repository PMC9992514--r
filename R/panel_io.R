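#' Read a county-year mortality table
#'
#' Parses a CSV export of county-level opioid mortality in the package's
#' documented dialect: columns \code{fips, year, population, crude_rate,
#' pop_t1, pop_t2, pop_t3}, one row per county-year. \code{pop_t1..pop_t3}
#' are the population counts falling in that year's national age terciles,
#' used downstream for regression-based age adjustment. Alternatively a
#' \code{deaths} column may be authoritative, in which case crude rates per
#' 100,000 persons are derived from \code{deaths / population}.
#'
#' @param path Path to the CSV file.
#' @param year_range Inclusive integer pair \code{c(first, last)}; rows
#'   outside the range are dropped.
#' @param rate_from Either \code{"crude_rate"} (default) or \code{"deaths"};
#'   selects which column is authoritative for the outcome rate.
#' @return A data frame with columns \code{fips} (zero-padded character),
#'   \code{year}, \code{population}, \code{crude_rate}, \code{pop_t1},
#'   \code{pop_t2}, \code{pop_t3}.
#' @export
read_mortality_csv <- function(path, year_range,
                               rate_from = c("crude_rate", "deaths")) {
  rate_from <- match.arg(rate_from)
  df <- read_table_csv(path)
  need <- c("fips", "year", "population",
            if (rate_from == "crude_rate") "crude_rate" else "deaths",
            "pop_t1", "pop_t2", "pop_t3")
  check_columns(df, need, path)
  df$fips <- pad_fips(df$fips)
  df$year <- as.integer(df$year)
  df <- df[df$year >= year_range[1] & df$year <= year_range[2], , drop = FALSE]
  check_no_duplicates(df)
  if (rate_from == "deaths") {
    df$crude_rate <- 1e5 * as.numeric(df$deaths) / as.numeric(df$population)
  }
  df$crude_rate <- as.numeric(df$crude_rate)
  df$population <- as.numeric(df$population)
  assert_that(all(df$crude_rate >= 0), "trop_validation_error",
              "negative crude_rate encountered in %s", path)
  assert_that(all(df$population > 0), "trop_validation_error",
              "non-positive population encountered in %s", path)
  terc <- as.matrix(df[, c("pop_t1", "pop_t2", "pop_t3")])
  assert_that(all(terc >= 0), "trop_validation_error",
              "negative tercile population in %s", path)
  assert_that(all(rowSums(terc) <= df$population * 1.001),
              "trop_validation_error",
              "tercile populations exceed total population in %s", path)
  rownames(df) <- NULL
  df[, c("fips", "year", "population", "crude_rate",
         "pop_t1", "pop_t2", "pop_t3")]
}

#' Read a county-year topic-loading table
#'
#' Columns: \code{fips, year, t0000..tNNNN} with non-negative loadings. All
#' rows must carry the same number of topic columns.
#'
#' @inheritParams read_mortality_csv
#' @return A data frame with \code{fips}, \code{year} and a \code{loadings}
#'   matrix column (counties-by-K).
#' @export
read_topics_csv <- function(path, year_range) {
  df <- read_table_csv(path)
  check_columns(df, c("fips", "year"), path)
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  assert_that(length(tcols) >= 1, "trop_schema_error",
              "no topic columns (t0000..) found in %s", path)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  df$fips <- pad_fips(df$fips)
  df$year <- as.integer(df$year)
  df <- df[df$year >= year_range[1] & df$year <= year_range[2], , drop = FALSE]
  check_no_duplicates(df)
  loadings <- as.matrix(df[, tcols, drop = FALSE])
  storage.mode(loadings) <- "double"
  assert_that(all(loadings >= 0), "trop_validation_error",
              "negative topic loading in %s", path)
  out <- df[, c("fips", "year")]
  rownames(out) <- rownames(loadings) <- NULL
  out$loadings <- loadings
  out
}

ses_columns <- c("log_median_income", "median_age", "pct_over_65",
                 "pct_female", "pct_african_american", "pct_hs_grad",
                 "pct_bachelor")

#' Read a county-year socio-economic table
#'
#' Columns: \code{fips, year} plus the seven variables
#' \code{log_median_income, median_age, pct_over_65, pct_female,
#' pct_african_american, pct_hs_grad, pct_bachelor}; percentages must lie
#' in [0, 100].
#'
#' @inheritParams read_mortality_csv
#' @return A data frame with \code{fips}, \code{year} and an n-by-7
#'   \code{ses} matrix column (column order as listed above).
#' @export
read_ses_csv <- function(path, year_range) {
  df <- read_table_csv(path)
  check_columns(df, c("fips", "year", ses_columns), path)
  df$fips <- pad_fips(df$fips)
  df$year <- as.integer(df$year)
  df <- df[df$year >= year_range[1] & df$year <= year_range[2], , drop = FALSE]
  check_no_duplicates(df)
  ses <- as.matrix(df[, ses_columns, drop = FALSE])
  storage.mode(ses) <- "double"
  pct <- ses[, grep("^pct_", ses_columns), drop = FALSE]
  assert_that(all(pct >= 0 & pct <= 100), "trop_validation_error",
              "SES percentage outside [0, 100] in %s", path)
  out <- df[, c("fips", "year")]
  rownames(out) <- rownames(ses) <- NULL
  out$ses <- ses
  out
}

read_table_csv <- function(path) {
  assert_that(file.exists(path), "trop_io_error", "file not found: %s", path)
  utils::read.csv(path, colClasses = c(fips = "character"),
                  check.names = TRUE, stringsAsFactors = FALSE)
}

check_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0, "trop_schema_error",
              "missing column(s) %s in %s", paste(missing, collapse = ", "),
              path)
}

check_no_duplicates <- function(df) {
  key <- paste(df$fips, df$year)
  dup <- key[duplicated(key)]
  assert_that(length(dup) == 0, "trop_integrity_error",
              "duplicate (fips, year) rows: %s",
              paste(unique(dup), collapse = "; "))
}

#' Assemble an aligned county-year panel
#'
#' Aligns the mortality, topic and (optional) socio-economic tables on a
#' common set of counties and a consecutive year axis. Only counties with
#' an observed outcome for \emph{every} year of the range are retained;
#' county-years without a topic row are kept but flagged unobserved in
#' \code{topic_observed} (imputation is a separate downstream step).
#'
#' @param mortality Data frame from [read_mortality_csv()].
#' @param topics Data frame from [read_topics_csv()].
#' @param ses Optional data frame from [read_ses_csv()]; counties missing
#'   any SES year are dropped when supplied.
#' @param year_range Inclusive integer pair; must span consecutive years.
#' @return A \code{county_panel} object: list with \code{counties},
#'   \code{years}, \code{rates} (counties x years), \code{topics}
#'   (counties x years x K), \code{ses} (counties x years x 7 or NULL),
#'   \code{topic_observed} (logical counties x years) and \code{meta}.
#' @export
assemble_panel <- function(mortality, topics, ses = NULL, year_range) {
  years <- seq.int(year_range[1], year_range[2])
  assert_that(is_consecutive(years) && length(years) >= 2,
              "trop_argument_error", "year_range must span >= 2 consecutive years")

  counties <- sort(unique(mortality$fips))
  complete <- vapply(counties, function(f) {
    yrs <- mortality$year[mortality$fips == f]
    all(years %in% yrs)
  }, logical(1))
  counties <- counties[complete]

  if (!is.null(ses)) {
    ses_ok <- vapply(counties, function(f) {
      all(years %in% ses$year[ses$fips == f])
    }, logical(1))
    counties <- counties[ses_ok]
  }
  assert_that(length(counties) > 0, "trop_empty_panel_error",
              "no county has a complete outcome series over %d-%d",
              year_range[1], year_range[2])

  nC <- length(counties); nY <- length(years)
  rates <- matrix(NA_real_, nC, nY, dimnames = list(counties, years))
  terc <- array(NA_real_, c(nC, nY, 3),
                dimnames = list(counties, years, c("t1", "t2", "t3")))
  pop <- matrix(NA_real_, nC, nY, dimnames = list(counties, years))
  idx <- match(paste(mortality$fips, mortality$year),
               paste(rep(counties, nY), rep(years, each = nC)))
  keep <- !is.na(idx)
  rates[idx[keep]] <- mortality$crude_rate[keep]
  pop[idx[keep]] <- mortality$population[keep]
  for (j in 1:3) terc[, , j][idx[keep]] <- mortality[[paste0("pop_t", j)]][keep]

  K <- ncol(topics$loadings)
  tarr <- array(0, c(nC, nY, K),
                dimnames = list(counties, years, colnames(topics$loadings)))
  observed <- matrix(FALSE, nC, nY, dimnames = list(counties, years))
  ti <- match(paste(topics$fips, topics$year),
              paste(rep(counties, nY), rep(years, each = nC)))
  tkeep <- !is.na(ti)
  observed[ti[tkeep]] <- TRUE
  if (any(tkeep)) {
    rows <- which(tkeep)
    ci <- (ti[tkeep] - 1) %% nC + 1
    yi <- (ti[tkeep] - 1) %/% nC + 1
    for (r in seq_along(rows))
      tarr[ci[r], yi[r], ] <- topics$loadings[rows[r], ]
  }

  sarr <- NULL
  if (!is.null(ses)) {
    sarr <- array(NA_real_, c(nC, nY, 7),
                  dimnames = list(counties, years, ses_columns))
    si <- match(paste(ses$fips, ses$year),
                paste(rep(counties, nY), rep(years, each = nC)))
    skeep <- !is.na(si)
    rows <- which(skeep)
    ci <- (si[skeep] - 1) %% nC + 1
    yi <- (si[skeep] - 1) %/% nC + 1
    for (r in seq_along(rows))
      sarr[ci[r], yi[r], ] <- ses$ses[rows[r], ]
  }

  new_county_panel(counties, years, rates, tarr, sarr, observed,
                   population = pop, terciles = terc)
}

new_county_panel <- function(counties, years, rates, topics, ses, observed,
                             population = NULL, terciles = NULL,
                             meta = list()) {
  stopifnot(nrow(rates) == length(counties), ncol(rates) == length(years))
  assert_that(!anyNA(rates), "trop_integrity_error",
              "panel rates contain missing values")
  structure(list(counties = counties, years = as.integer(years),
                 rates = rates, topics = topics, ses = ses,
                 topic_observed = observed, population = population,
                 terciles = terciles, meta = meta),
            class = "county_panel")
}

#' @export
print.county_panel <- function(x, ...) {
  cat(sprintf("<county_panel> %d counties x %d years (%d-%d), %d topic dims%s\n",
              length(x$counties), length(x$years), min(x$years), max(x$years),
              dim(x$topics)[3], if (is.null(x$ses)) "" else ", +SES"))
  cat(sprintf("  topic cells observed: %d / %d\n",
              sum(x$topic_observed), length(x$topic_observed)))
  invisible(x)
}

#' @export
dim.county_panel <- function(x) {
  c(counties = length(x$counties), years = length(x$years),
    topics = dim(x$topics)[3])
}

#' Write per-window forecasts next to observed rates
#'
#' Writes one CSV row per (county, year) with the observed rate, the
#' predicted rate, the predicted change and the absolute error, aligned to
#' the panel's county order.
#'
#' @param panel A \code{county_panel}.
#' @param predictions Data frame with columns \code{fips}, \code{year},
#'   \code{predicted_level}, \code{predicted_change} (as produced by
#'   [forecast()]).
#' @param path Output CSV path.
#' @export
write_predictions_csv <- function(panel, predictions, path) {
  need <- c("fips", "year", "predicted_level", "predicted_change")
  assert_that(all(need %in% names(predictions)), "trop_argument_error",
              "predictions must have columns %s", paste(need, collapse = ", "))
  ci <- match(predictions$fips, panel$counties)
  yi <- match(predictions$year, panel$years)
  assert_that(!anyNA(ci) && !anyNA(yi), "trop_argument_error",
              "predictions are not aligned to the panel (unknown fips or year)")
  observed <- panel$rates[cbind(ci, yi)]
  out <- data.frame(fips = predictions$fips, year = predictions$year,
                    observed_rate = observed,
                    predicted_rate = predictions$predicted_level,
                    predicted_change = predictions$predicted_change,
                    abs_error = abs(observed - predictions$predicted_level))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
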