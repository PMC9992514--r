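#' Configuration of the synthetic county-panel generator
#'
#' Generates county-year panels with the statistical structure the
#' pipeline assumes: per-county outcome rates following an
#' autoregressive change process with an upward per-county drift, whose
#' future changes partially depend on the lagged changes of a small set
#' of "signal" topics; nuisance topics evolving by non-negative random
#' walks; time-constant age terciles adding a county age offset to the
#' crude rate; optional SES covariates tied to one latent county factor;
#' and a sprinkle of unobserved topic-years (at most 2 per county).
#'
#' Default scales mirror the real setting the pipeline targets: rates of
#' roughly 5-40 deaths per 100,000 with yearly changes of a few units
#' per 100k over a 7-year span.
#'
#' @param n_counties Counties (default 357).
#' @param n_years Consecutive years (default 7, labelled 2011 onward).
#' @param n_topics Topic dimension K (default 2000).
#' @param n_signal_topics Topics carrying signal (default 8).
#' @param ar_coefficient Persistence of the outcome-change process in
#'   (-1, 1) (default 0.25).
#' @param language_effect Standardized-scale coefficient linking each
#'   lagged signal-topic change to the next outcome change (default 0.5;
#'   0 removes all language signal).
#' @param noise_sd Outcome innovation SD, per-100k change units
#'   (default 1.0).
#' @param drift_mean,drift_sd Mean and between-county SD of the
#'   per-county yearly drift (defaults 1.0, 0.5 per 100k).
#' @param base_rate_range Initial-rate interval per 100k (default
#'   c(5, 40)).
#' @param topic_drift_sd Yearly random-walk SD of nuisance topic
#'   loadings (default 0.1); signal topics use
#'   \code{signal_drift_multiplier} times this so the planted signal sits
#'   among the dominant directions of language variation.
#' @param signal_drift_multiplier Default 2.
#' @param age_effect Per-100k offset per SD of elderly population share
#'   (default 2; time-constant, so differencing removes it).
#' @param missing_rate Probability scale of unobserved topic-years;
#'   capped at 2 missing years per county by construction (default
#'   0.01, a small number of counties per year).
#' @param ses Generate the 7 SES covariates (default TRUE).
#' @param first_year First calendar year label (default 2011).
#' @param seed Integer master seed; all draws derive from it through
#'   labelled substreams, so e.g. toggling SES does not perturb the
#'   topic draws.
#' @export
sim_config <- function(n_counties = 357, n_years = 7, n_topics = 2000,
                       n_signal_topics = 8, ar_coefficient = 0.25,
                       language_effect = 0.5, noise_sd = 1.0,
                       drift_mean = 1.0, drift_sd = 0.5,
                       base_rate_range = c(5, 40), topic_drift_sd = 0.1,
                       signal_drift_multiplier = 2, age_effect = 2,
                       missing_rate = 0.01, ses = TRUE,
                       first_year = 2011, seed = 1) {
  assert_that(n_signal_topics <= n_topics, "trop_argument_error",
              "n_signal_topics cannot exceed n_topics")
  assert_that(noise_sd >= 0 && missing_rate >= 0 && missing_rate <= 1,
              "trop_argument_error", "invalid noise/missing parameters")
  assert_that(abs(ar_coefficient) < 1, "trop_argument_error",
              "ar_coefficient must be in (-1, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic county panel with planted language signal
#'
#' @param config A [sim_config()].
#' @return List with \code{panel} (a \code{county_panel} whose rates are
#'   crude rates) and \code{truth}: the signal topic ids (0-based, as in
#'   association output), their raw-scale coefficients, the per-county
#'   drift, and the age offsets.
#' @export
generate_panel <- function(config) {
  nC <- config$n_counties; nY <- config$n_years; K <- config$n_topics
  years <- seq(config$first_year, length.out = nY)
  counties <- pad_fips(seq_len(nC))

  # latent county factor drives population structure and SES
  u <- with_substream(config$seed, "latent", stats::rnorm(nC))

  pops <- with_substream(config$seed, "population",
    round(exp(stats::rnorm(nC, log(2e5), 0.7))))
  shares <- with_substream(config$seed, "terciles", {
    raw <- cbind(1 / 3 - 0.08 * u, rep(1 / 3, nC), 1 / 3 + 0.08 * u) +
      matrix(stats::rnorm(3 * nC, 0, 0.02), nC)
    raw <- pmax(raw, 0.05)
    raw / rowSums(raw)
  })
  terc <- round(shares * pops)
  old_share <- terc[, 3] / pops
  age_offset <- config$age_effect *
    (old_share - mean(old_share)) / max(stats::sd(old_share), 1e-12)

  # topics: non-negative random walks around per-topic prevalences with
  # county-specific preferences; yearly drift is a substantial share of
  # the loading scale, as with yearly topic prevalences, so the change
  # signal survives a variance-driven dimensionality reduction. Signal
  # topics vary more, keeping the planted directions among the dominant
  # ones.
  sig_idx <- with_substream(config$seed, "signal_topics",
                            sort(sample.int(K, config$n_signal_topics)))
  sds <- rep(config$topic_drift_sd, K)
  sds[sig_idx] <- sds[sig_idx] * config$signal_drift_multiplier
  topics <- with_substream(config$seed, "topics", {
    base <- stats::runif(K, 0.5, 2)
    # county preferences live on a low non-negative rank (latent language
    # "styles"), emulating the strong cross-topic correlation of LDA
    # loadings that makes a 20-dimensional NMF compression faithful;
    # idiosyncratic county-topic noise is small by comparison
    r <- 10L
    A <- matrix(stats::rexp(nC * r), nC)
    B <- matrix(stats::rexp(r * K) *
                  stats::rbinom(r * K, 1, 0.3), r)
    pref <- A %*% B
    pref <- pref * (0.5 / stats::sd(pref)) +
      matrix(abs(stats::rnorm(nC * K, 0, 0.1)), nC)
    arr <- array(0, c(nC, nY, K))
    arr[, 1, ] <- sweep(pref, 2, base, "+")
    for (j in 2:nY) {
      step <- matrix(stats::rnorm(nC * K), nC) *
        matrix(sds, nC, K, byrow = TRUE)
      arr[, j, ] <- pmax(arr[, j - 1, ] + step, 0)
    }
    arr
  })

  # outcome change process; signal enters through lagged topic changes
  # scaled by their generation SD, so the per-topic raw coefficient is
  # language_effect / sd_k (recorded in the ground truth)
  sig_coef <- if (config$n_signal_topics > 0)
    config$language_effect / sds[sig_idx] else numeric(0)
  proc <- with_substream(config$seed, "outcome", {
    drift <- stats::rnorm(nC, config$drift_mean, config$drift_sd)
    levels <- matrix(0, nC, nY)
    changes <- matrix(0, nC, nY)  # changes[, j] = level j - level j-1
    levels[, 1] <- stats::runif(nC, config$base_rate_range[1],
                                config$base_rate_range[2])
    for (j in 2:nY) {
      eps <- stats::rnorm(nC, 0, config$noise_sd)
      sig <- rep(0, nC)
      if (j >= 3 && length(sig_idx) > 0) {
        dT <- topics[, j - 1, sig_idx, drop = FALSE] -
          topics[, j - 2, sig_idx, drop = FALSE]
        sig <- drop(matrix(dT, nC) %*% sig_coef)
      }
      ar_part <- if (j >= 3) config$ar_coefficient *
        (changes[, j - 1] - drift) else 0
      changes[, j] <- drift + ar_part + sig + eps
      levels[, j] <- pmax(levels[, j - 1] + changes[, j], 0)
      changes[, j] <- levels[, j] - levels[, j - 1]
    }
    list(levels = levels, drift = drift)
  })
  rates <- pmax(proc$levels + age_offset, 0)
  dimnames(rates) <- list(counties, years)

  ses_arr <- NULL
  if (isTRUE(config$ses)) {
    ses_arr <- with_substream(config$seed, "ses", {
      base <- cbind(10.5 + 0.30 * u, 38 + 2.5 * u,
                    pmin(pmax(15 + 3 * u, 2), 40),
                    pmin(pmax(50 + stats::rnorm(nC, 0, 1), 40), 60),
                    pmin(pmax(10 + 8 * abs(stats::rnorm(nC)), 0), 90),
                    pmin(pmax(85 + 3 * u, 40), 100),
                    pmin(pmax(28 + 6 * u, 2), 90))
      arr <- array(0, c(nC, nY, 7),
                   dimnames = list(counties, years, ses_columns))
      arr[, 1, ] <- base
      for (j in 2:nY)
        arr[, j, ] <- arr[, j - 1, ] +
          matrix(stats::rnorm(nC * 7, 0, 0.05), nC)
      arr[, , 3:7] <- pmin(pmax(arr[, , 3:7], 0), 100)
      arr
    })
  }

  observed <- with_substream(config$seed, "missing", {
    obs <- matrix(TRUE, nC, nY, dimnames = list(counties, years))
    n_miss <- pmin(stats::rbinom(nC, nY, config$missing_rate), 2L)
    for (i in which(n_miss > 0))
      obs[i, sample.int(nY, n_miss[i])] <- FALSE
    obs
  })

  terc_arr <- array(rep(terc, nY), c(nC, 3, nY))
  terc_arr <- aperm(terc_arr, c(1, 3, 2))
  dimnames(terc_arr) <- list(counties, years, c("t1", "t2", "t3"))
  pop_mat <- matrix(pops, nC, nY, dimnames = list(counties, years))
  dimnames(topics) <- list(counties, years,
                           sprintf("t%04d", seq_len(K) - 1))

  panel <- new_county_panel(counties, years, rates, topics, ses_arr,
                            observed, population = pop_mat,
                            terciles = terc_arr,
                            meta = list(sim_seed = config$seed))
  truth <- list(signal_topics = sig_idx - 1L, signal_coefs = sig_coef,
                language_effect = config$language_effect,
                ar_coefficient = config$ar_coefficient,
                drift = proc$drift, age_offset = age_offset,
                latent_levels = proc$levels)
  list(panel = panel, truth = truth)
}

#' Generate a null panel (no language signal)
#'
#' As [generate_panel()] with \code{language_effect = 0}: topics carry
#' no information about the outcome; used for false-discovery and
#' paired-test calibration.
#'
#' @param config A [sim_config()].
#' @return A \code{county_panel}.
#' @export
generate_null_panel <- function(config) {
  config$language_effect <- 0
  generate_panel(config)$panel
}

#' Write a panel in the package's three CSV dialects
#'
#' Emits \code{<prefix>_mortality.csv}, \code{<prefix>_topics.csv} and,
#' when present, \code{<prefix>_ses.csv} into \code{dir}, in the exact
#' schemas the readers expect, so the full pipeline runs unchanged on
#' synthetic data. Unobserved topic cells are written as absent rows.
#'
#' @param panel A \code{county_panel}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "panel").
#' @return Named vector of written paths.
#' @export
write_panel_csvs <- function(panel, dir, prefix = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nC <- length(panel$counties); nY <- length(panel$years)
  mort <- data.frame(
    fips = rep(panel$counties, nY),
    year = rep(panel$years, each = nC),
    population = as.vector(panel$population %||%
                             matrix(1e5, nC, nY)),
    crude_rate = as.vector(panel$rates),
    pop_t1 = as.vector(panel$terciles[, , 1]),
    pop_t2 = as.vector(panel$terciles[, , 2]),
    pop_t3 = as.vector(panel$terciles[, , 3]))
  paths <- c(mortality = file.path(dir, paste0(prefix, "_mortality.csv")))
  utils::write.csv(mort, paths["mortality"], row.names = FALSE,
                   quote = FALSE)

  K <- dim(panel$topics)[3]
  obs_idx <- which(panel$topic_observed, arr.ind = TRUE)
  tdf <- data.frame(fips = panel$counties[obs_idx[, 1]],
                    year = panel$years[obs_idx[, 2]])
  tmat <- t(vapply(seq_len(nrow(obs_idx)), function(r)
    panel$topics[obs_idx[r, 1], obs_idx[r, 2], ], numeric(K)))
  colnames(tmat) <- sprintf("t%04d", seq_len(K) - 1)
  paths["topics"] <- file.path(dir, paste0(prefix, "_topics.csv"))
  utils::write.csv(cbind(tdf, tmat), paths["topics"], row.names = FALSE,
                   quote = FALSE)

  if (!is.null(panel$ses)) {
    sdf <- data.frame(fips = rep(panel$counties, nY),
                      year = rep(panel$years, each = nC))
    smat <- matrix(panel$ses, nC * nY, 7)
    colnames(smat) <- ses_columns
    paths["ses"] <- file.path(dir, paste0(prefix, "_ses.csv"))
    utils::write.csv(cbind(sdf, smat), paths["ses"], row.names = FALSE,
                     quote = FALSE)
  }
  paths
}
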