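#' Configuration for the synthetic tissue-microarray cohort
#'
#' Per-patient AR and CDK11 staining categories are produced by thresholding
#' a latent bivariate standard normal with correlation \code{rhoLatent} at
#' five ordered cutpoints (probit-style), giving the ordinal categories
#' 0--5.  Event times are exponential with hazard
#' \code{baselineHazard * hazardRatioHigh^I(AR-high)}, where AR-high means
#' staining category >= 3; censoring times are exponential with rate
#' \code{censorRate}; follow-up is the minimum of the two.
#'
#' The default cutpoints place the marginal category frequencies at the
#' distribution observed in the evaluable osteosarcoma TMA specimens
#' (5, 24, 22, 19, 15, 2 out of 87); covariate mixes follow the cohort
#' table (62\% male, grades roughly 13/46/40\%, 67\% metastatic, 30\%
#' recurrent, chemotherapy response good/poor/unknown 13/55/32\%).
#'
#' @param nPatients cohort size.
#' @param rhoLatent latent correlation of the AR and CDK11 scores, in
#'   \eqn{[-1, 1]}.
#' @param categoryThresholds five strictly increasing latent cutpoints
#'   mapping to staining categories 0--5.
#' @param hazardRatioHigh multiplicative hazard for AR-high vs AR-low.
#' @param baselineHazard events per month for AR-low patients.
#' @param censorRate censoring hazard (per month); 0 disables censoring.
#' @param covariateMixes named list of marginal frequencies for
#'   \code{gender}, \code{grade}, \code{metastasis}, \code{recurrence},
#'   \code{chemo_response}; each must sum to 1.
#' @param seed RNG seed.
#' @return A validated list of class \code{CohortSimConfig}.
#' @seealso [simulateTMACohort()]
#' @export
cohortSimConfig <- function(nPatients = 87L, rhoLatent = 0.8,
                            categoryThresholds = c(-1.575, -0.431, 0.218,
                                                   0.859, 1.995),
                            hazardRatioHigh = 2.5, baselineHazard = 0.012,
                            censorRate = 0.01,
                            covariateMixes = list(
                              gender = c(male = 0.62, female = 0.38),
                              grade = c(`1` = 0.13, `2` = 0.47, `3` = 0.40),
                              metastasis = c(absent = 0.33, present = 0.67),
                              recurrence = c(absent = 0.70, present = 0.30),
                              chemo_response = c(good = 0.13, poor = 0.55,
                                                 na = 0.32)),
                            seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), rhoLatent = rhoLatent,
              categoryThresholds = categoryThresholds,
              hazardRatioHigh = hazardRatioHigh,
              baselineHazard = baselineHazard, censorRate = censorRate,
              covariateMixes = covariateMixes, seed = as.integer(seed))
  class(cfg) <- "CohortSimConfig"
  .validateCohortSimConfig(cfg)
  cfg
}

.validateCohortSimConfig <- function(cfg) {
  with(cfg, {
    if (nPatients < 1) .cfgStop("nPatients", "must be >= 1")
    if (abs(rhoLatent) > 1) .cfgStop("rhoLatent", "must lie in [-1, 1]")
    if (length(categoryThresholds) != 5 ||
        any(diff(categoryThresholds) <= 0))
      .cfgStop("categoryThresholds",
               "must be 5 strictly increasing cutpoints")
    if (hazardRatioHigh <= 0) .cfgStop("hazardRatioHigh", "must be > 0")
    if (baselineHazard <= 0) .cfgStop("baselineHazard", "must be > 0")
    if (censorRate < 0) .cfgStop("censorRate", "must be >= 0")
    for (nm in names(covariateMixes))
      if (abs(sum(covariateMixes[[nm]]) - 1) > 1e-6)
        .cfgStop(paste0("covariateMixes$", nm), "frequencies must sum to 1")
  })
  invisible(cfg)
}

#' Simulate a TMA cohort with correlated staining and a planted hazard ratio
#'
#' @param cfg a \code{CohortSimConfig}; see [cohortSimConfig()] for the
#'   generative model.
#' @return A list with \code{cohort} (data.frame: \code{patient_id},
#'   \code{ar_category}, \code{cdk11_category}, \code{age_years},
#'   \code{gender}, \code{grade}, \code{metastasis}, \code{recurrence},
#'   \code{chemo_response}, \code{followup_months}, \code{event}) and
#'   \code{truth} (planted correlation, hazard ratio, thresholds).
#' @examples
#' sim <- simulateTMACohort(cohortSimConfig(nPatients = 50, seed = 3))
#' head(sim$cohort)
#' @export
simulateTMACohort <- function(cfg = cohortSimConfig()) {
  .validateCohortSimConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$nPatients
  rho <- cfg$rhoLatent

  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  arCat <- findInterval(z1, cfg$categoryThresholds)
  cdkCat <- findInterval(z2, cfg$categoryThresholds)

  arHigh <- arCat >= 3
  hz <- cfg$baselineHazard * ifelse(arHigh, cfg$hazardRatioHigh, 1)
  eventTime <- rexp(n, hz)
  censorTime <- if (cfg$censorRate > 0) rexp(n, cfg$censorRate) else
    rep(Inf, n)
  followup <- pmin(eventTime, censorTime)
  event <- eventTime <= censorTime

  mixes <- cfg$covariateMixes
  drawMix <- function(m) sample(names(m), n, replace = TRUE, prob = m)
  cohort <- data.frame(
    patient_id = sprintf("PT%03d", seq_len(n)),
    ar_category = arCat, cdk11_category = cdkCat,
    age_years = pmin(pmax(round(rlnorm(n, log(28), 0.45)), 6L), 72L),
    gender = drawMix(mixes$gender),
    grade = as.integer(drawMix(mixes$grade)),
    metastasis = drawMix(mixes$metastasis) == "present",
    recurrence = drawMix(mixes$recurrence) == "present",
    chemo_response = drawMix(mixes$chemo_response),
    followup_months = followup, event = event)
  cohort$chemo_response[cohort$chemo_response == "na"] <- NA

  list(cohort = cohort,
       truth = list(rhoLatent = rho, hazardRatioHigh = cfg$hazardRatioHigh,
                    categoryThresholds = cfg$categoryThresholds,
                    config = cfg))
}
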