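#' Specification for a simulated ablation cohort
#'
#' Default covariate distributions reproduce the published summary
#' statistics of a large single-centre de-novo ablation cohort
#' (n = 2223): binary prevalences for the comorbidities, and
#' median/inter-quartile ranges (simulated as log-normal) for the
#' continuous measurements. The latent wall stress follows an additive
#' linear model on the 10^3 dyn/cm^2 scale whose coefficients are the
#' published multivariate association estimates; peak LA pressure is
#' then derived so that the Law of Laplace holds row-wise. Recurrence
#' times are exponential proportional hazards with a configurable
#' hazard-ratio for top-quartile stress, administratively censored.
#'
#' @param n number of patients.
#' @param prevalence named prevalences of the binary covariates.
#' @param continuous named list of `c(median, q1, q3)` triplets for the
#'   log-normally simulated continuous covariates.
#' @param stressCoef named coefficients (10^3 dyn/cm^2 per unit) linking
#'   covariates to latent stress; names must be covariate columns.
#' @param stressIntercept intercept of the latent stress model
#'   (10^3 dyn/cm^2).
#' @param stressNoiseSD additive Gaussian noise SD (10^3 dyn/cm^2).
#' @param baselineHazard exponential event rate per month for a
#'   reference (non-Q4, paroxysmal) patient, after blanking.
#' @param logHrQ4 log hazard ratio of top-quartile stress membership.
#' @param logHrCovariates named log hazard ratios for additional
#'   covariate effects on recurrence.
#' @param censorWindow administrative censoring window, months after
#'   blanking.
#' @param blanking blanking period in months (recurrence inside it is
#'   not the endpoint).
#' @param blankingRule `"regenerate"` redraws endpoint events to occur
#'   after blanking (memoryless); `"censor"` censors patients whose
#'   first event fell inside the blanking period at time 0.
#' @param correlation optional correlation matrix (Gaussian copula)
#'   among the continuous covariates, in the order of `continuous`.
#' @param missingRate optional MCAR missingness rate applied to peak LA
#'   pressure (the invasive measurement).
#' @return A list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(n = 2223,
                       prevalence = c(non_paroxysmal_af = 0.287,
                                      male_sex = 0.728,
                                      hypertension = 0.471,
                                      diabetes = 0.149,
                                      stroke_tia = 0.112,
                                      vascular_disease = 0.112,
                                      heart_failure = 0.118),
                       continuous = list(
                         age = c(59, 52, 67),
                         bmi = c(24.7, 23.0, 26.7),
                         lvef = c(64, 59, 68),
                         e_em = c(9.0, 7.2, 12.0),
                         la_diameter_mm = c(41, 37, 45),
                         la_wall_thickness_mm = c(1.95, 1.75, 2.15),
                         la_voltage_mv = c(1.33, 0.84, 1.83)),
                       stressCoef = c(non_paroxysmal_af = 31.08,
                                      bmi = 2.91,
                                      diabetes = 15.36,
                                      vascular_disease = 22.27,
                                      e_em = 4.95,
                                      la_voltage_mv = -22.24),
                       stressIntercept = 41,
                       stressNoiseSD = 70,
                       baselineHazard = 0.011,
                       logHrQ4 = log(2.43),
                       logHrCovariates = c(non_paroxysmal_af = log(1.61)),
                       censorWindow = 72,
                       blanking = 3,
                       blankingRule = c("regenerate", "censor"),
                       correlation = NULL,
                       missingRate = 0) {
  blankingRule <- match.arg(blankingRule)
  if (n < 8) stop("n must be at least 8")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalences must lie in (0, 1)")
  if (!all(is.finite(stressCoef)))
    stop("stress coefficients must be finite")
  if (baselineHazard <= 0) stop("baseline hazard must be positive")
  if (censorWindow <= blanking)
    stop("censoring window must exceed the blanking period")
  if (!is.null(correlation)) {
    k <- length(continuous)
    if (!is.matrix(correlation) || any(dim(correlation) != k))
      stop("correlation must be a ", k, " x ", k, " matrix")
  }
  structure(as.list(environment()), class = "cohortSpec")
}

lnormFromQuartiles <- function(med, q1, q3) {
  c(meanlog = log(med), sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Simulate an ablation cohort
#'
#' Draws covariates, latent wall stress, quartile labels and
#' post-blanking recurrence outcomes according to a [cohortSpec()].
#' Peak LA pressure is back-computed from the latent stress so that
#' `lawStress(pressure, diameter, thickness)` reproduces the stored
#' `stress_dyn_cm2` column exactly.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed; output is bitwise reproducible given the
#'   seed and spec.
#' @return A data.frame with one row per patient: the binary and
#'   continuous covariates, `peak_la_pressure_mmhg`, `stress_dyn_cm2`,
#'   `stress_quartile` (factor Q1-Q4), `early_recurrence`,
#'   `follow_up_months` (from end of blanking) and `recurrence`.
#' @examples
#' co <- simulateCohort(cohortSpec(n = 200), seed = 7)
#' table(co$stress_quartile)
#' @export
simulateCohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(as.integer(seed))
  n <- spec$n

  df <- data.frame(id = seq_len(n))
  for (nm in names(spec$prevalence))
    df[[nm]] <- rbinom(n, 1L, spec$prevalence[[nm]])

  k <- length(spec$continuous)
  if (is.null(spec$correlation)) {
    z <- matrix(rnorm(n * k), n, k)
  } else {
    z <- matrix(rnorm(n * k), n, k) %*% chol(spec$correlation)
  }
  for (i in seq_len(k)) {
    q <- spec$continuous[[i]]
    p <- lnormFromQuartiles(q[1], q[2], q[3])
    df[[names(spec$continuous)[i]]] <- exp(p["meanlog"] + p["sdlog"] * z[, i])
  }

  # latent stress (10^3 dyn/cm^2): linear predictor + noise
  lp <- spec$stressIntercept
  for (nm in names(spec$stressCoef)) {
    if (is.null(df[[nm]])) stop("stress coefficient names unknown: ", nm)
    lp <- lp + spec$stressCoef[[nm]] * df[[nm]]
  }
  stress3 <- lp + rnorm(n, sd = spec$stressNoiseSD)
  stress3 <- pmax(stress3, 5)   # keep stress physical
  df$stress_dyn_cm2 <- stress3 * 1e3

  # pressure consistent with the Law of Laplace, sigma = 1333.22 P D / (4 h)
  df$peak_la_pressure_mmhg <- df$stress_dyn_cm2 * 4 *
    df$la_wall_thickness_mm / (MMHG_TO_DYN_CM2 * df$la_diameter_mm)

  qp <- quartilePartition(df$stress_dyn_cm2)
  df$stress_quartile <- qp$labels
  isQ4 <- as.integer(df$stress_quartile == "Q4")

  loghr <- spec$logHrQ4 * isQ4
  for (nm in names(spec$logHrCovariates))
    loghr <- loghr + spec$logHrCovariates[[nm]] * df[[nm]]
  rate <- spec$baselineHazard * exp(loghr)

  tRaw <- rexp(n, rate)                     # first event, from ablation
  df$early_recurrence <- as.integer(tRaw < spec$blanking)
  if (spec$blankingRule == "regenerate") {
    # memoryless: endpoint event time after blanking is a fresh draw
    tPost <- rexp(n, rate)
  } else {
    tPost <- rexp(n, rate)
    tPost[df$early_recurrence == 1L] <- 0
  }
  cens <- runif(n, 0, spec$censorWindow - spec$blanking)
  if (spec$blankingRule == "censor") {
    df$recurrence <- as.integer(tPost < cens & df$early_recurrence == 0L)
    df$follow_up_months <- ifelse(df$early_recurrence == 1L, 0,
                                  pmin(tPost, cens))
  } else {
    df$recurrence <- as.integer(tPost < cens)
    df$follow_up_months <- pmin(tPost, cens)
  }

  if (spec$missingRate > 0) {
    mis <- runif(n) < spec$missingRate
    df$peak_la_pressure_mmhg[mis] <- NA_real_
  }
  df
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a cohort data.frame as produced by [simulateCohort()].
#' @param path CSV file path.
#' @return `readCohort` returns the data.frame with the quartile column
#'   restored as a factor.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- read.csv(path)
  if (!is.null(df$stress_quartile))
    df$stress_quartile <- factor(df$stress_quartile,
                                 levels = c("Q1", "Q2", "Q3", "Q4"))
  df
}
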