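#' Run the phantom validation study
#'
#' Generates shell phantoms across a resolution ladder, runs the full
#' measurement chain (segmentation, Laplace solve, streamline tracing)
#' on each, and reports the measured mean thickness against the
#' analytic truth. Deterministic given the seed.
#'
#' @param shapes phantom shapes to include.
#' @param resolutions isotropic voxel sizes in mm, coarse to fine.
#' @param noiseSD intensity noise SD (HU-like units; class gap is 100).
#' @param rInner,rOuter,offset,slabGap phantom geometry, mm.
#' @param seed master seed (fanned out per stage).
#' @param tol,maxIter Laplace solver settings.
#' @param outDir optional directory; when given, the report table is
#'   written as CSV and the summary as JSON.
#' @return list of class `"phantomStudy"`: `table` (one row per shape x
#'   resolution: true and measured mean thickness, relative error, wall
#'   Dice, solver iterations and residual, flagged fraction), `seed`,
#'   `configHash`.
#' @export
runPhantomStudy <- function(shapes = c("slab", "concentric", "eccentric"),
                            resolutions = c(0.5, 0.25),
                            noiseSD = 5, rInner = 10, rOuter = 12,
                            offset = 1, slabGap = 3, seed = 1L,
                            tol = 1e-6, maxIter = 10000L, outDir = NULL) {
  cfg <- list(shapes = shapes, resolutions = resolutions, noiseSD = noiseSD,
              rInner = rInner, rOuter = rOuter, offset = offset,
              slabGap = slabGap, tol = tol, maxIter = maxIter)
  rows <- list()
  counter <- 0L
  for (shape in shapes) for (res in resolutions) {
    counter <- counter + 1L
    ph <- shellPhantom(shape, rInner = rInner, rOuter = rOuter,
                       offset = offset, slabGap = slabGap,
                       spacing = rep(res, 3), noiseSD = noiseSD,
                       seed = stageSeed(seed, counter))
    mask <- segmentWall(ph$volume)
    dice <- diceCoefficient(wallLabels(mask) == 2L,
                            wallLabels(ph$mask) == 2L)
    field <- solveLaplace(mask, tol = tol, maxIter = maxIter)
    th <- thicknessMap(field)
    rows[[counter]] <- data.frame(
      shape = shape, spacing_mm = res,
      trueMean_mm = ph$meanThickness,
      measuredMean_mm = meanThickness(th),
      relError = abs(meanThickness(th) - ph$meanThickness) /
        ph$meanThickness,
      dice = dice,
      iterations = solverIterations(field),
      residual = solverResidual(field),
      flaggedFraction = th@diagnostics$flaggedFraction)
  }
  report <- structure(list(table = do.call(rbind, rows), seed = seed,
                           configHash = configHash(cfg), config = cfg),
                      class = "phantomStudy")
  if (!is.null(outDir)) writeReport(report, outDir, "phantom_study")
  report
}

#' @exportS3Method base::print
print.phantomStudy <- function(x, ...) {
  cat(sprintf("Phantom thickness study (seed %d, config %s)\n",
              x$seed, x$configHash))
  print(transform(x$table, trueMean_mm = round(trueMean_mm, 3),
                  measuredMean_mm = round(measuredMean_mm, 3),
                  relError = round(relError, 4), dice = round(dice, 4),
                  residual = signif(residual, 3)), row.names = FALSE)
  invisible(x)
}

#' Run the cohort outcome study
#'
#' End-to-end synthetic-cohort analysis: computes wall stress from
#' pressure, diameter and thickness via the Law of Laplace, stratifies
#' into quartiles, trains and evaluates the top-quartile classifier
#' over `repeats` split/train cycles, and analyses recurrence with
#' Kaplan-Meier curves, a log-rank test across quartiles, and Cox
#' models for top-quartile membership (univariate screen then
#' multivariate). Stage failures at degenerate sample sizes are
#' downgraded to warnings and recorded in the report.
#'
#' @param cohort a cohort data.frame (see [simulateCohort()]) or NULL
#'   to simulate one from `spec`.
#' @param spec a [cohortSpec()] used when `cohort` is NULL.
#' @param repeats classifier repeats (default 5).
#' @param config a [trainConfig()].
#' @param seed master seed.
#' @param candidates Cox candidate covariates (screened univariately at
#'   p < 0.05).
#' @param outDir optional output directory for CSV/JSON artifacts.
#' @return list of class `"cohortStudy"` with elements `cutoffs`,
#'   `quartileSizes`, `classifier` (a `"repeatEval"` or NULL),
#'   `logistic`, `km`, `logrank`, `cox`, `linreg`, `failures`, `seed`,
#'   `configHash`.
#' @export
runCohortStudy <- function(cohort = NULL, spec = cohortSpec(),
                           repeats = 5L, config = trainConfig(),
                           seed = 1L,
                           candidates = c("q4_stress", "non_paroxysmal_af",
                                          "age", "hypertension", "diabetes",
                                          "heart_failure", "lvef"),
                           outDir = NULL) {
  cfg <- list(spec = if (is.null(cohort)) unclass(spec) else "external",
              repeats = repeats, config = unclass(config),
              candidates = candidates)
  if (is.null(cohort)) cohort <- simulateCohort(spec, seed = stageSeed(seed, 1L))
  need <- c("peak_la_pressure_mmhg", "la_diameter_mm",
            "la_wall_thickness_mm", "follow_up_months", "recurrence")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort schema mismatch, missing column(s): ",
         paste(miss, collapse = ", "))
  failures <- character()

  cohort <- cohortStress(cohort)
  cohort$q4_stress <- as.integer(cohort$stress_quartile == "Q4")

  classifier <- NULL
  withCallingHandlers(
    classifier <- tryCatch(
      repeatAndSelect(classifierFeatures(cohort), cohort$q4_stress,
                      k = repeats, config = config,
                      seed = stageSeed(seed, 2L)),
      error = function(e) {
        warning("classifier stage failed: ", conditionMessage(e))
        NULL
      }),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(classifier)) failures <- c(failures, "classifier")

  logistic <- tryCatch(
    fitLogistic(classifierFeatures(cohort), cohort$q4_stress),
    error = function(e) {
      warning("logistic stage failed: ", conditionMessage(e)); NULL
    })

  km <- kmCurve(cohort$follow_up_months, cohort$recurrence,
                cohort$stress_quartile)
  lr <- tryCatch(
    logrankTest(cohort$follow_up_months, cohort$recurrence,
                cohort$stress_quartile),
    error = function(e) {
      warning("log-rank stage failed: ", conditionMessage(e)); NULL
    })
  if (is.null(lr)) failures <- c(failures, "logrank")

  cand <- intersect(candidates, names(cohort))
  cox <- tryCatch(
    suppressWarnings(selectThenMultivariate(cohort, cand, model = "cox")),
    error = function(e) {
      warning("Cox stage failed: ", conditionMessage(e)); NULL
    })
  if (is.null(cox)) failures <- c(failures, "cox")

  linCand <- intersect(c("non_paroxysmal_af", "age", "hypertension",
                         "diabetes", "stroke_tia", "vascular_disease",
                         "heart_failure", "bmi", "lvef", "e_em",
                         "la_voltage_mv"), names(cohort))
  linreg <- tryCatch(
    selectThenMultivariate(cohort, linCand, model = "linear"),
    error = function(e) {
      warning("linear-association stage failed: ", conditionMessage(e)); NULL
    })

  report <- structure(list(
    cutoffs = attr(cohort, "cutoffs"),
    quartileSizes = table(cohort$stress_quartile),
    classifier = classifier, logistic = logistic,
    km = km, logrank = lr, cox = cox, linreg = linreg,
    n = nrow(cohort), failures = failures,
    seed = seed, configHash = configHash(cfg)),
    class = "cohortStudy")
  if (!is.null(outDir)) writeReport(report, outDir, "cohort_study")
  report
}

#' @exportS3Method base::print
print.cohortStudy <- function(x, ...) {
  cat(sprintf("Cohort study, n = %d (seed %d, config %s)\n", x$n, x$seed,
              x$configHash))
  cat("Stress quartile cutoffs (10^3 dyn/cm^2):",
      paste(round(x$cutoffs / 1e3, 1), collapse = " / "), "\n")
  if (!is.null(x$classifier))
    cat(sprintf("Classifier: mean test AUC %.3f over %d repeats\n",
                x$classifier$means["testAUC"], x$classifier$k))
  if (!is.null(x$logrank))
    cat(sprintf("Log-rank across quartiles: p = %.4g\n", x$logrank$p.value))
  if (!is.null(x$cox) && !is.null(x$cox$multivariate)) {
    q4 <- subset(x$cox$multivariate$table, covariate == "q4_stress")
    if (nrow(q4))
      cat(sprintf("Q4 stress multivariate HR %.2f (%.2f-%.2f), p = %.4g\n",
                  q4$hr, q4$lower95, q4$upper95, q4$p))
  }
  if (length(x$failures))
    cat("Failed stages:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}

# write a study report's tables to outDir as CSV + JSON summary with
# provenance (seed, config hash)
writeReport <- function(report, outDir, prefix) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  prov <- list(seed = report$seed, configHash = report$configHash)
  if (inherits(report, "phantomStudy")) {
    write.csv(cbind(report$table, seed = report$seed,
                    configHash = report$configHash),
              file.path(outDir, paste0(prefix, ".csv")), row.names = FALSE)
    jsonlite::write_json(c(prov, list(table = report$table)),
                         file.path(outDir, paste0(prefix, ".json")),
                         auto_unbox = TRUE, digits = NA)
  } else {
    summary <- c(prov, list(
      n = report$n,
      cutoffs_dyn_cm2 = as.numeric(report$cutoffs),
      quartileSizes = as.numeric(report$quartileSizes),
      logrank_p = if (!is.null(report$logrank)) report$logrank$p.value,
      classifier_mean_test_auc = if (!is.null(report$classifier))
        as.numeric(report$classifier$means["testAUC"]),
      failures = report$failures))
    jsonlite::write_json(summary,
                         file.path(outDir, paste0(prefix, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(report$classifier))
      write.csv(report$classifier$perRepeat,
                file.path(outDir, paste0(prefix, "_classifier.csv")),
                row.names = FALSE)
  }
  invisible(outDir)
}
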