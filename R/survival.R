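#' Kaplan-Meier curve of arrhythmia-free survival
#'
#' Product-limit estimate of freedom from recurrence, with time
#' measured in months from the end of the blanking period. Censoring at
#' tied times is handled after events (the product-limit convention).
#'
#' @param time follow-up in months (>= 0).
#' @param event 0/1 recurrence indicator.
#' @param group optional group factor; one curve per level.
#' @return list of class `"kmCurve"`: data.frame `curve` with columns
#'   `group`, `time`, `nRisk`, `nEvent`, `nCensor`, `surv`, and the
#'   underlying `survival::survfit` object.
#' @export
kmCurve <- function(time, event, group = NULL) {
  if (any(time < 0, na.rm = TRUE)) stop("negative follow-up times")
  if (!all(event %in% 0:1)) stop("event flag must be 0/1")
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    grp <- factor(rep("all", length(fit$time)))
  } else {
    df$group <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    grp <- if (is.null(fit$strata)) factor(rep(levels(df$group)[1],
                                               length(fit$time)))
           else factor(rep(sub("^group=", "", names(fit$strata)),
                           fit$strata))
  }
  curve <- data.frame(group = grp, time = fit$time, nRisk = fit$n.risk,
                      nEvent = fit$n.event, nCensor = fit$n.censor,
                      surv = fit$surv)
  structure(list(curve = curve, fit = fit), class = "kmCurve")
}

#' @exportS3Method base::print
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve(s):\n")
  print(head(x$curve, 10), row.names = FALSE)
  if (nrow(x$curve) > 10) cat("  ...", nrow(x$curve), "rows\n")
  invisible(x)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected chi-square statistic over the
#' pooled event times; supports k groups (e.g. the four stress
#' quartiles).
#'
#' @param time,event follow-up months and 0/1 recurrence flag.
#' @param group group labels (>= 2 non-empty levels).
#' @return list of class `"logrankTest"`: `statistic`, `df`, `p.value`,
#'   and the per-group observed/expected table.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (sum(event) < 1) stop("no events observed")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n)
  stat <- sd$chisq
  structure(list(statistic = stat, df = k - 1,
                 p.value = pchisq(stat, k - 1, lower.tail = FALSE),
                 table = data.frame(group = levels(group), n = as.numeric(sd$n),
                                    observed = sd$obs, expected = sd$exp)),
            class = "logrankTest")
}

#' @exportS3Method base::print
print.logrankTest <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with the Efron approximation for tied event
#' times. Hazard ratios with Wald 95% confidence intervals and Wald
#' p-values, matching the HR (CI) reporting style of clinical tables.
#'
#' @param data data.frame holding time, event and covariates.
#' @param covariates character vector of covariate column names.
#' @param timeCol,eventCol column names of follow-up and event flag.
#' @return list of class `"coxFit"`: `table` (covariate, HR, lower95,
#'   upper95, p), `logLik`, `n`, `nEvents`, `ties = "efron"`, and the
#'   `survival::coxph` object.
#' @export
coxFit <- function(data, covariates, timeCol = "follow_up_months",
                   eventCol = "recurrence") {
  stopifnot(length(covariates) >= 1)
  miss <- setdiff(c(covariates, timeCol, eventCol), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.numeric(v) && var(v, na.rm = TRUE) == 0)
      stop("zero-variance covariate: ", cv)
  }
  nev <- sum(data[[eventCol]])
  if (nev < 10 * length(covariates))
    warning(sprintf("only %d events for %d covariates (< 10 per covariate)",
                    nev, length(covariates)))
  fml <- as.formula(paste0("survival::Surv(", timeCol, ", ", eventCol,
                           ") ~ ", paste(covariates, collapse = " + ")))
  sepMsg <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Loglik converged at beta",
                conditionMessage(w))) {
        sepMsg <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(sepMsg))
    stop("monotone likelihood (perfect separation): Cox fit did not converge")
  s <- summary(fit)
  tab <- data.frame(covariate = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower95 = s$conf.int[, "lower .95"],
                    upper95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, logLik = as.numeric(logLik(fit)),
                 n = s$n, nEvents = s$nevent, ties = "efron", fit = fit),
            class = "coxFit")
}

#' @importFrom stats logLik fitted model.matrix
NULL

#' @exportS3Method base::print
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties), %d subjects / %d events:\n",
              x$n, x$nEvents))
  print(transform(x$table, hr = round(hr, 3), lower95 = round(lower95, 3),
                  upper95 = round(upper95, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Univariate screening then multivariate fit
#'
#' Implements the published selection rule: every candidate covariate
#' is fitted univariately, and those with p < `alpha` (default 0.05)
#' enter a joint multivariate model. Both stages are reported. Works
#' for Cox recurrence models and for linear stress-association models.
#'
#' @param data data.frame with outcome and covariates.
#' @param candidates character vector of candidate covariates.
#' @param model `"cox"` (outcome = time/event columns) or `"linear"`
#'   (outcome = `responseCol`).
#' @param alpha univariate inclusion threshold.
#' @param timeCol,eventCol,responseCol outcome columns.
#' @return list of class `"selectFit"`: `univariate` (data.frame with
#'   estimate, CI, p per candidate), `selected` (character), and
#'   `multivariate` (a `"coxFit"`/`"linregFit"`, or NULL when nothing
#'   passes).
#' @export
selectThenMultivariate <- function(data, candidates,
                                   model = c("cox", "linear"),
                                   alpha = 0.05,
                                   timeCol = "follow_up_months",
                                   eventCol = "recurrence",
                                   responseCol = "stress_dyn_cm2") {
  model <- match.arg(model)
  stopifnot(length(candidates) >= 1)
  uni <- lapply(candidates, function(cv) {
    if (model == "cox") {
      f <- coxFit(data, cv, timeCol, eventCol)
      cbind(f$table, stage = "univariate")
    } else {
      f <- linregFit(data, cv, responseCol)
      cbind(f$table, stage = "univariate")
    }
  })
  uni <- do.call(rbind, uni)
  selected <- candidates[uni$p < alpha]
  multi <- NULL
  if (length(selected)) {
    multi <- if (model == "cox") coxFit(data, selected, timeCol, eventCol)
             else linregFit(data, selected, responseCol)
  }
  structure(list(univariate = uni, selected = selected,
                 multivariate = multi, alpha = alpha, model = model),
            class = "selectFit")
}

#' Linear regression of wall stress on clinical covariates
#'
#' Ordinary least squares of the response (reported on the
#' 10^3 dyn/cm^2 scale when the response column is in dyn/cm^2) on one
#' or more covariates, with Wald 95% confidence intervals.
#'
#' @param data data.frame.
#' @param covariates covariate column names (one = univariate mode).
#' @param responseCol response column; values in dyn/cm^2 are divided
#'   by 1000 when `rescale = TRUE`.
#' @param rescale divide the response by 1000 (report per
#'   10^3 dyn/cm^2).
#' @return list of class `"linregFit"`: `table` (covariate, beta,
#'   lower95, upper95, p) and the `lm` object. Exact collinearity is an
#'   error naming the dependent columns.
#' @export
linregFit <- function(data, covariates, responseCol = "stress_dyn_cm2",
                      rescale = TRUE) {
  miss <- setdiff(c(covariates, responseCol), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[responseCol]]
  if (rescale) y <- y / 1e3
  df <- data.frame(.y = y, data[covariates], check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  fml <- as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                        collapse = " + ")))
  mm <- stats::model.matrix(fml, df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dep <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("exact collinearity among covariates: ",
         paste(dep, collapse = ", "))
  }
  fit <- lm(fml, data = df)
  ci <- confint(fit)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  keep <- setdiff(names(cf), "(Intercept)")
  tab <- data.frame(covariate = gsub("`", "", keep),
                    beta = cf[keep],
                    lower95 = ci[keep, 1], upper95 = ci[keep, 2],
                    p = sm[keep, "Pr(>|t|)"], row.names = NULL)
  structure(list(table = tab, fit = fit, n = nrow(df)),
            class = "linregFit")
}

#' @exportS3Method base::print
print.linregFit <- function(x, ...) {
  cat(sprintf("Linear association model (n = %d, response 10^3 dyn/cm^2):\n",
              x$n))
  print(transform(x$table, beta = round(beta, 3),
                  lower95 = round(lower95, 3), upper95 = round(upper95, 3),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}
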