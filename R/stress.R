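#' @keywords internal
MMHG_TO_DYN_CM2 <- 1333.22

#' Convert pressure from mmHg to dyn/cm^2
#'
#' Uses the CGS conversion 1 mmHg = 1333.22 dyn/cm^2 (presented rounded
#' to 1333 in clinical use).
#'
#' @param p pressure in mmHg (vectorized).
#' @return pressure in dyn/cm^2.
#' @examples
#' round(mmHgToDynCm2(1))   # 1333
#' @export
mmHgToDynCm2 <- function(p) {
  stopifnot(is.numeric(p))
  p * MMHG_TO_DYN_CM2
}

#' Left atrial wall stress by the Law of Laplace
#'
#' For a thin-walled sphere the Law of Laplace gives
#' \eqn{\sigma = P r / (2 h)}. With the radius taken as half the
#' echocardiographic anterior-posterior diameter, \eqn{r = D/2}, this is
#' \deqn{\sigma = \frac{P \times D}{4 h} \times 1333.22 \ \mathrm{dyn/cm^2}}
#' for P in mmHg and D, h both in mm (their ratio is dimensionless).
#'
#' @param P peak left atrial pressure, mmHg (vectorized).
#' @param D left atrial anterior-posterior diameter, mm.
#' @param h mean left atrial wall thickness, mm.
#' @return wall stress in dyn/cm^2. Missing pressure yields NA (the
#'   record is excluded upstream, mirroring exclusion of patients
#'   without a sinus-rhythm pressure measurement).
#' @examples
#' round(lawStress(1, 40, 2))    # 6666
#' @export
lawStress <- function(P, D, h) {
  P <- as.numeric(P)
  if (any(D <= 0, na.rm = TRUE)) stop("diameter D must be positive")
  if (any(h <= 0, na.rm = TRUE)) stop("wall thickness h must be positive")
  if (any(P < 0, na.rm = TRUE)) stop("pressure P must be non-negative")
  mmHgToDynCm2(P) * D / (4 * h)
}

#' Partition cohort values into quartile groups
#'
#' Sorts the values ascending and places the group boundaries at the
#' round-half-up ranks \eqn{\lfloor k n/4 + 1/2 \rfloor} for
#' k = 1, 2, 3. Ties are assigned to the lower group deterministically
#' (by original order among tied values). For n = 2223 tie-free values
#' this yields group sizes 556/556/555/556.
#'
#' @param values numeric vector of (stress) values, length >= 4.
#' @return A list with `labels` (factor Q1-Q4 aligned with `values`),
#'   `cutoffs` (the three boundary values, ascending) and `sizes`
#'   (named group sizes).
#' @examples
#' quartilePartition(1:8)$sizes   # 2 2 2 2
#' @export
quartilePartition <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  if (length(unique(values[ok])) == 1L)
    stop("all values identical: quartile partition is degenerate")
  n <- sum(ok)
  bounds <- floor((1:3) * n / 4 + 0.5)   # round-half-up boundary ranks
  rk <- rank(values[ok], ties.method = "first")
  grp <- findInterval(rk, c(bounds + 0.5), left.open = FALSE) + 1L
  labels <- factor(rep(NA_character_, length(values)),
                   levels = c("Q1", "Q2", "Q3", "Q4"))
  labels[ok] <- paste0("Q", grp)
  srt <- sort(values[ok])
  cutoffs <- srt[bounds]
  if (any(diff(cutoffs) < 0)) stop("cutoffs are not increasing")
  list(labels = labels,
       cutoffs = cutoffs,
       sizes = table(labels))
}

#' Append wall stress and quartile columns to a cohort table
#'
#' Computes `stress_dyn_cm2 = lawStress(P, D, h)` from the pressure,
#' diameter and thickness columns and stratifies all records with a
#' valid stress into quartiles. Records with missing pressure are
#' excluded from the partition (their quartile is NA) and counted in
#' the attached exclusion report.
#'
#' @param cohort data.frame with columns `peak_la_pressure_mmhg`,
#'   `la_diameter_mm`, `la_wall_thickness_mm`.
#' @return the cohort with `stress_dyn_cm2` and `stress_quartile`
#'   columns replaced/appended; attribute `"cutoffs"` holds the quartile
#'   boundaries (dyn/cm^2) and `"excluded"` the number of records
#'   without a computable stress.
#' @export
cohortStress <- function(cohort) {
  need <- c("peak_la_pressure_mmhg", "la_diameter_mm", "la_wall_thickness_mm")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  sig <- lawStress(cohort$peak_la_pressure_mmhg,
                   cohort$la_diameter_mm,
                   cohort$la_wall_thickness_mm)
  qp <- quartilePartition(sig)
  cohort$stress_dyn_cm2 <- sig
  cohort$stress_quartile <- qp$labels
  attr(cohort, "cutoffs") <- qp$cutoffs
  attr(cohort, "excluded") <- sum(is.na(sig))
  cohort
}
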