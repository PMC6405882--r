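#' BMI-for-age reference table (LMS coefficients)
#'
#' Reads the bundled synthetic BMI-for-age LMS reference, or a user-supplied
#' table with the same layout. The LMS method parameterizes a reference
#' distribution at each age by a Box-Cox power (L), median (M, kg/m^2) and
#' coefficient of variation (S); see [bmi_zscore()].
#'
#' The bundled table (`inst/extdata/who_lms_synthetic.tsv`) is a *synthetic*
#' stand-in with the shape of the WHO BMI-for-age references (adiposity
#' rebound near age 5-6, rising median and increasing right skew through
#' adolescence) but not the official coefficients; its header records this
#' provenance. Supply `path` to use an official table (columns: `sex`
#' coded "M"/"F", `age_months`, `L`, `M`, `S`, tab- or comma-separated).
#'
#' @param path Optional path to an LMS table; default: the bundled table.
#' @return A data frame with columns `sex`, `age_months`, `L`, `M`, `S`.
#' @export
#' @examples
#' ref <- lms_reference()
#' range(ref$age_months)
lms_reference <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("lms", envir = .bmisim_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "who_lms_synthetic.tsv", package = "bmisim")
    ref <- .read_lms(path)
    assign("lms", ref, envir = .bmisim_cache)
    return(ref)
  }
  .read_lms(path)
}

.bmisim_cache <- new.env(parent = emptyenv())

.read_lms <- function(path) {
  ref <- utils::read.delim(path, comment.char = "#", sep = "",
                           stringsAsFactors = FALSE)
  need <- c("sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(ref)))
    stop("LMS table must have columns: ", paste(need, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop("LMS table: M and S must be positive")
  for (sx in unique(ref$sex)) {
    a <- ref$age_months[ref$sex == sx]
    if (is.unsorted(a, strictly = TRUE))
      stop("LMS table: age_months must be strictly increasing within sex ", sx)
  }
  ref
}

#' Convert age in years to reference age in months
#'
#' Whole-year ages are mapped to the middle of the year (`years * 12 + 6`),
#' so "age 5" is treated as 66 months; fractional ages are converted exactly
#' (`years * 12`).
#'
#' @param age_years Numeric vector of ages in years.
#' @param mid_year Apply the +6 month mid-year offset to whole-year ages.
#' @return Ages in months.
#' @export
age_to_months <- function(age_years, mid_year = TRUE) {
  whole <- age_years %% 1 == 0
  age_years * 12 + if (mid_year) 6 * whole else 0
}

# Interpolate L, M, S linearly in age (months), per sex. Errors on ages
# outside table coverage (no extrapolation).
.lms_at <- function(age_months, sex, ref) {
  n <- max(length(age_months), length(sex))
  age_months <- rep_len(age_months, n)
  sex <- rep_len(sex, n)
  out <- list(L = numeric(n), M = numeric(n), S = numeric(n))
  for (sx in unique(sex)) {
    sub <- ref[ref$sex == sx, ]
    if (!nrow(sub)) stop("LMS reference has no rows for sex '", sx, "'")
    idx <- which(sex == sx)
    a <- age_months[idx]
    bad <- a < min(sub$age_months) | a > max(sub$age_months)
    if (any(bad))
      stop(sprintf("age %s months outside LMS coverage [%d, %d] for sex %s",
                   paste(unique(a[bad]), collapse = ", "),
                   min(sub$age_months), max(sub$age_months), sx))
    out$L[idx] <- stats::approx(sub$age_months, sub$L, a)$y
    out$M[idx] <- stats::approx(sub$age_months, sub$M, a)$y
    out$S[idx] <- stats::approx(sub$age_months, sub$S, a)$y
  }
  out
}

#' BMI-for-age z-score (LMS method)
#'
#' Computes the standard-deviation score of a BMI value relative to the sex-
#' and age-specific reference distribution:
#' \deqn{z = \frac{(\mathrm{bmi}/M)^L - 1}{L\,S}} for \eqn{L \neq 0}, and
#' \eqn{z = \log(\mathrm{bmi}/M)/S} in the limit \eqn{L \to 0}. L, M and S
#' are linearly interpolated at the child's age in months.
#'
#' @param bmi BMI in kg/m^2 (vector).
#' @param age_years Age in years (vector, recycled); whole years are read as
#'   mid-year, see [age_to_months()].
#' @param sex "M" or "F" (vector, recycled).
#' @param ref LMS reference table from [lms_reference()].
#' @return z-scores (SD units).
#' @export
#' @examples
#' bmi_zscore(16.3, 4, "F")
bmi_zscore <- function(bmi, age_years, sex, ref = lms_reference()) {
  stopifnot(all(bmi > 0 | is.na(bmi)))
  n <- max(length(bmi), length(age_years), length(sex))
  bmi <- rep_len(bmi, n)
  p <- .lms_at(rep_len(age_to_months(age_years), n), rep_len(sex, n), ref)
  L0 <- abs(p$L) < 1e-12
  z <- ((bmi / p$M)^p$L - 1) / (p$L * p$S)
  z[L0] <- log(bmi[L0] / p$M[L0]) / p$S[L0]
  z
}

#' Invert a BMI-for-age z-score to a BMI value
#'
#' Exact inverse of [bmi_zscore()]: \eqn{M (1 + L S z)^{1/L}} for
#' \eqn{L \neq 0}, \eqn{M e^{S z}} otherwise. Used, e.g., to convert weight
#' status cut points (z = +1, +2, +3) into BMI thresholds at a given age.
#'
#' @inheritParams bmi_zscore
#' @param z z-score (SD units, vector).
#' @return BMI in kg/m^2.
#' @export
zscore_to_bmi <- function(z, age_years, sex, ref = lms_reference()) {
  n <- max(length(z), length(age_years), length(sex))
  z <- rep_len(z, n)
  p <- .lms_at(rep_len(age_to_months(age_years), n), rep_len(sex, n), ref)
  base <- 1 + p$L * p$S * z
  if (any(base <= 0 & abs(p$L) >= 1e-12, na.rm = TRUE))
    stop("z outside representable range: 1 + L*S*z <= 0")
  out <- p$M * base^(1 / p$L)
  L0 <- abs(p$L) < 1e-12
  out[L0] <- p$M[L0] * exp(p$S[L0] * z[L0])
  out
}

#' Weight-status cut points (SD units)
#'
#' The z-score thresholds separating weight-status categories. Category
#' exceedance is strict (`z > cutoff`), so a child exactly at z = +1 is
#' classified healthy. Severe obesity (z > +3 by this package's convention)
#' is a subcategory of obesity for prevalence reporting.
#'
#' @param underweight,overweight,obese,severe_obese Thresholds in SD units.
#' @return A named numeric vector of class `status_cutoffs`.
#' @export
status_cutoffs <- function(underweight = -2, overweight = 1, obese = 2,
                           severe_obese = 3) {
  v <- c(underweight = underweight, overweight = overweight, obese = obese,
         severe_obese = severe_obese)
  if (is.unsorted(v, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  structure(v, class = "status_cutoffs")
}

#' Classify BMI-for-age z-scores into weight-status categories
#'
#' Maps each finite z-score to exactly one of `underweight` (z < cut),
#' `healthy`, `overweight`, `obese` using strict exceedance at each cut
#' point. The severe-obesity flag is a refinement of `obese`, obtained
#' separately via [severe_obese()].
#'
#' @param z z-scores (SD units).
#' @param cutoffs From [status_cutoffs()].
#' @return Factor with levels underweight, healthy, overweight, obese.
#' @export
#' @examples
#' classify_status(c(-2.5, 0, 1.5, 2.5))
classify_status <- function(z, cutoffs = status_cutoffs()) {
  lev <- c("underweight", "healthy", "overweight", "obese")
  idx <- ifelse(z < cutoffs[["underweight"]], 1L,
         ifelse(z <= cutoffs[["overweight"]], 2L,
         ifelse(z <= cutoffs[["obese"]], 3L, 4L)))
  factor(lev[idx], levels = lev)
}

#' Severe-obesity flag
#'
#' @inheritParams classify_status
#' @return Logical: z strictly above the severe-obesity cut point.
#' @export
severe_obese <- function(z, cutoffs = status_cutoffs()) {
  z > cutoffs[["severe_obese"]]
}
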