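#' Shifted log-normal distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter (shifted) log-normal distribution used for BMI
#' cross-sections: `X = shift + exp(N(meanlog, sdlog))`. Right-skewed, with
#' exactly three free parameters, matching the three calibration constraints
#' (mean plus two tail probabilities) of [calibrate_bmi_distribution()].
#'
#' @param x,q Quantiles. @param p Probabilities. @param n Number of draws.
#' @param shift Location shift (lower bound of support).
#' @param meanlog,sdlog Parameters of the log-normal component.
#' @return `dshlnorm` the density, `pshlnorm` the CDF, `qshlnorm` the
#'   quantile function, `rshlnorm` random draws.
#' @name shlnorm
NULL

#' @rdname shlnorm
#' @export
dshlnorm <- function(x, shift, meanlog, sdlog)
  stats::dlnorm(x - shift, meanlog, sdlog)

#' @rdname shlnorm
#' @export
pshlnorm <- function(q, shift, meanlog, sdlog)
  stats::plnorm(q - shift, meanlog, sdlog)

#' @rdname shlnorm
#' @export
qshlnorm <- function(p, shift, meanlog, sdlog)
  shift + stats::qlnorm(p, meanlog, sdlog)

#' @rdname shlnorm
#' @export
rshlnorm <- function(n, shift, meanlog, sdlog)
  shift + stats::rlnorm(n, meanlog, sdlog)

.shlnorm_mean <- function(par) par[["shift"]] + exp(par[["meanlog"]] + par[["sdlog"]]^2 / 2)

#' Calibrate a BMI cross-section distribution to a summary triple
#'
#' Solves for shifted log-normal parameters such that the implied mean
#' equals `mean_bmi` and the exceedance probabilities over the overweight
#' and obesity BMI thresholds at (`age`, `sex`) equal the target
#' percentages. Overweight and obese are treated as *disjoint* reported
#' categories, so the calibrated tails are
#' `P(X > overweight cut) = (pct_overweight + pct_obese)/100` and
#' `P(X > obese cut) = pct_obese/100`.
#'
#' Given the two tail constraints, `meanlog` and `sdlog` are exact functions
#' of the shift; the shift is then found by root-finding on the mean
#' constraint (tolerance 1e-10 on the shift, so all three moments hold to
#' well under 1e-6). A degenerate request with both percentages zero returns
#' a near-point-mass log-normal (sdlog = 0.01) centred on the mean.
#'
#' @param mean_bmi Target mean BMI, kg/m^2.
#' @param pct_overweight,pct_obese Target prevalences in percent
#'   (overweight excluding obese).
#' @param age Age in years at which thresholds are evaluated.
#' @param sex "M" or "F".
#' @param ref LMS reference from [lms_reference()].
#' @param cutoffs Weight-status cut points, [status_cutoffs()].
#' @return Named numeric vector `c(shift, meanlog, sdlog)`.
#' @export
#' @examples
#' par <- calibrate_bmi_distribution(16.3, 23.8, 9.1, 4.5, "F")
#' abs(.Machine$double.eps + mean(rshlnorm(1e5, par[1], par[2], par[3])) - 16.3) < 0.05
calibrate_bmi_distribution <- function(mean_bmi, pct_overweight, pct_obese,
                                       age, sex, ref = lms_reference(),
                                       cutoffs = status_cutoffs()) {
  stopifnot(mean_bmi > 10, pct_overweight >= 0, pct_obese >= 0,
            pct_overweight + pct_obese <= 100)
  t1 <- zscore_to_bmi(cutoffs[["overweight"]], age, sex, ref)
  t2 <- zscore_to_bmi(cutoffs[["obese"]], age, sex, ref)
  if (t1 >= t2)
    stop("inconsistent thresholds: overweight cut not below obese cut")
  p1 <- (pct_overweight + pct_obese) / 100
  p2 <- pct_obese / 100
  if (p1 == 0) {
    sdlog <- 0.01
    return(c(shift = 0, meanlog = log(mean_bmi) - sdlog^2 / 2, sdlog = sdlog))
  }
  if (p2 == 0) { # no obese tail requested: pin it four SDs beyond z1
    p2 <- stats::pnorm(stats::qnorm(1 - p1) + 4, lower.tail = FALSE)
  }
  if (p2 >= p1) stop("pct_obese tail must be below the overweight+obese tail")
  z1 <- stats::qnorm(1 - p1)
  z2 <- stats::qnorm(1 - p2)
  sig_of <- function(cc) (log(t2 - cc) - log(t1 - cc)) / (z2 - z1)
  mu_of <- function(cc, s) log(t1 - cc) - z1 * s
  f <- function(cc) { s <- sig_of(cc); cc + exp(mu_of(cc, s) + s^2 / 2) - mean_bmi }
  lo <- t1 - 80
  hi <- t1 - 1e-8
  if (f(lo) > 0)
    stop(sprintf(paste0("calibration infeasible: mean %.2f below the minimum ",
                        "achievable (%.2f) for tails (%.1f%%, %.1f%%) at age %s"),
                 mean_bmi, f(lo) + mean_bmi, 100 * p1, 100 * p2, age))
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  s <- sig_of(r$root)
  c(shift = r$root, meanlog = mu_of(r$root, s), sdlog = s)
}
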