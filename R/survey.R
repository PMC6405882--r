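#' Design-based (survey-weighted) mean with Taylor-linearized variance
#'
#' Point estimate is the Hajek ratio `sum(w*x)/sum(w)`. The standard error
#' uses first-order Taylor linearization with the with-replacement
#' approximation: per-record scores `w*(x - point)/sum(w)` are totalled per
#' primary sampling unit (PSU), and the variance is the between-PSU,
#' within-stratum variance of those totals,
#' `sum_h n_h/(n_h - 1) * sum_c (t_hc - mean_h)^2`. The 95% interval uses
#' the normal quantile 1.96. Invariant to rescaling all weights by a
#' constant.
#'
#' @param x Numeric values.
#' @param weights Positive survey weights.
#' @param stratum,psu Design identifiers (any atomic type).
#' @return List of class `svy_estimate`: `point`, `se`, `ci95_lo`,
#'   `ci95_hi`, `n`.
#' @export
#' @examples
#' svy_mean(c(1, 2, 3, 4), rep(1, 4), rep(1, 4), 1:4) # classical SE of mean
svy_mean <- function(x, weights, stratum, psu) {
  stopifnot(length(x) == length(weights), length(x) == length(stratum),
            length(x) == length(psu))
  if (any(!is.finite(x))) stop("values must be finite")
  if (any(weights <= 0)) stop("weights must be positive")
  W <- sum(weights)
  point <- sum(weights * x) / W
  score <- weights * (x - point) / W
  id <- interaction(stratum, psu, drop = TRUE)
  tot <- tapply(score, id, sum)
  st_of_psu <- tapply(as.character(stratum), id, `[`, 1)
  v <- 0
  for (h in unique(st_of_psu)) {
    th <- tot[st_of_psu == h]
    nh <- length(th)
    if (nh < 2)
      stop("stratum '", h, "' has a single PSU; collapse strata or treat ",
           "it as a certainty unit before variance estimation")
    v <- v + nh / (nh - 1) * sum((th - mean(th))^2)
  }
  se <- sqrt(v)
  structure(list(point = point, se = se, ci95_lo = point - 1.96 * se,
                 ci95_hi = point + 1.96 * se, n = length(x)),
            class = "svy_estimate")
}

#' Survey-weighted prevalence of a category (percent)
#'
#' The design-based mean of the 0/100 indicator of membership in
#' `category`. `statuses` may be a factor/character vector of categories or
#' a logical vector (with `category = TRUE`).
#'
#' @param statuses Category labels or logical membership.
#' @param category The category whose prevalence is estimated.
#' @inheritParams svy_mean
#' @return A `svy_estimate` in percent.
#' @export
svy_prevalence <- function(statuses, category, weights, stratum, psu) {
  ind <- 100 * (statuses == category)
  svy_mean(as.numeric(ind), weights, stratum, psu)
}

#' Survey-weighted population total
#'
#' Sum of weights over (present) records: the number of population members
#' the sample represents.
#'
#' @param weights Positive survey weights.
#' @param present Optional logical vector restricting the sum.
#' @return Numeric total.
#' @export
svy_total <- function(weights, present = NULL) {
  if (!is.null(present)) weights <- weights[present]
  sum(weights)
}

#' @export
print.svy_estimate <- function(x, ...) {
  cat(sprintf("%.4g (SE %.3g, 95%% CI %.4g to %.4g, n = %d)\n",
              x$point, x$se, x$ci95_lo, x$ci95_hi, x$n))
  invisible(x)
}
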