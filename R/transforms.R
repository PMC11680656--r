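#' Intake transform used throughout the trajectory model
#'
#' Alcohol intakes (grams ethanol/day) are modelled on the natural-log scale
#' after adding one, `log(x + 1)`, which accommodates the point mass at zero
#' and the right skew of intake distributions.
#'
#' @param x Non-negative intakes in grams/day.
#' @return `log(x + 1)`.
#' @seealso [inverse_transform_intake()]
#' @export
transform_intake <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("intakes must be finite and non-negative")
  }
  log1p(x)
}

#' Back-transform from the modelled scale to grams/day
#'
#' Inverse of [transform_intake()]: `max(exp(y) - 1, 0)`. The floor at zero
#' keeps simulated or predicted intakes on the physically meaningful scale.
#'
#' @param y Values on the `log(x + 1)` scale.
#' @export
inverse_transform_intake <- function(y) {
  pmax(expm1(y), 0)
}

#' Rescaled age used as the trajectory time axis
#'
#' Age in years is recentred at 35 and rescaled by 13, `t = (age - 35)/13`,
#' so that the retrospective measurement ages 22 and 48 map to -1 and 1 and
#' polynomial coefficients are on comparable scales.
#'
#' @param age Age in years.
#' @return Unitless time `t`.
#' @export
rescale_age <- function(age) {
  (age - 35) / 13
}

#' Inverse of [rescale_age()]
#' @param t Unitless trajectory time.
#' @return Age in years.
#' @export
unscale_age <- function(t) {
  35 + 13 * t
}
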