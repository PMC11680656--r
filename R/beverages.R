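#' Ethanol content per serving of each beverage type
#'
#' Grams of ethanol per standard serving for the six beverage categories on
#' the cohort's food-frequency questionnaire: bottled beer in three strengths
#' (330 ml bottles), wine (125 ml glass), fortified wine (60 ml glass) and
#' spirits (30 ml drink).
#'
#' @format Named numeric vector, grams of ethanol per serving.
#' @export
ethanol_grams_per_serving <- c(
  light_beer     = 8.9,
  regular_beer   = 12.2,
  strong_beer    = 17.5,
  wine           = 12.5,
  fortified_wine = 9.3,
  spirits        = 9.9
)

#' Servings per day for the 12 reported frequency categories
#'
#' The questionnaire records consumption frequency in 12 ordered categories
#' from "never" to "8 or more times per day". The mapping to servings/day uses
#' category midpoints (a month taken as 30.4 days), with the open top category
#' mapped to 8. The exact mapping is not part of the published constants; this
#' table is the package's documented choice.
#'
#' @format Named numeric vector of length 12 (servings/day).
#' @export
frequency_category_servings <- c(
  "never"            = 0,
  "<1/month"         = 0.5 / 30.4,
  "1/month"          = 1 / 30.4,
  "2-3/month"        = 2.5 / 30.4,
  "1/week"           = 1 / 7,
  "2-4/week"         = 3 / 7,
  "5-6/week"         = 5.5 / 7,
  "1/day"            = 1,
  "2-3/day"          = 2.5,
  "4-5/day"          = 4.5,
  "6-7/day"          = 6.5,
  ">=8/day"          = 8
)

#' Convert beverage-specific consumption frequencies to grams ethanol/day
#'
#' Computes total daily ethanol intake as the frequency-weighted sum of the
#' per-serving ethanol contents in [ethanol_grams_per_serving].
#'
#' @param freq Named numeric vector or list of servings/day. Names must be a
#'   subset of `names(ethanol_grams_per_serving)`; omitted beverages count as
#'   zero.
#' @return Grams of ethanol per day (single non-negative number).
#' @examples
#' frequency_to_grams(c(regular_beer = 1))           # 12.2
#' frequency_to_grams(c(wine = 2, spirits = 1))      # 34.9
#' @export
frequency_to_grams <- function(freq) {
  freq <- unlist(freq)
  if (length(freq) == 0) return(0)
  if (is.null(names(freq)) || any(!nzchar(names(freq)))) {
    stop("'freq' must be a named vector of servings/day")
  }
  unknown <- setdiff(names(freq), names(ethanol_grams_per_serving))
  if (length(unknown) > 0) {
    stop("unknown beverage type(s): ", paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop("beverage frequencies must be finite and non-negative")
  }
  sum(freq * ethanol_grams_per_serving[names(freq)])
}
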