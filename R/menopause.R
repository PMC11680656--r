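#' Classify menopausal status at baseline from menstrual history
#'
#' Applies the baseline classification cascade used for cohort assembly:
#'
#' 1. *Post*: no menses during the preceding 12 months
#'    (`months_since_last_menses >= 12`) or surgically induced menopause by
#'    bilateral ovariectomy.
#' 2. If the menstrual history is missing, or the woman reports a hysterectomy
#'    or exogenous hormone use: *post* if aged >= 55, *peri* if aged 46-55,
#'    otherwise *pre*. Age exactly 55 is classified *post* (the ">= 55" clause
#'    takes precedence over the 46-55 band).
#' 3. *Peri*: fewer than 9 menstrual periods in the preceding year, or menses
#'    during the preceding year but not at the time of baseline assessment.
#' 4. Otherwise *pre*.
#'
#' The menstrual history counts as missing when `months_since_last_menses`,
#' `periods_last_year` and `menstruating_at_baseline` are all `NA`.
#'
#' @param profiles Data frame with columns `baseline_age`,
#'   `months_since_last_menses`, `periods_last_year`,
#'   `menstruating_at_baseline`, `bilateral_ovariectomy`, `hysterectomy`,
#'   `exogenous_hormone_use`. Missing history fields may be `NA`; the surgery
#'   and hormone flags must be logical (`NA` treated as `FALSE`).
#' @return Factor with levels `pre`, `peri`, `post`, one per row.
#' @export
classify_menopause <- function(profiles) {
  required <- c("baseline_age", "months_since_last_menses", "periods_last_year",
                "menstruating_at_baseline", "bilateral_ovariectomy",
                "hysterectomy", "exogenous_hormone_use")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols) > 0) {
    stop("profiles lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  age <- profiles$baseline_age
  if (any(is.na(age))) stop("baseline_age must be present for every subject")

  months  <- profiles$months_since_last_menses
  periods <- profiles$periods_last_year
  menstr  <- profiles$menstruating_at_baseline
  ovx     <- isTRUE_vec(profiles$bilateral_ovariectomy)
  hyst    <- isTRUE_vec(profiles$hysterectomy)
  horm    <- isTRUE_vec(profiles$exogenous_hormone_use)

  history_missing <- is.na(months) & is.na(periods) & is.na(menstr)

  status <- rep(NA_character_, nrow(profiles))

  # rule 1: definite postmenopause
  r1 <- (!is.na(months) & months >= 12) | ovx
  status[r1] <- "post"

  # rule 2: history uninformative (missing / hysterectomy / hormone use)
  r2 <- is.na(status) & (history_missing | hyst | horm)
  status[r2 & age >= 55] <- "post"
  status[r2 & age >= 46 & age < 55] <- "peri"
  status[r2 & age < 46] <- "pre"

  # rule 3: perimenopausal signs
  r3 <- is.na(status) &
    ((!is.na(periods) & periods < 9) |
       ((!is.na(months) & months <= 12) & (!is.na(menstr) & !menstr)))
  status[r3] <- "peri"

  # rule 4: default premenopausal
  status[is.na(status)] <- "pre"

  factor(status, levels = c("pre", "peri", "post"))
}

# NA-safe logical coercion: NA flags are treated as FALSE
isTRUE_vec <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}

#' Recode perimenopausal status as postmenopausal
#'
#' For the survival analysis, perimenopausal women at baseline are analysed as
#' postmenopausal (they are assumed to have reached menopause by diagnosis or
#' end of follow-up).
#'
#' @param status Factor or character vector with values in
#'   `c("pre", "peri", "post")`.
#' @return Factor with levels `pre`, `post`.
#' @export
recode_peri_as_post <- function(status) {
  status <- as.character(status)
  bad <- setdiff(unique(status[!is.na(status)]), c("pre", "peri", "post"))
  if (length(bad) > 0) stop("invalid status value(s): ", paste(bad, collapse = ", "))
  status[status == "peri"] <- "post"
  factor(status, levels = c("pre", "post"))
}
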