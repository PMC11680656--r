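#' Covariates required for the fully adjusted hazard model
#'
#' The eight lifestyle and reproductive adjustment covariates; any subject
#' with a missing value in one of these is excluded from the survival set
#' (complete-case analysis). The recruitment-date quintile enters both
#' adjustment models.
#' @export
model2_covariates <- c("physical_activity", "smoking", "education", "bmi_cat",
                       "age_first_pregnancy", "menarche", "breastfed",
                       "hrt_ever")

#' Trim the extreme 1% tails of the energy-intake/energy-requirement ratio
#'
#' Subjects whose reported energy intake to calculated energy requirement
#' ratio lies strictly below the lower or strictly above the upper empirical
#' percentile are excluded. Percentiles use the standard linear-interpolation
#' empirical quantile (type 7); ties at the cut values are retained.
#'
#' @param values Numeric vector of EI/ER ratios, named by subject id (or
#'   unnamed, in which case positions are the ids).
#' @param lower,upper Quantile probabilities delimiting retention
#'   (defaults 0.01 and 0.99).
#' @return List with `retained` (ids kept, in input order), `excluded`
#'   (ids dropped), and `cuts` (the two quantiles used).
#' @export
exclude_energy_ratio_extremes <- function(values, lower = 0.01, upper = 0.99) {
  ids <- names(values)
  if (is.null(ids)) ids <- seq_along(values)
  keep_finite <- is.finite(values)
  if (!any(keep_finite)) stop("no finite EI/ER values supplied")
  q <- stats::quantile(values[keep_finite], probs = c(lower, upper),
                       na.rm = TRUE, names = FALSE, type = 7)
  drop <- keep_finite & (values < q[1] | values > q[2])
  list(retained = ids[!drop & keep_finite],
       excluded = ids[drop | !keep_finite],
       cuts = c(lower = q[1], upper = q[2]))
}

#' Sequential exclusion accounting
#'
#' Applies a named vector of exclusion counts to a starting cohort size and
#' returns the ordered flow table. Used both for synthetic flow reports and
#' for checking arithmetic on published participant flows.
#'
#' @param n_input Starting number of subjects.
#' @param exclusions Named integer vector of exclusion counts, applied in
#'   order.
#' @return Data frame with columns `step`, `excluded_n`, `remaining_n`;
#'   attribute `final_n` holds the final cohort size.
#' @examples
#' flow_accounting(28720, c(premenopausal = 2077, missing_covariates = 2100))
#' @export
flow_accounting <- function(n_input, exclusions) {
  if (length(exclusions) > 0 && is.null(names(exclusions))) {
    stop("'exclusions' must be named")
  }
  remaining <- n_input - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) stop("exclusions exceed the available cohort")
  out <- data.frame(step = c("input", names(exclusions)),
                    excluded_n = c(0, as.numeric(exclusions)),
                    remaining_n = c(n_input, remaining))
  attr(out, "final_n") <- out$remaining_n[nrow(out)]
  out
}

#' Assemble the trajectory and survival analysis sets
#'
#' Applies the cohort exclusion flow: (1) the EI/ER 1% trim (when an
#' `energy_ratio` column is present) defines the trajectory set used for
#' latent-class estimation, irrespective of menopausal status or covariate
#' completeness; (2) premenopausal women (after recoding peri as post) and
#' women with a missing value in any of [model2_covariates] are further
#' excluded to form the survival set.
#'
#' @param intakes Long-format intake records (`subject_id`, `age_years`,
#'   `intake_g_day`, `source`).
#' @param profiles One row per subject: baseline age, menstrual history,
#'   covariates, `entry_age`, `exit_age`, `event` and optionally
#'   `energy_ratio`.
#' @param energy_trim Logical; apply the EI/ER trim when the column exists
#'   (default `TRUE`).
#' @return List with `trajectory` (intakes + profiles for the trajectory set),
#'   `survival` (profiles for the survival set, with a `menopause` column),
#'   and `flow` (ordered flow report, see [flow_accounting()]).
#' @export
assemble_analysis_sets <- function(intakes, profiles, energy_trim = TRUE) {
  if (anyDuplicated(profiles$subject_id)) {
    stop("duplicated subject ids in profiles")
  }
  if (!all(intakes$subject_id %in% profiles$subject_id)) {
    stop("intake records reference unknown subject ids")
  }
  n_input <- nrow(profiles)
  exclusions <- integer(0)

  traj_profiles <- profiles
  if (energy_trim && "energy_ratio" %in% names(profiles)) {
    ratios <- stats::setNames(profiles$energy_ratio, profiles$subject_id)
    trim <- exclude_energy_ratio_extremes(ratios)
    traj_profiles <- profiles[profiles$subject_id %in% trim$retained, ]
    exclusions <- c(exclusions, energy_ratio_extremes = n_input - nrow(traj_profiles))
  }
  traj_intakes <- intakes[intakes$subject_id %in% traj_profiles$subject_id, ]

  status <- recode_peri_as_post(classify_menopause(traj_profiles))
  surv_profiles <- traj_profiles
  surv_profiles$menopause <- status
  keep_post <- status == "post"
  exclusions <- c(exclusions, premenopausal = sum(!keep_post))
  surv_profiles <- surv_profiles[keep_post, ]

  have_cov <- intersect(model2_covariates, names(surv_profiles))
  complete <- if (length(have_cov) > 0) {
    stats::complete.cases(surv_profiles[, have_cov, drop = FALSE])
  } else rep(TRUE, nrow(surv_profiles))
  exclusions <- c(exclusions, missing_covariates = sum(!complete))
  surv_profiles <- surv_profiles[complete, ]

  flow <- flow_accounting(n_input, exclusions)
  list(trajectory = list(intakes = traj_intakes, profiles = traj_profiles),
       survival = surv_profiles,
       flow = flow)
}

#' Published cohort margins used for arithmetic checks
#'
#' Class sizes and breast-cancer case counts for the four trajectory classes
#' in the published postmenopausal complete-case cohort (n = 24,543 of 28,720
#' women after excluding 2,077 premenopausal women and 2,100 with missing
#' covariates), in class order: low-to-moderate increasing, consistently
#' high, moderate increasing, consistently low (reference).
#'
#' @format List with `flow` (input n and the two exclusion counts),
#'   `class_n`, `class_cases` and `trajectory_shares` (the 4-class shares of
#'   the full trajectory cohort, as proportions).
#' @export
published_cohort_margins <- list(
  flow = c(input = 28720, premenopausal = 2077, missing_covariates = 2100),
  class_n = c(4087, 3577, 12351, 4528),
  class_cases = c(269, 272, 787, 263),
  trajectory_shares = c(0.163, 0.151, 0.506, 0.180)
)
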