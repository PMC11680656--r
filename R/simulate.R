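#' Simulate a synthetic cohort with known latent structure
#'
#' Draws a cohort from the generating model assumed by the two-stage
#' analysis. Each woman receives a latent class from the configured shares; a
#' random intercept/slope/quadratic triple; transformed-scale intakes
#' `y = x' beta_g + z' b + eps` at the retrospective ages and at her baseline
#' age, back-transformed to grams/day as `max(exp(y) - 1, 0)`; an event age
#' from a Weibull proportional-hazards model with her class log hazard ratio,
#' drawn conditional on exceeding her baseline (entry) age; and exponential
#' competing censoring plus an administrative horizon. Menstrual-history
#' fields and class-conditional adjustment covariates emulate the cohort's
#' baseline questionnaire.
#'
#' All randomness is driven by `config$seed`; identical configurations give
#' byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `intakes` (long
#'   format records), `subjects` (one row per woman) and `truth` (the latent
#'   class, random effects and uncensored event age per woman, plus the
#'   configuration). `truth` is withheld from all estimation code.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  G <- length(config$class_shares)
  ids <- sprintf("S%05d", seq_len(n))

  cls <- sample.int(G, n, replace = TRUE, prob = config$class_shares)

  # random effects via Cholesky-like factor (PSD-safe through eigen)
  ev <- eigen(config$re_covariance, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3) %*% t(ev$vectors)
  b <- matrix(stats::rnorm(n * 3), n, 3) %*% rt

  baseline_age <- stats::runif(n, config$baseline_age_range[1],
                               config$baseline_age_range[2])

  # intake measurements: retrospective ages + exact baseline age
  retro <- config$measure_ages
  ages <- cbind(matrix(retro, n, length(retro), byrow = TRUE), baseline_age)
  src <- c(paste0("retro", retro), "baseline_ffq")
  keep_retro <- matrix(stats::runif(n * length(retro)) >= config$missing_rate,
                       n, length(retro))
  keep <- cbind(keep_retro, TRUE)

  tt <- rescale_age(ages)
  beta <- config$class_fixed_effects
  y <- beta[cls, 1] + b[, 1] +
    (beta[cls, 2] + b[, 2]) * tt +
    (beta[cls, 3] + b[, 3]) * tt^2 +
    matrix(stats::rnorm(n * ncol(ages), sd = config$residual_sd), n, ncol(ages))
  intake <- inverse_transform_intake(y)

  intakes <- data.frame(
    subject_id = rep(ids, times = ncol(ages)),
    age_years = as.vector(ages),
    intake_g_day = as.vector(intake),
    source = rep(src, each = n),
    stringsAsFactors = FALSE
  )
  intakes <- intakes[as.vector(keep), ]
  intakes <- intakes[order(intakes$subject_id, intakes$age_years), ]
  rownames(intakes) <- NULL

  # event age: Weibull PH, truncated draw conditional on exceeding entry age
  eta <- config$class_log_hr[cls]
  H_entry <- (baseline_age / config$weibull_scale)^config$weibull_shape
  S_entry <- exp(-H_entry * exp(eta))
  v <- stats::runif(n) * S_entry
  event_age <- config$weibull_scale * (-log(v) / exp(eta))^(1 / config$weibull_shape)

  censor_age <- baseline_age + stats::rexp(n, rate = config$censor_rate)
  admin_age <- baseline_age + config$admin_followup_years
  exit_age <- pmin(event_age, censor_age, admin_age)
  event <- as.integer(event_age <= censor_age & event_age <= admin_age)

  # menstrual history consistent with baseline age
  meno_age <- stats::rnorm(n, config$menopause_age_mean, config$menopause_age_sd)
  hyst <- stats::runif(n) < config$hysterectomy_rate
  ovx <- stats::runif(n) < config$ovariectomy_rate
  horm <- stats::runif(n) < config$hormone_use_rate
  hist_missing <- stats::runif(n) < config$history_missing_rate

  months_since <- pmax(round(12 * (baseline_age - meno_age)), 0)
  menstruating <- meno_age > baseline_age
  # women within a year of natural menopause: waning cycles
  waning <- !menstruating & months_since < 12
  periods <- ifelse(menstruating, 12L, ifelse(waning, 6L, 0L))
  months_since[menstruating] <- 0

  months_since[hist_missing] <- NA
  periods[hist_missing] <- NA
  menstruating[hist_missing] <- NA

  subjects <- data.frame(
    subject_id = ids,
    baseline_age = baseline_age,
    months_since_last_menses = months_since,
    periods_last_year = periods,
    menstruating_at_baseline = menstruating,
    bilateral_ovariectomy = ovx,
    hysterectomy = hyst,
    exogenous_hormone_use = horm,
    recruitment_quintile = sample.int(5, n, replace = TRUE),
    energy_ratio = stats::rlnorm(n, meanlog = 0, sdlog = config$energy_ratio_sdlog),
    entry_age = baseline_age,
    exit_age = exit_age,
    event = event,
    stringsAsFactors = FALSE
  )
  for (nm in names(config$covariate_model)) {
    pm <- config$covariate_model[[nm]]
    levels <- colnames(pm)
    u <- stats::runif(n)
    cum <- t(apply(pm, 1, cumsum))
    idx <- rowSums(u > cum[cls, , drop = FALSE]) + 1
    val <- levels[idx]
    val[stats::runif(n) < config$covariate_missing_rate] <- NA
    subjects[[nm]] <- val
  }

  truth <- list(
    subject_id = ids,
    class = cls,
    random_effects = b,
    event_age_uncensored = event_age,
    config = config
  )
  structure(list(intakes = intakes, subjects = subjects, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d intake records\n",
              nrow(x$subjects), nrow(x$intakes)))
  cat(sprintf("  events: %d (%.1f%%)\n", sum(x$subjects$event),
              100 * mean(x$subjects$event)))
  tab <- table(factor(x$truth$class, levels = seq_along(x$truth$config$class_shares)))
  cat("  true class counts:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `intakes.csv`, `subjects.csv` and `truth.json` (the ground truth is
#' stored separately and is never read by the estimation code).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("intakes.csv", "subjects.csv", "truth.json"))
  utils::write.csv(cohort$intakes, paths[1], row.names = FALSE)
  utils::write.csv(cohort$subjects, paths[2], row.names = FALSE)
  truth <- cohort$truth
  truth$random_effects <- unname(split(truth$random_effects,
                                       row(truth$random_effects)))
  truth$config <- unclass(truth$config)
  truth$config$class_fixed_effects <-
    unname(split(truth$config$class_fixed_effects, row(truth$config$class_fixed_effects)))
  truth$config$re_covariance <-
    unname(split(truth$config$re_covariance, row(truth$config$re_covariance)))
  truth$config$covariate_model <- lapply(truth$config$covariate_model, function(m) {
    list(levels = colnames(m), probs = unname(split(m, row(m))))
  })
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `intakes.csv` and `subjects.csv`.
#' @return List with `intakes` and `subjects` data frames (no truth).
#' @export
read_cohort <- function(dir) {
  intakes <- utils::read.csv(file.path(dir, "intakes.csv"),
                             stringsAsFactors = FALSE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  list(intakes = intakes, subjects = subjects)
}
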