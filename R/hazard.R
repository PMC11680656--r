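# Stage 2: parametric proportional hazards across latent classes, with the
# stage-1 posterior class probabilities held fixed and the likelihood
# marginalized over class membership to correct for classification error.
# Age is the timescale; delayed entry divides by survival at the entry age.

# canonical factor level orders for the adjustment covariates
covariate_levels <- list(
  physical_activity = c("inactive", "moderately inactive",
                        "moderately active", "active"),
  smoking = c("never", "former", "smoker"),
  education = c("primary", "technical/professional", "secondary", "higher"),
  bmi_cat = c("<18.5", "18.5-24.9", "25-<30", ">=30"),
  age_first_pregnancy = c("none", "<=21", "22-26", ">26"),
  menarche = c("<=12", "13-14", ">14"),
  breastfed = c("yes", "no"),
  hrt_ever = c("yes", "no")
)

# Design matrix of adjustment covariates (treatment coding, no intercept:
# the baseline hazard absorbs the reference level).
hazard_design <- function(data, covariate_set) {
  cols <- "recruitment_quintile"
  if (covariate_set == "model2") cols <- c(cols, model2_covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("survival data lack covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data[, cols, drop = FALSE]
  df$recruitment_quintile <- factor(df$recruitment_quintile, levels = 1:5)
  for (nm in intersect(names(covariate_levels), cols)) {
    lev <- covariate_levels[[nm]]
    obs <- unique(df[[nm]])
    df[[nm]] <- factor(df[[nm]],
                       levels = if (all(obs %in% lev)) lev else sort(obs))
  }
  if (anyNA(df)) stop("missing covariate values in the survival set; ",
                      "apply assemble_analysis_sets() first")
  W <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
  # unrepresented levels give constant columns; drop them
  keep <- apply(W, 2, function(x) stats::var(x) > 0)
  W[, keep, drop = FALSE]
}

# Mixture PH log-likelihood from precomputed baseline pieces.
# probs: n x G; eta: n x G linear predictors; h0T, H0T, H0E: length n.
lc_ph_core <- function(probs, event, h0T, H0T, H0E, eta, ids = NULL) {
  # log f_ig = delta*(log h0(T) + eta) - (H0(T) - H0(E)) exp(eta)
  lh <- ifelse(event == 1, log(h0T), 0)
  lf <- event * (lh + eta) - (H0T - H0E) * exp(eta)
  lp <- log(probs) + lf
  ll_i <- logsumexp_rows(lp)
  if (any(!is.finite(ll_i))) {
    bad <- which(!is.finite(ll_i))[1]
    id <- if (!is.null(ids)) ids[bad] else bad
    stop("non-finite likelihood contribution for subject ", id)
  }
  sum(ll_i)
}

#' Latent-class proportional-hazards log-likelihood
#'
#' Evaluates the classification-error-corrected log-likelihood
#' `sum_i log sum_g p_ig h_g(T_i)^{delta_i} S_g(T_i) / S_g(E_i)`, where
#' `h_g(t) = h0(t) exp(xi_g + gamma' W_i)`, `S_g` the matching survival
#' function, `T_i` the exit age, `E_i` the entry age and `p_ig` the fixed
#' stage-1 posterior class probabilities.
#'
#' @param posteriors `posterior_matrix` or N x G probability matrix with
#'   subject ids as rownames.
#' @param data Survival records: `subject_id`, `entry_age`, `exit_age`,
#'   `event`, plus covariate columns as needed.
#' @param xi Per-class log hazard ratios (length G; the reference entry 0).
#' @param baseline List: `list(family = "weibull", shape =, scale =)` or
#'   `list(family = "mspline", knots =, coefficients =)`.
#' @param gamma Covariate coefficients matching `covariates` (default none).
#' @param covariates Optional character vector of covariate columns or a
#'   precomputed numeric design matrix aligned with `data`.
#' @return The log-likelihood (scalar).
#' @export
lc_ph_loglik <- function(posteriors, data, xi, baseline, gamma = NULL,
                         covariates = NULL) {
  probs <- if (inherits(posteriors, "posterior_matrix")) posteriors$probs
           else as.matrix(posteriors)
  if (!is.null(rownames(probs)) && !is.null(data$subject_id)) {
    idx <- match(as.character(data$subject_id), rownames(probs))
    if (anyNA(idx)) stop("posterior matrix and survival data have misaligned ids")
    probs <- probs[idx, , drop = FALSE]
  } else if (nrow(probs) != nrow(data)) {
    stop("posterior matrix and survival data have different sizes")
  }
  if (any(data$exit_age <= data$entry_age)) {
    stop("every subject needs exit_age > entry_age")
  }
  G <- ncol(probs)
  stopifnot(length(xi) == G)
  W <- NULL
  if (!is.null(covariates)) {
    W <- if (is.character(covariates)) {
      as.matrix(data[, covariates, drop = FALSE])
    } else as.matrix(covariates)
    stopifnot(length(gamma) == ncol(W))
  }
  wx <- if (is.null(W)) rep(0, nrow(data)) else drop(W %*% gamma)
  eta <- outer(wx, xi, "+")
  bl <- baseline_pieces(baseline, data$exit_age, data$entry_age)
  lc_ph_core(probs, data$event, bl$h0T, bl$H0T, bl$H0E, eta,
             ids = data$subject_id)
}

baseline_pieces <- function(baseline, exit, entry) {
  if (baseline$family == "weibull") {
    wT <- weibull_hazard(exit, baseline$shape, baseline$scale)
    HE <- weibull_hazard(entry, baseline$shape, baseline$scale)$cumhaz
    list(h0T = wT$hazard, H0T = wT$cumhaz, H0E = HE)
  } else if (baseline$family == "mspline") {
    mT <- mspline_hazard(exit, baseline$knots, baseline$coefficients)
    HE <- mspline_hazard(entry, baseline$knots, baseline$coefficients)$cumhaz
    list(h0T = mT$hazard, H0T = mT$cumhaz, H0E = HE)
  } else stop("unknown baseline family: ", baseline$family)
}

#' Fit the latent-class proportional-hazards model
#'
#' Maximizes [lc_ph_loglik()] over the class log hazard ratios, covariate
#' effects and baseline-hazard parameters, holding the stage-1 posterior
#' probabilities fixed. Positivity of baseline parameters is enforced by log
#' reparameterization; standard errors come from the inverse observed
#' information (conditioning on stage 1), and Wald confidence intervals for
#' the hazard ratios are reported on the exponential scale. Optionally,
#' stage-1 uncertainty is propagated by a parametric bootstrap that redraws
#' the LCMM parameters from their asymptotic normal distribution, recomputes
#' posteriors and refits.
#'
#' @param data Survival records: `subject_id`, `entry_age`, `exit_age`,
#'   `event`, `recruitment_quintile` and, for `covariate_set = "model2"`,
#'   the eight adjustment covariates.
#' @param posteriors `posterior_matrix` (or matrix with id rownames) from the
#'   stage-1 fit. Rows are matched to `data` by subject id.
#' @param baseline `"weibull"` or `"mspline"`.
#' @param n_knots Total knots for the M-spline baseline (boundary included;
#'   candidates 5 and 4).
#' @param covariate_set `"model1"` (recruitment quintile only; age is the
#'   timescale) or `"model2"` (adds the eight lifestyle/reproductive
#'   covariates).
#' @param reference Reference class index (hazard ratio fixed at 1). Default:
#'   the last class.
#' @param ci_level Confidence level for the Wald intervals (default 0.95).
#' @param stage1_fit Optional `traj_lcmm` fit enabling `boot_stage1`.
#' @param boot_stage1 Number of parametric-bootstrap replicates propagating
#'   stage-1 uncertainty (default 0 = condition on stage 1).
#' @param control Passed to [stats::nlminb()] (`iter.max` etc.).
#' @return Object of class `lc_hazard`.
#' @export
lc_hazard <- function(data, posteriors, baseline = c("weibull", "mspline"),
                      n_knots = 5, covariate_set = c("model1", "model2"),
                      reference = NULL, ci_level = 0.95,
                      stage1_fit = NULL, boot_stage1 = 0, control = list()) {
  baseline <- match.arg(baseline)
  covariate_set <- match.arg(covariate_set)
  probs <- if (inherits(posteriors, "posterior_matrix")) posteriors$probs
           else as.matrix(posteriors)
  idx <- match(as.character(data$subject_id), rownames(probs))
  if (anyNA(idx)) stop("posterior matrix and survival data have misaligned ids")
  probs <- probs[idx, , drop = FALSE]
  G <- ncol(probs)
  if (is.null(reference)) reference <- G
  stopifnot(reference >= 1, reference <= G)
  if (sum(data$event) < 1) stop("need at least one event")
  if (any(data$exit_age <= data$entry_age)) {
    stop("every subject needs exit_age > entry_age")
  }

  W <- hazard_design(data, covariate_set)
  p_cov <- ncol(W)
  free <- setdiff(seq_len(G), reference)
  entry <- data$entry_age; exit <- data$exit_age; event <- data$event
  D <- sum(event)

  knots <- NULL
  if (baseline == "mspline") {
    knots <- place_knots(entry, exit, event, n_knots)
  }
  nb <- if (baseline == "weibull") 2 else length(knots) - 2 + 4

  unpack <- function(theta) {
    xi <- numeric(G)
    xi[free] <- theta[seq_along(free)]
    gamma <- theta[length(free) + seq_len(p_cov)]
    bpar <- theta[length(free) + p_cov + seq_len(nb)]
    bl <- if (baseline == "weibull") {
      list(family = "weibull", shape = exp(bpar[1]), scale = exp(bpar[2]))
    } else {
      list(family = "mspline", knots = knots, coefficients = exp(bpar))
    }
    list(xi = xi, gamma = gamma, baseline = bl)
  }

  negll <- function(theta) {
    p <- unpack(theta)
    ll <- tryCatch({
      bl <- baseline_pieces(p$baseline, exit, entry)
      eta <- outer(drop(W %*% p$gamma), p$xi, "+")
      lc_ph_core(probs, event, bl$h0T, bl$H0T, bl$H0E, eta)
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # initial values: moment-matched Weibull, flat spline at the Weibull level
  shape0 <- 4
  scale0 <- (sum(exit^shape0 - entry^shape0) / D)^(1 / shape0)
  theta0 <- c(rep(0, length(free)), rep(0, p_cov))
  if (baseline == "weibull") {
    theta0 <- c(theta0, log(shape0), log(scale0))
  } else {
    Hmax <- (knots[length(knots)] / scale0)^shape0 -
      (knots[1] / scale0)^shape0
    theta0 <- c(theta0, rep(log(max(Hmax, 0.01) / nb), nb))
  }

  ctrl <- utils::modifyList(list(iter.max = 500, eval.max = 2000), control)
  opt <- stats::nlminb(theta0, negll, control = ctrl)
  if (opt$convergence != 0) {
    g <- numeric_grad(negll, opt$par)
    warning(sprintf("hazard fit did not fully converge (gradient norm %.3g)",
                    sqrt(sum(g^2))))
  }
  theta <- opt$par
  ll <- -opt$objective
  pars <- unpack(theta)
  n_params <- length(theta)

  param_names <- c(paste0("xi_class", free), colnames(W),
                   if (baseline == "weibull") c("log_shape", "log_scale")
                   else paste0("log_eta", seq_len(nb)))
  H <- stats::optimHess(theta, negll)
  V <- tryCatch(solve(H), error = function(e) {
    ev <- eigen(H, symmetric = TRUE)
    null_vec <- ev$vectors[, ev$values < max(ev$values) * 1e-10, drop = FALSE]
    bad <- unique(unlist(apply(abs(null_vec), 2, function(v) {
      param_names[v > 0.3]
    })))
    stop("singular information matrix; near-collinear terms: ",
         paste(bad, collapse = ", "))
  })

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se_xi <- rep(NA_real_, G)
  se_xi[free] <- sqrt(pmax(diag(V)[seq_along(free)], 0))
  hr_table <- data.frame(
    class = seq_len(G),
    n = as.integer(round(colSums(probs))),
    events = as.integer(round(colSums(probs * event))),
    log_hr = pars$xi,
    se = se_xi,
    hr = exp(pars$xi),
    ci_low = ifelse(seq_len(G) == reference, NA, exp(pars$xi - z * se_xi)),
    ci_high = ifelse(seq_len(G) == reference, NA, exp(pars$xi + z * se_xi))
  )

  fit <- structure(list(
    xi = pars$xi, gamma = stats::setNames(pars$gamma, colnames(W)),
    baseline = pars$baseline, baseline_family = baseline, knots = knots,
    loglik = ll, n_params = n_params, aic = 2 * n_params - 2 * ll,
    vcov = V, theta = theta, reference = reference, ci_level = ci_level,
    hr_table = hr_table, covariate_set = covariate_set,
    n_subjects = nrow(data), n_events = D, G = G,
    converged = opt$convergence == 0,
    ids = sort(as.character(data$subject_id)),
    call = match.call()
  ), class = "lc_hazard")

  if (boot_stage1 > 0) {
    if (is.null(stage1_fit)) stop("boot_stage1 requires 'stage1_fit'")
    fit$boot <- boot_stage1_variance(fit, stage1_fit, data, boot_stage1,
                                     baseline, n_knots, covariate_set,
                                     reference, control)
  }
  fit
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Parametric bootstrap over stage-1 parameters: redraw LCMM parameters from
# their asymptotic normal, recompute posteriors, refit the hazard model.
boot_stage1_variance <- function(fit, stage1_fit, data, B, baseline, n_knots,
                                 covariate_set, reference, control) {
  V1 <- vcov(stage1_fit)
  cV <- chol((V1 + t(V1)) / 2 + diag(1e-10, nrow(V1)))
  xi_boot <- matrix(NA_real_, B, fit$G)
  for (b in seq_len(B)) {
    th <- stage1_fit$theta + drop(t(cV) %*% stats::rnorm(nrow(V1)))
    p <- lcmm_unpack(th, stage1_fit$n_classes)
    ld <- lcmm_logdens(stage1_fit$data, p$beta, p$B, p$sigma^2)$logdens
    lp <- sweep(ld, 2, log(p$shares), "+")
    probs <- exp(lp - logsumexp_rows(lp))
    rownames(probs) <- stage1_fit$data$ids
    rb <- tryCatch(
      lc_hazard(data, probs, baseline = baseline, n_knots = n_knots,
                covariate_set = covariate_set, reference = reference,
                control = control),
      error = function(e) NULL)
    if (!is.null(rb)) xi_boot[b, ] <- rb$xi
  }
  used <- stats::complete.cases(xi_boot)
  between <- apply(xi_boot[used, , drop = FALSE], 2, stats::var)
  list(xi_draws = xi_boot, n_used = sum(used), between_var = between,
       total_se = sqrt(ifelse(is.na(fit$hr_table$se), NA,
                              fit$hr_table$se^2) + (1 + 1 / sum(used)) * between))
}
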