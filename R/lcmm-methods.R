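#' @export
print.traj_lcmm <- function(x, ...) {
  cat(sprintf("Latent class mixed model: %d class(es), %d subjects, %d measurements\n",
              x$n_classes, x$n_subjects, x$n_obs))
  cat(sprintf("  log-likelihood %.3f (%d parameters)%s\n", x$loglik, x$n_params,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  class shares:", paste(sprintf("%.3f", x$shares), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.traj_lcmm <- function(object, ...) {
  post <- posterior_probs(object)
  out <- list(
    n_classes = object$n_classes,
    n_subjects = object$n_subjects,
    loglik = object$loglik,
    n_params = object$n_params,
    bic = mixture_bic(object$loglik, object$n_params, object$n_subjects),
    shares = object$shares,
    beta = object$beta,
    re_covariance = object$re_covariance,
    residual_sd = object$residual_sd,
    mean_posterior_by_class = post$mean_posterior_by_class,
    entropy = if (object$n_classes > 1) relative_entropy(post$probs) else NA_real_,
    converged = object$converged
  )
  class(out) <- "summary.traj_lcmm"
  out
}

#' @export
print.summary.traj_lcmm <- function(x, ...) {
  cat(sprintf("Latent class mixed model (%d classes, %d subjects)\n",
              x$n_classes, x$n_subjects))
  cat(sprintf("  logLik %.3f  BIC %.3f  entropy %s\n", x$loglik, x$bic,
              ifelse(is.na(x$entropy), "n/a", sprintf("%.3f", x$entropy))))
  cat("\nClass trajectories (intercept, slope, quadratic on log(x+1) scale):\n")
  tab <- cbind(share = x$shares, x$beta,
               mean_posterior = x$mean_posterior_by_class)
  colnames(tab) <- c("share", "intercept", "slope", "quadratic", "mean_post")
  rownames(tab) <- paste0("class ", seq_len(x$n_classes))
  print(round(tab, 4))
  cat(sprintf("\nResidual SD: %.4f;  RE variance at t = 0: %.4f (ratio %.2f)\n",
              x$residual_sd, x$re_covariance[1, 1],
              x$re_covariance[1, 1] / x$residual_sd^2))
  invisible(x)
}

#' @export
coef.traj_lcmm <- function(object, ...) {
  b <- object$beta
  dimnames(b) <- list(paste0("class", seq_len(nrow(b))),
                      c("intercept", "slope", "quadratic"))
  b
}

#' @export
logLik.traj_lcmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' Posterior class-membership probabilities
#'
#' Bayes posterior `p_ig = pi_g f(Y_i | g) / sum_h pi_h f(Y_i | h)` for every
#' subject, together with the modal assignment (ties broken towards the
#' lowest class index) and the per-class mean posterior probability among
#' modally assigned subjects.
#'
#' @param fit A `traj_lcmm` fit.
#' @param newdata Optional intake records (or `lcmm_data`) to score instead
#'   of the training data.
#' @return Object of class `posterior_matrix`: list with `probs` (N x G,
#'   rownames = subject ids), `modal_class`, `mean_posterior_by_class`.
#' @export
posterior_probs <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "traj_lcmm"))
  ldata <- if (is.null(newdata)) fit$data
           else if (inherits(newdata, "lcmm_data")) newdata
           else lcmm_data(newdata)
  ld <- lcmm_logdens(ldata, fit$beta, fit$re_covariance,
                     fit$residual_sd^2)$logdens
  lp <- sweep(ld, 2, log(fit$shares), "+")
  probs <- exp(lp - logsumexp_rows(lp))
  rownames(probs) <- ldata$ids
  modal <- max.col(probs, ties.method = "first")
  meanpost <- vapply(seq_len(ncol(probs)), function(g) {
    idx <- modal == g
    if (!any(idx)) NA_real_ else mean(probs[idx, g])
  }, numeric(1))
  structure(list(probs = probs, modal_class = modal,
                 mean_posterior_by_class = meanpost),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("Posterior class memberships: %d subjects x %d classes\n",
              nrow(x$probs), ncol(x$probs)))
  cat("  modal counts:", paste(tabulate(x$modal_class, ncol(x$probs)),
                               collapse = " "), "\n")
  cat("  mean posterior (modal):",
      paste(sprintf("%.3f", x$mean_posterior_by_class), collapse = " "), "\n")
  invisible(x)
}

#' Predicted class mean trajectories
#'
#' Evaluates each class's quadratic mean curve over an age grid, on the
#' transformed `log(x+1)` scale and on the natural grams/day scale via the
#' plug-in back-transform `exp(y) - 1` (a mean-curve back-transform, not the
#' expectation of the back-transformed distribution). Ages outside the
#' extrapolation guard trigger a warning, not an error.
#'
#' @param object A `traj_lcmm` fit.
#' @param ages Age grid in years (default `seq(20, 65)`).
#' @param guard Extrapolation guard interval (default `c(18, 70)`).
#' @param ... Unused.
#' @return Data frame with `class`, `age`, `t`, `transformed`, `natural`.
#' @export
predict.traj_lcmm <- function(object, ages = seq(20, 65), guard = c(18, 70),
                              ...) {
  if (any(ages < guard[1] | ages > guard[2])) {
    warning("ages outside the extrapolation guard [", guard[1], ", ",
            guard[2], "] years")
  }
  t1 <- rescale_age(ages)
  X <- cbind(1, t1, t1^2)
  out <- do.call(rbind, lapply(seq_len(object$n_classes), function(g) {
    yhat <- drop(X %*% object$beta[g, ])
    data.frame(class = g, age = ages, t = t1, transformed = yhat,
               natural = inverse_transform_intake(yhat))
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.traj_lcmm <- function(x, ages = seq(20, 65), natural = TRUE, ...) {
  pred <- predict(x, ages = ages)
  ycol <- if (natural) "natural" else "transformed"
  yl <- if (natural) "alcohol intake (g/day)" else "log(intake + 1)"
  ym <- split(pred[[ycol]], pred$class)
  graphics::matplot(ages, do.call(cbind, ym), type = "l", lty = 1, lwd = 2,
                    xlab = "age (years)", ylab = yl,
                    main = sprintf("%d-class mean trajectories", x$n_classes),
                    ...)
  graphics::legend("topleft", bty = "n", lwd = 2, col = seq_len(x$n_classes),
                   legend = sprintf("class %d (%.1f%%)",
                                    seq_len(x$n_classes), 100 * x$shares))
  invisible(pred)
}

#' Simulate intake data from a fitted LCMM
#'
#' Draws new cohorts from the fitted mixture: class labels from the fitted
#' shares, random effects from the fitted covariance, residual noise at the
#' fitted SD, using the measurement ages of the training subjects.
#'
#' @param object A `traj_lcmm` fit.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` intake data frames.
#' @export
simulate.traj_lcmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ld <- object$data
  G <- object$n_classes
  L <- object$re_cholesky
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    cls <- sample.int(G, ld$n, replace = TRUE, prob = object$shares)
    b <- matrix(stats::rnorm(ld$n * 3), ld$n, 3) %*% t(L)
    i <- ld$obs$subject
    t1 <- ld$obs$t
    y <- object$beta[cls[i], 1] + b[i, 1] +
      (object$beta[cls[i], 2] + b[i, 2]) * t1 +
      (object$beta[cls[i], 3] + b[i, 3]) * t1^2 +
      stats::rnorm(nrow(ld$obs), sd = object$residual_sd)
    out[[s]] <- data.frame(subject_id = ld$ids[i],
                           age_years = unscale_age(t1),
                           intake_g_day = inverse_transform_intake(y),
                           stringsAsFactors = FALSE)
  }
  if (nsim == 1) out[[1]] else out
}

# Empirical-Bayes conditional random-effect means, one n x 3 matrix per class,
# plus posterior weights.
lcmm_eb <- function(fit) {
  comp <- lcmm_logdens(fit$data, fit$beta, fit$re_covariance,
                       fit$residual_sd^2, estep = TRUE)
  lp <- sweep(comp$logdens, 2, log(fit$shares), "+")
  W <- exp(lp - logsumexp_rows(lp))
  list(m = comp$m, W = W)
}

#' Empirical-Bayes random-effect estimates
#'
#' Posterior-weighted conditional means of the subject random effects,
#' `sum_g p_ig E[b_i | Y_i, g]`.
#'
#' @param fit A `traj_lcmm` fit.
#' @return N x 3 matrix (intercept, slope, quadratic deviations).
#' @export
ranef_lcmm <- function(fit) {
  eb <- lcmm_eb(fit)
  out <- matrix(0, fit$data$n, 3)
  for (g in seq_len(fit$n_classes)) out <- out + eb$W[, g] * eb$m[[g]]
  rownames(out) <- fit$data$ids
  colnames(out) <- c("intercept", "slope", "quadratic")
  out
}

#' @export
residuals.traj_lcmm <- function(object, ...) {
  eb <- lcmm_eb(object)
  i <- object$data$obs$subject
  t1 <- object$data$obs$t
  X <- cbind(1, t1, t1^2)
  fitted_w <- numeric(nrow(X))
  for (g in seq_len(object$n_classes)) {
    pred_g <- drop(X %*% object$beta[g, ]) + rowSums(X * eb$m[[g]][i, , drop = FALSE])
    fitted_w <- fitted_w + eb$W[i, g] * pred_g
  }
  object$data$obs$y - fitted_w
}

#' Weighted observed vs. predicted trajectory diagnostic
#'
#' Goodness-of-fit table comparing, per latent class and age bin, the
#' posterior-probability-weighted mean of the observed transformed intakes
#' with the weighted mean of the subject-specific predictions (class fixed
#' effects plus empirical-Bayes random effects). Empty bins are omitted.
#'
#' @param fit A `traj_lcmm` fit.
#' @param age_breaks Bin edges in years (default 5-year bins spanning the
#'   data).
#' @return Data frame with `class`, `age_bin`, `age_mid`, `n_obs`, `weight`,
#'   `observed`, `predicted` (transformed scale).
#' @export
weighted_fit_diagnostic <- function(fit, age_breaks = NULL) {
  stopifnot(inherits(fit, "traj_lcmm"))
  obs <- fit$data$obs
  age <- unscale_age(obs$t)
  if (is.null(age_breaks)) {
    age_breaks <- seq(floor(min(age) / 5) * 5, ceiling(max(age) / 5) * 5, by = 5)
  }
  bin <- cut(age, age_breaks, include.lowest = TRUE)
  empty <- levels(bin)[tabulate(bin, nlevels(bin)) == 0]
  if (length(empty) > 0) {
    message("omitting empty age bin(s): ", paste(empty, collapse = ", "))
  }
  eb <- lcmm_eb(fit)
  i <- obs$subject
  X <- cbind(1, obs$t, obs$t^2)
  rows <- list()
  for (g in seq_len(fit$n_classes)) {
    w <- eb$W[i, g]
    pred <- drop(X %*% fit$beta[g, ]) + rowSums(X * eb$m[[g]][i, , drop = FALSE])
    for (lev in levels(bin)) {
      idx <- !is.na(bin) & bin == lev
      wsum <- sum(w[idx])
      if (!any(idx) || wsum <= 0) next
      e <- range(age[idx])
      rows[[length(rows) + 1]] <- data.frame(
        class = g, age_bin = lev, age_mid = mean(e), n_obs = sum(idx),
        weight = wsum,
        observed = sum(w[idx] * obs$y[idx]) / wsum,
        predicted = sum(w[idx] * pred[idx]) / wsum)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permute latent class labels of a fitted model
#'
#' Estimation is label-agnostic; this explicit utility reorders classes for
#' presentation (the fitted model itself is never silently relabelled).
#'
#' @param fit A `traj_lcmm` fit.
#' @param perm Permutation of `1:G`: new class `k` is old class `perm[k]`.
#' @return The relabelled fit.
#' @seealso [order_classes_by_intake()]
#' @export
relabel_classes <- function(fit, perm) {
  stopifnot(inherits(fit, "traj_lcmm"),
            length(perm) == fit$n_classes,
            all(sort(perm) == seq_len(fit$n_classes)))
  fit$beta <- fit$beta[perm, , drop = FALSE]
  fit$shares <- fit$shares[perm]
  G <- fit$n_classes
  fit$membership_logits <- if (G > 1) log(fit$shares[-G] / fit$shares[G]) else numeric(0)
  fit$theta <- lcmm_pack(fit$beta, fit$membership_logits, fit$re_cholesky,
                         fit$residual_sd)
  fit$relabelled <- perm
  fit
}

#' Presentation ordering of classes by predicted intake at a reference age
#'
#' @param fit A `traj_lcmm` fit.
#' @param age Reference age in years (default 50).
#' @param decreasing Order from highest to lowest intake (default `TRUE`).
#' @return Permutation usable with [relabel_classes()].
#' @export
order_classes_by_intake <- function(fit, age = 50, decreasing = TRUE) {
  t1 <- rescale_age(age)
  val <- drop(fit$beta %*% c(1, t1, t1^2))
  order(val, decreasing = decreasing)
}

#' Serialize a fitted LCMM to JSON
#'
#' Writes all parameters, the start log-likelihood trace and seeds, so a fit
#' can be archived alongside the run manifest.
#'
#' @param fit A `traj_lcmm` fit.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_lcmm_json <- function(fit, path) {
  out <- list(
    n_classes = fit$n_classes, n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    beta = unname(split(fit$beta, row(fit$beta))),
    shares = fit$shares, membership_logits = fit$membership_logits,
    re_covariance = unname(split(fit$re_covariance, row(fit$re_covariance))),
    residual_sd = fit$residual_sd, loglik = fit$loglik,
    n_params = fit$n_params, converged = fit$converged,
    n_starts_used = fit$n_starts_used, best_start = fit$best_start,
    start_logliks = fit$start_logliks, seed = fit$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
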