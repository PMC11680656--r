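#' @export
print.lc_hazard <- function(x, ...) {
  cat(sprintf("Latent-class proportional hazards (%s baseline, %s)\n",
              x$baseline_family, x$covariate_set))
  cat(sprintf("  %d subjects, %d events; logLik %.3f, AIC %.3f%s\n",
              x$n_subjects, x$n_events, x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$hr_table
  for (g in seq_len(nrow(tab))) {
    if (g == x$reference) {
      cat(sprintf("  class %d: HR 1.00 (reference)\n", g))
    } else {
      cat(sprintf("  class %d: HR %.2f (%.0f%% CI %.2f-%.2f)\n", g,
                  tab$hr[g], 100 * x$ci_level, tab$ci_low[g], tab$ci_high[g]))
    }
  }
  invisible(x)
}

#' @export
summary.lc_hazard <- function(object, ...) {
  object$gamma_table <- data.frame(
    term = names(object$gamma),
    estimate = unname(object$gamma),
    se = sqrt(diag(object$vcov))[object$G - 1 + seq_along(object$gamma)]
  )
  class(object) <- c("summary.lc_hazard", class(object))
  object
}

#' @export
print.summary.lc_hazard <- function(x, ...) {
  print.lc_hazard(x, ...)
  if (x$baseline_family == "weibull") {
    cat(sprintf("  baseline: Weibull shape %.3f, scale %.2f\n",
                x$baseline$shape, x$baseline$scale))
  } else {
    cat(sprintf("  baseline: cubic M-spline, knots at %s\n",
                paste(sprintf("%.1f", x$knots), collapse = ", ")))
  }
  if (nrow(x$gamma_table) > 0) {
    cat("\nCovariate effects (log hazard):\n")
    print(transform(x$gamma_table, estimate = round(estimate, 4),
                    se = round(se, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.lc_hazard <- function(object, ...) {
  c(stats::setNames(object$xi, paste0("class", seq_along(object$xi))),
    object$gamma)
}

#' @export
logLik.lc_hazard <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
vcov.lc_hazard <- function(object, ...) object$vcov

#' @export
confint.lc_hazard <- function(object, parm, level = 0.95, ...) {
  tab <- object$hr_table
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(low = exp(tab$log_hr - z * tab$se),
               high = exp(tab$log_hr + z * tab$se))
  rownames(out) <- paste0("class", tab$class)
  out
}

#' Predicted baseline hazard curve
#' @param object An `lc_hazard` fit.
#' @param ages Evaluation ages (default: 200-point grid over the data range
#'   for splines, 50-90 for Weibull).
#' @param ... Unused.
#' @return Data frame with `age`, `hazard`, `cumhaz`.
#' @export
predict.lc_hazard <- function(object, ages = NULL, ...) {
  if (is.null(ages)) {
    rng <- if (object$baseline_family == "mspline") range(object$knots)
           else c(50, 90)
    ages <- seq(rng[1], rng[2], length.out = 200)
  }
  bl <- baseline_pieces(object$baseline, ages, rep(ages[1], length(ages)))
  data.frame(age = ages, hazard = bl$h0T, cumhaz = bl$H0T)
}

#' @export
plot.lc_hazard <- function(x, ...) {
  pr <- predict(x)
  graphics::plot(pr$age, pr$hazard, type = "l", lwd = 2,
                 xlab = "age (years)", ylab = "baseline hazard",
                 main = sprintf("%s baseline hazard", x$baseline_family), ...)
  invisible(pr)
}

#' Compare baseline-hazard specifications by AIC
#'
#' Given hazard fits estimated on identical data (checked through the sorted
#' subject-id fingerprint), returns the minimum-AIC fit and the comparison
#' table; exact AIC ties go to the first-listed fit with a note.
#'
#' @param fits List of `lc_hazard` fits.
#' @return Object of class `baseline_comparison`: list with `chosen`,
#'   `table`, `tie`.
#' @export
compare_baselines <- function(fits) {
  stopifnot(length(fits) >= 1)
  lapply(fits, function(f) stopifnot(inherits(f, "lc_hazard")))
  ids <- lapply(fits, `[[`, "ids")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    stop("fits were estimated on different data (subject-id mismatch)")
  }
  label <- vapply(fits, function(f) {
    if (f$baseline_family == "mspline") {
      sprintf("mspline-%dknots", length(f$knots))
    } else "weibull"
  }, character(1))
  tab <- data.frame(
    model = label,
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  best <- which(tab$aic == min(tab$aic))
  tie <- length(best) > 1
  structure(list(chosen = fits[[best[1]]], table = tab, tie = tie),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat("Baseline hazard comparison (AIC)\n")
  print(format(x$table, digits = 7), row.names = FALSE)
  cat(sprintf("chosen: %s%s\n",
              x$table$model[which.min(x$table$aic)],
              if (x$tie) " (AIC tie; first listed wins)" else ""))
  invisible(x)
}

#' Write the hazard-ratio table to CSV
#'
#' One row per class: size, events, HR, CI bounds — the layout of a
#' per-model association table.
#'
#' @param fit An `lc_hazard` fit.
#' @param path Output file.
#' @export
write_hr_table <- function(fit, path) {
  utils::write.csv(fit$hr_table, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a hazard fit to JSON
#' @param fit An `lc_hazard` fit.
#' @param path Output file.
#' @export
write_hazard_json <- function(fit, path) {
  out <- list(
    baseline_family = fit$baseline_family, covariate_set = fit$covariate_set,
    xi = fit$xi, gamma = as.list(fit$gamma),
    baseline = fit$baseline[setdiff(names(fit$baseline), "family")],
    loglik = fit$loglik, aic = fit$aic, n_params = fit$n_params,
    reference = fit$reference, n_subjects = fit$n_subjects,
    n_events = fit$n_events, converged = fit$converged,
    hr_table = fit$hr_table
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
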