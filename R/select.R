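# Model-selection criteria for the number of latent classes.

#' Bayesian information criterion for a mixture of subjects
#'
#' `-2 loglik + n_params log(N)` with N the number of subjects (not
#' measurements), the convention for subject-level mixture models.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_subjects Number of subjects.
#' @export
mixture_bic <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1)
  -2 * loglik + n_params * log(n_subjects)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_i sum_g -p_ig log p_ig / (N log G)`, with `0 log 0 = 0`.
#' Equals 1 for a perfectly separated (0/1) classification and 0 for a
#' completely uninformative (uniform) one. Undefined for G = 1.
#'
#' @param posteriors N x G posterior matrix, or a `posterior_matrix`.
#' @export
relative_entropy <- function(posteriors) {
  P <- if (inherits(posteriors, "posterior_matrix")) posteriors$probs else posteriors
  G <- ncol(P)
  if (G < 2) stop("entropy is undefined for a single class")
  pl <- P * log(P)
  pl[P == 0] <- 0
  1 - sum(-pl) / (nrow(P) * log(G))
}

#' Integrated classification likelihood criterion
#'
#' Classification-penalized BIC: `BIC - 2 sum_i log p_{i,modal(i)}`. The
#' penalty term is non-negative, so `ICL >= BIC`, with equality for a
#' perfectly certain classification.
#'
#' @param bic_value BIC of the candidate model.
#' @param posteriors N x G posterior matrix, or a `posterior_matrix`.
#' @export
icl <- function(bic_value, posteriors) {
  P <- if (inherits(posteriors, "posterior_matrix")) posteriors$probs else posteriors
  modal <- max.col(P, ties.method = "first")
  bic_value - 2 * sum(log(P[cbind(seq_len(nrow(P)), modal)]))
}

#' Selection-criteria table over candidate class numbers
#'
#' Computes, for each candidate fit, the log-likelihood, parameter count,
#' BIC, ICL, relative entropy, class shares, smallest class share and
#' per-class mean posterior probability.
#'
#' @param fits List of `traj_lcmm` fits (possibly different G).
#' @return Data frame, one row per candidate, with list-columns `shares` and
#'   `mean_posterior`.
#' @export
selection_report <- function(fits) {
  stopifnot(length(fits) >= 1)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "traj_lcmm"))
    post <- posterior_probs(f)
    b <- mixture_bic(f$loglik, f$n_params, f$n_subjects)
    data.frame(
      G = f$n_classes, loglik = f$loglik, n_params = f$n_params,
      bic = b,
      icl = icl(b, post),
      entropy = if (f$n_classes > 1) relative_entropy(post) else NA_real_,
      smallest_share = min(f$shares),
      min_mean_posterior = min(post$mean_posterior_by_class, na.rm = TRUE),
      shares = I(list(f$shares)),
      mean_posterior = I(list(post$mean_posterior_by_class)))
  })
  do.call(rbind, rows)
}

#' Choose the number of latent classes
#'
#' Applies the selection rules: candidates with any class smaller than
#' `min_share` of the subjects, or any class whose mean posterior probability
#' among modally assigned subjects falls below `min_mean_posterior`, are
#' discarded; among the survivors the lowest BIC wins (ICL and entropy are
#' always reported, and the trace records what each criterion preferred).
#'
#' @param fits List of `traj_lcmm` fits, or a [selection_report()] table.
#' @param min_share Smallest admissible class share (default 0.05).
#' @param min_mean_posterior Smallest admissible per-class mean posterior
#'   (default 0.75).
#' @return Object of class `lcmm_selection`: list with `chosen_G`, `table`,
#'   `trace` (character vector of rule decisions).
#' @export
select_n_classes <- function(fits, min_share = 0.05, min_mean_posterior = 0.75) {
  report <- if (is.data.frame(fits)) fits else selection_report(fits)
  stopifnot(nrow(report) >= 1)
  trace <- character(0)
  ok <- rep(TRUE, nrow(report))
  for (i in seq_len(nrow(report))) {
    if (report$smallest_share[i] < min_share) {
      ok[i] <- FALSE
      trace <- c(trace, sprintf(
        "G = %d discarded: smallest class share %.1f%% < %.0f%%",
        report$G[i], 100 * report$smallest_share[i], 100 * min_share))
    } else if (report$G[i] > 1 &&
               report$min_mean_posterior[i] < min_mean_posterior) {
      ok[i] <- FALSE
      trace <- c(trace, sprintf(
        "G = %d discarded: mean posterior %.2f below %.2f in some class",
        report$G[i], report$min_mean_posterior[i], min_mean_posterior))
    }
  }
  if (!any(ok)) {
    stop("all candidates violate the selection rules:\n  ",
         paste(trace, collapse = "\n  "))
  }
  surv <- report[ok, ]
  chosen <- surv$G[which.min(surv$bic)]
  trace <- c(trace,
             sprintf("BIC prefers G = %d among survivors", chosen),
             sprintf("ICL prefers G = %d among survivors",
                     surv$G[which.min(surv$icl)]),
             sprintf("chosen: G = %d (lowest BIC among admissible candidates)",
                     chosen))
  structure(list(chosen_G = chosen, table = report, trace = trace,
                 min_share = min_share,
                 min_mean_posterior = min_mean_posterior),
            class = "lcmm_selection")
}

#' @export
print.lcmm_selection <- function(x, ...) {
  cat("Latent class number selection\n")
  tab <- x$table[, c("G", "loglik", "n_params", "bic", "icl", "entropy",
                     "smallest_share", "min_mean_posterior")]
  print(format(tab, digits = 6), row.names = FALSE)
  cat("\n", paste(x$trace, collapse = "\n "), "\n", sep = "")
  cat(sprintf("\nChosen number of classes: %d\n", x$chosen_G))
  invisible(x)
}

#' Serialize a selection report to JSON
#' @param selection An `lcmm_selection`.
#' @param path Output file.
#' @export
write_selection_json <- function(selection, path) {
  tab <- selection$table
  out <- list(
    chosen_G = selection$chosen_G,
    trace = selection$trace,
    candidates = lapply(seq_len(nrow(tab)), function(i) list(
      G = tab$G[i], loglik = tab$loglik[i], n_params = tab$n_params[i],
      bic = tab$bic[i], icl = tab$icl[i], entropy = tab$entropy[i],
      shares = tab$shares[[i]], mean_posterior = tab$mean_posterior[[i]]))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
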