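# Likelihood machinery for the latent class mixed model.
#
# Model: for subject i in class g, transformed intakes
#   Y_i | g ~ N(X_i beta_g, V_i),  V_i = Z_i B Z_i' + sigma^2 I,
# with X_i = Z_i = [1, t, t^2] rows at the subject's rescaled measurement
# ages. The marginal likelihood only needs, per subject, the sufficient
# statistics k_i, y'y, Z'y (3-vector) and S_i = Z'Z (symmetric 3x3), so all
# N subjects are evaluated with vectorized arithmetic regardless of their
# individual measurement ages; the 3x3 determinants/inverses use closed-form
# adjugates on columns of an n x 6 array (order s11 s12 s13 s22 s23 s33).

#' Prepare intake records for latent-class estimation
#'
#' Transforms intakes with [transform_intake()], rescales ages with
#' [rescale_age()], and precomputes the per-subject sufficient statistics
#' used by the marginal likelihood.
#'
#' @param intakes Long-format data frame with `subject_id`, `age_years`,
#'   `intake_g_day`.
#' @return Object of class `lcmm_data`.
#' @export
lcmm_data <- function(intakes) {
  req <- c("subject_id", "age_years", "intake_g_day")
  if (!all(req %in% names(intakes))) {
    stop("intakes must have columns ", paste(req, collapse = ", "))
  }
  ok <- !is.na(intakes$intake_g_day) & !is.na(intakes$age_years)
  intakes <- intakes[ok, ]
  if (any(intakes$age_years <= 10 | intakes$age_years >= 110)) {
    stop("ages must lie in (10, 110) years")
  }
  id <- factor(intakes$subject_id, levels = unique(intakes$subject_id))
  y <- transform_intake(intakes$intake_g_day)
  t1 <- rescale_age(intakes$age_years)
  t2 <- t1^2

  k <- as.vector(table(id))
  if (any(k < 1)) stop("every subject needs at least one measurement")
  yty <- as.vector(rowsum(y * y, id))
  Zty <- cbind(as.vector(rowsum(y, id)),
               as.vector(rowsum(y * t1, id)),
               as.vector(rowsum(y * t2, id)))
  S <- cbind(k,
             as.vector(rowsum(t1, id)),
             as.vector(rowsum(t2, id)),
             as.vector(rowsum(t1 * t1, id)),
             as.vector(rowsum(t1 * t2, id)),
             as.vector(rowsum(t2 * t2, id)))
  colnames(S) <- c("s11", "s12", "s13", "s22", "s23", "s33")

  structure(list(
    ids = levels(id), n = nlevels(id), n_obs = length(y),
    k = k, yty = yty, Zty = Zty, S = S,
    obs = data.frame(subject = as.integer(id), t = t1, y = y)
  ), class = "lcmm_data")
}

# closed-form determinant of symmetric 3x3 stored as n x 6 columns
sym3_det <- function(m) {
  m[, 1] * (m[, 4] * m[, 6] - m[, 5]^2) -
    m[, 2] * (m[, 2] * m[, 6] - m[, 3] * m[, 5]) +
    m[, 3] * (m[, 2] * m[, 5] - m[, 4] * m[, 3])
}

# closed-form inverse (adjugate/det), n x 6 in, n x 6 out
sym3_inv <- function(m, det = sym3_det(m)) {
  cbind((m[, 4] * m[, 6] - m[, 5]^2) / det,
        (m[, 3] * m[, 5] - m[, 2] * m[, 6]) / det,
        (m[, 2] * m[, 5] - m[, 3] * m[, 4]) / det,
        (m[, 1] * m[, 6] - m[, 3]^2) / det,
        (m[, 2] * m[, 3] - m[, 1] * m[, 5]) / det,
        (m[, 1] * m[, 4] - m[, 2]^2) / det)
}

# quadratic form u' A u for symmetric A (n x 6) and u (n x 3)
sym3_quad <- function(a, u) {
  a[, 1] * u[, 1]^2 + a[, 4] * u[, 2]^2 + a[, 6] * u[, 3]^2 +
    2 * (a[, 2] * u[, 1] * u[, 2] + a[, 3] * u[, 1] * u[, 3] +
           a[, 5] * u[, 2] * u[, 3])
}

# matrix-vector product A u for symmetric A (n x 6), u (n x 3)
sym3_mv <- function(a, u) {
  cbind(a[, 1] * u[, 1] + a[, 2] * u[, 2] + a[, 3] * u[, 3],
        a[, 2] * u[, 1] + a[, 4] * u[, 2] + a[, 5] * u[, 3],
        a[, 3] * u[, 1] + a[, 5] * u[, 2] + a[, 6] * u[, 3])
}

# Per-class Gaussian log-densities for all subjects.
# Returns list(logdens = n x G, and E-step byproducts when estep = TRUE).
lcmm_logdens <- function(ldata, beta, B, sigma2, estep = FALSE) {
  G <- nrow(beta)
  n <- ldata$n
  S <- ldata$S

  cB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cB)) stop("random-effect covariance must be positive definite")
  logdetB <- 2 * sum(log(diag(cB)))
  P <- chol2inv(cB)
  Pv <- c(P[1, 1], P[1, 2], P[1, 3], P[2, 2], P[2, 3], P[3, 3])

  M <- sweep(S / sigma2, 2, Pv, "+")
  detM <- sym3_det(M)
  Minv <- sym3_inv(M, detM)
  logdetV <- ldata$k * log(sigma2) + logdetB + log(detM)

  logdens <- matrix(0, n, G)
  m_list <- if (estep) vector("list", G) else NULL
  base <- ldata$k * log(2 * pi) + logdetV
  for (g in seq_len(G)) {
    b <- beta[g, ]
    u1 <- ldata$Zty[, 1] - (S[, 1] * b[1] + S[, 2] * b[2] + S[, 3] * b[3])
    u2 <- ldata$Zty[, 2] - (S[, 2] * b[1] + S[, 4] * b[2] + S[, 5] * b[3])
    u3 <- ldata$Zty[, 3] - (S[, 3] * b[1] + S[, 5] * b[2] + S[, 6] * b[3])
    rtr <- ldata$yty - 2 * (ldata$Zty[, 1] * b[1] + ldata$Zty[, 2] * b[2] +
                              ldata$Zty[, 3] * b[3]) +
      (S[, 1] * b[1]^2 + S[, 4] * b[2]^2 + S[, 6] * b[3]^2 +
         2 * (S[, 2] * b[1] * b[2] + S[, 3] * b[1] * b[3] + S[, 5] * b[2] * b[3]))
    uMu <- Minv[, 1] * u1^2 + Minv[, 4] * u2^2 + Minv[, 6] * u3^2 +
      2 * (Minv[, 2] * u1 * u2 + Minv[, 3] * u1 * u3 + Minv[, 5] * u2 * u3)
    quad <- rtr / sigma2 - uMu / sigma2^2
    logdens[, g] <- -0.5 * (base + quad)
    if (estep) m_list[[g]] <- sym3_mv(Minv, cbind(u1, u2, u3)) / sigma2
  }
  out <- list(logdens = logdens)
  if (estep) {
    out$m <- m_list            # conditional random-effect means per class
    out$Cinv <- Minv           # conditional covariance C_i = M_i^{-1}
  }
  out
}

logsumexp_rows <- function(x) {
  m <- x[, 1]
  for (g in seq_len(ncol(x))[-1]) m <- pmax(m, x[, g])
  m + log(rowSums(exp(x - m)))
}

# Observed-data log-likelihood and posterior pieces.
lcmm_loglik <- function(ldata, beta, shares, B, sigma2) {
  ld <- lcmm_logdens(ldata, beta, B, sigma2)$logdens
  lp <- sweep(ld, 2, log(shares), "+")
  sum(logsumexp_rows(lp))
}

#' Per-class log-densities and marginal log-likelihood for one subject
#'
#' Computes, for a single subject's transformed intakes, the multivariate
#' normal log-density under each latent class (mean `X beta_g`, covariance
#' `Z B Z' + sigma^2 I` with `X = Z = [1, t, t^2]`) and the marginal mixture
#' log-likelihood `log sum_g pi_g f_g` evaluated with log-sum-exp. This
#' direct dense evaluation is deliberately independent of the vectorized
#' machinery used in fitting and accepts singular-but-valid covariances
#' (e.g. `B = 0`) as long as the total covariance is positive definite.
#'
#' @param ages Measurement ages in years.
#' @param intakes Intakes in grams/day at those ages.
#' @param beta G x 3 matrix of class fixed effects (transformed scale).
#' @param shares Class probabilities (sum to 1).
#' @param re_covariance 3 x 3 random-effect covariance.
#' @param residual_sd Residual SD, > 0 unless `re_covariance` makes the total
#'   covariance positive definite.
#' @return List with `class_logdens` (length G) and `marginal`.
#' @export
subject_loglik <- function(ages, intakes, beta, shares, re_covariance,
                           residual_sd) {
  if (length(ages) < 1 || length(ages) != length(intakes)) {
    stop("need at least one measurement, with matching ages and intakes")
  }
  beta <- as.matrix(beta)
  t1 <- rescale_age(ages)
  Z <- cbind(1, t1, t1^2)
  V <- Z %*% re_covariance %*% t(Z) + diag(residual_sd^2, length(ages))
  cV <- tryCatch(chol(V), error = function(e) {
    stop("singular within-subject covariance (residual_sd = 0 with degenerate ",
         "random-effect covariance)")
  })
  y <- transform_intake(intakes)
  logdet <- 2 * sum(log(diag(cV)))
  ld <- vapply(seq_len(nrow(beta)), function(g) {
    r <- y - drop(Z %*% beta[g, ])
    w <- backsolve(cV, r, transpose = TRUE)
    -0.5 * (length(y) * log(2 * pi) + logdet + sum(w^2))
  }, numeric(1))
  lp <- ld + log(shares)
  m <- max(lp)
  list(class_logdens = ld, marginal = m + log(sum(exp(lp - m))))
}
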