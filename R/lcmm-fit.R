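# Estimation of the latent class mixed model: EM warm-up with closed-form
# M-steps, followed by quasi-Newton refinement of the full parameter vector
# under constraint-enforcing reparameterizations (Cholesky factor with
# log-diagonals for the random-effect covariance, log residual SD, softmax
# membership logits with the last class as reference).

lcmm_n_params <- function(G) 3 * G + (G - 1) + 6 + 1

# parameter list <-> unconstrained vector
lcmm_pack <- function(beta, logits, L, sigma) {
  c(as.vector(t(beta)), logits,
    log(L[1, 1]), L[2, 1], L[3, 1], log(L[2, 2]), L[3, 2], log(L[3, 3]),
    log(sigma))
}

lcmm_unpack <- function(theta, G) {
  beta <- matrix(theta[seq_len(3 * G)], G, 3, byrow = TRUE)
  logits <- if (G > 1) theta[3 * G + seq_len(G - 1)] else numeric(0)
  lpar <- theta[3 * G + (G - 1) + 1:6]
  L <- matrix(0, 3, 3)
  L[1, 1] <- exp(lpar[1]); L[2, 1] <- lpar[2]; L[3, 1] <- lpar[3]
  L[2, 2] <- exp(lpar[4]); L[3, 2] <- lpar[5]; L[3, 3] <- exp(lpar[6])
  sigma <- exp(theta[3 * G + (G - 1) + 7])
  el <- c(logits, 0)
  shares <- exp(el - max(el)); shares <- shares / sum(shares)
  list(beta = beta, logits = logits, shares = shares, L = L,
       B = L %*% t(L), sigma = sigma)
}

lcmm_objective <- function(theta, ldata, G) {
  p <- lcmm_unpack(theta, G)
  ll <- tryCatch(lcmm_loglik(ldata, p$beta, p$shares, p$B, p$sigma^2),
                 error = function(e) NA_real_)
  if (!is.finite(ll)) return(1e10)
  -ll
}

# One EM pass; returns updated parameters and current log-likelihood.
lcmm_em_step <- function(ldata, beta, shares, B, sigma2) {
  G <- nrow(beta)
  comp <- lcmm_logdens(ldata, beta, B, sigma2, estep = TRUE)
  lp <- sweep(comp$logdens, 2, log(shares), "+")
  lse <- logsumexp_rows(lp)
  W <- exp(lp - lse)
  ll <- sum(lse)
  S <- ldata$S

  shares_new <- colMeans(W)
  shares_new <- pmax(shares_new, 1e-12); shares_new <- shares_new / sum(shares_new)

  beta_new <- beta
  sse <- 0
  mm_sum <- matrix(0, 3, 3)
  for (g in seq_len(G)) {
    w <- W[, g]
    m <- comp$m[[g]]
    Sm <- sym3_mv(S, m)
    A <- matrix(0, 3, 3)
    A[1, 1] <- sum(w * S[, 1]); A[1, 2] <- A[2, 1] <- sum(w * S[, 2])
    A[1, 3] <- A[3, 1] <- sum(w * S[, 3]); A[2, 2] <- sum(w * S[, 4])
    A[2, 3] <- A[3, 2] <- sum(w * S[, 5]); A[3, 3] <- sum(w * S[, 6])
    rhs <- colSums(w * (ldata$Zty - Sm))
    beta_new[g, ] <- solve(A, rhs)

    b <- beta_new[g, ]
    u <- ldata$Zty - sym3_mv(S, matrix(b, ldata$n, 3, byrow = TRUE))
    rtr <- ldata$yty - 2 * drop(ldata$Zty %*% b) +
      (S[, 1] * b[1]^2 + S[, 4] * b[2]^2 + S[, 6] * b[3]^2 +
         2 * (S[, 2] * b[1] * b[2] + S[, 3] * b[1] * b[3] + S[, 5] * b[2] * b[3]))
    # ||y - X b - Z m||^2 = r'r - 2 u'm + m'S m
    fit2 <- rtr - 2 * rowSums(u * m) + sym3_quad(S, m)
    trSC <- S[, 1] * comp$Cinv[, 1] + S[, 4] * comp$Cinv[, 4] +
      S[, 6] * comp$Cinv[, 6] +
      2 * (S[, 2] * comp$Cinv[, 2] + S[, 3] * comp$Cinv[, 3] +
             S[, 5] * comp$Cinv[, 5])
    sse <- sse + sum(w * (fit2 + trSC))
    mm_sum <- mm_sum + crossprod(sqrt(w) * m)
  }
  # C_i is class-free; sum over subjects once (class weights sum to 1)
  Csum <- colSums(comp$Cinv)
  Cmat <- matrix(c(Csum[1], Csum[2], Csum[3],
                   Csum[2], Csum[4], Csum[5],
                   Csum[3], Csum[5], Csum[6]), 3, 3)
  B_new <- (mm_sum + Cmat) / ldata$n
  B_new <- (B_new + t(B_new)) / 2
  sigma2_new <- sse / ldata$n_obs

  list(beta = beta_new, shares = shares_new, B = B_new,
       sigma2 = max(sigma2_new, 1e-10), loglik = ll)
}

# EM iterations from an initial parameter list; returns state + loglik trace.
lcmm_em_run <- function(ldata, G, init, max_iter, rel_tol) {
  beta <- init$beta; shares <- init$shares
  B <- init$B; sigma2 <- init$sigma^2
  ll_prev <- -Inf
  iters <- 0
  converged_em <- FALSE
  for (it in seq_len(max_iter)) {
    st <- tryCatch(lcmm_em_step(ldata, beta, shares, B, sigma2),
                   error = function(e) NULL)
    if (is.null(st)) break
    iters <- it
    beta <- st$beta; shares <- st$shares; B <- st$B; sigma2 <- st$sigma2
    if (is.finite(ll_prev) &&
        abs(st$loglik - ll_prev) < rel_tol * (abs(ll_prev) + 1)) {
      converged_em <- TRUE
      ll_prev <- st$loglik
      break
    }
    ll_prev <- st$loglik
  }
  list(beta = beta, shares = shares, B = B, sigma = sqrt(sigma2),
       loglik = ll_prev, iterations = iters, converged_em = converged_em)
}

# EM warm-up followed by nlminb refinement from one set of initial values.
lcmm_fit_single <- function(ldata, G, init, control) {
  # EM does the bulk of the climb (closed-form steps are cheap); the
  # quasi-Newton pass then only polishes
  em_tol <- if (is.null(control$em_tol)) control$rel_tol else control$em_tol
  em <- lcmm_em_run(ldata, G, init, control$em_iter, em_tol)
  # guard: EM may have collapsed B towards singularity
  B <- em$B + diag(1e-8, 3)
  L <- t(chol(B))
  logits <- if (G > 1) log(em$shares[-G] / em$shares[G]) else numeric(0)
  theta <- lcmm_pack(em$beta, logits, L, em$sigma)
  iters <- em$iterations

  if (control$refine) {
    opt <- stats::nlminb(theta, lcmm_objective, ldata = ldata, G = G,
                         control = list(iter.max = control$max_iter,
                                        eval.max = 4 * control$max_iter,
                                        rel.tol = control$rel_tol))
    theta <- opt$par
    ll <- -opt$objective
    converged <- opt$convergence == 0 && is.finite(ll)
    if (!converged && is.finite(ll)) {
      # PORT may report "false convergence" on a flat optimum; accept when
      # the score is numerically zero relative to the log-likelihood scale
      g <- numeric_grad(function(th) lcmm_objective(th, ldata, G), theta)
      converged <- max(abs(g)) < control$grad_tol * max(1, abs(ll))
    }
    iters <- iters + opt$iterations
  } else {
    ll <- -lcmm_objective(theta, ldata, G)
    converged <- is.finite(ll) && em$converged_em
  }
  p <- lcmm_unpack(theta, G)
  list(theta = theta, params = p, loglik = ll, converged = converged,
       iterations = iters)
}

# Random starts around the 1-class solution. Class intercepts are anchored
# at randomly permuted Gaussian quantiles of the subject intercept
# distribution (so every start straddles the heterogeneity the classes must
# explain), then all coefficients receive Gaussian jitter on the
# between-subject scale.
lcmm_random_start <- function(base, G, scatter, perturb_scale) {
  beta <- matrix(rep(base$beta[1, ], each = G), G, 3)
  if (G > 1) {
    anchors <- stats::qnorm((sample.int(G) - 0.5) / G) *
      scatter[1] * perturb_scale
    beta[, 1] <- beta[, 1] + anchors
  }
  beta <- beta + matrix(stats::rnorm(G * 3), G, 3) *
    matrix(rep(0.4 * scatter, each = G), G, 3)
  list(beta = beta, shares = rep(1 / G, G), B = base$B, sigma = base$sigma)
}

# Warm start from a (G-1)-class fit: split the largest class.
lcmm_warm_start <- function(prev, G, scatter, perturb_scale) {
  big <- which.max(prev$shares)
  beta <- rbind(prev$beta,
                prev$beta[big, ] + stats::rnorm(3) * 0.5 * perturb_scale * scatter)
  shares <- c(prev$shares, prev$shares[big] / 2)
  shares[big] <- shares[big] / 2
  shares <- shares / sum(shares)
  list(beta = beta, shares = shares, B = prev$re_covariance,
       sigma = prev$residual_sd)
}

# Scatter scale for multistart perturbations: the between-subject SD of the
# 1-class fit (random-effect SDs, floored at a small constant). Classes are
# heterogeneous subgroups of subjects, so starts must be spread on the scale
# of the subject distribution, which does not shrink with n.
lcmm_start_scale <- function(fit1) {
  pmax(sqrt(diag(fit1$re_covariance)), c(0.1, 0.05, 0.02))
}

#' Fit a latent class mixed model to repeated intake measurements
#'
#' Maximum-likelihood estimation of a G-class mixture of linear mixed models
#' on the `log(x+1)` intake scale: class-specific quadratic mean trajectories
#' in rescaled age `t = (age-35)/13`, a shared subject-level random
#' intercept/slope/quadratic with unstructured covariance, homoscedastic
#' residuals, and an intercept-only multinomial membership model. Estimation
#' runs EM warm-up (closed-form posterior-weighted M-steps) followed by
#' quasi-Newton refinement of the full parameter vector, from multiple
#' starting points: random perturbations of the 1-class solution's fixed
#' effects (scale = `perturb_scale` times their asymptotic SEs) and, when a
#' `warm_start` fit with G-1 classes is supplied, a split of its largest
#' class. The best converged log-likelihood wins; ties go to the earliest
#' start.
#'
#' @param intakes Long-format intake records (`subject_id`, `age_years`,
#'   `intake_g_day`), or an [lcmm_data()] object.
#' @param n_classes Number of latent classes G >= 1.
#' @param n_starts Number of random starts (ignored for G = 1).
#' @param warm_start Optional `traj_lcmm` fit with `n_classes - 1` classes
#'   used to build an additional informed start.
#' @param start Optional explicit start: list with `beta` (G x 3), `shares`,
#'   `B`, `sigma`. Added to the start set.
#' @param base_fit Optional 1-class `traj_lcmm` fit to anchor the random
#'   starts (fitted internally when absent).
#' @param perturb_scale Multiplier on the between-subject (random-effect) SD
#'   of the 1-class fit used to spread the class-intercept anchors of the
#'   random starts (default 1.5; the scatter lives on the scale of the
#'   subject distribution, so starts stay spread regardless of sample size).
#' @param seed Seed for start generation (default 1).
#' @param control List: `em_iter` (EM warm-up cap, default 300), `max_iter`
#'   (quasi-Newton iteration cap, default 500), `rel_tol` (relative
#'   log-likelihood tolerance, default 1e-8), `refine` (run the quasi-Newton
#'   stage, default TRUE), `screen_iter` / `n_refine` (length of the short
#'   EM screening run given to every start, and how many of the best basins
#'   are then fully refined; defaults 40 and 4).
#' @return Object of class `traj_lcmm`.
#' @export
traj_lcmm <- function(intakes, n_classes = 1, n_starts = 100,
                      warm_start = NULL, start = NULL, base_fit = NULL,
                      perturb_scale = 1.5, seed = 1, control = list()) {
  ldata <- if (inherits(intakes, "lcmm_data")) intakes else lcmm_data(intakes)
  G <- as.integer(n_classes)
  stopifnot(G >= 1)
  ctrl <- utils::modifyList(
    list(em_iter = 600, max_iter = 500, rel_tol = 1e-8, refine = TRUE,
         screen_iter = 40, n_refine = 4, grad_tol = 1e-3),
    control)

  starts <- list()
  if (G == 1) {
    # pooled quadratic regression start
    fit0 <- stats::lm(y ~ t + I(t^2), data = ldata$obs)
    s2 <- mean(fit0$residuals^2)
    starts[[1]] <- list(beta = matrix(coef(fit0), 1, 3), shares = 1,
                        B = diag(c(s2 / 2, s2 / 8, s2 / 32)),
                        sigma = sqrt(s2 / 2))
  } else if (n_starts > 0 || !is.null(warm_start)) {
    if (is.null(base_fit)) {
      base_fit <- traj_lcmm(ldata, 1, control = ctrl)
    }
    base <- list(beta = base_fit$beta, shares = 1,
                 B = base_fit$re_covariance, sigma = base_fit$residual_sd)
    scatter <- lcmm_start_scale(base_fit)
    set.seed(seed)
    for (s in seq_len(n_starts)) {
      starts[[s]] <- lcmm_random_start(base, G, scatter, perturb_scale)
    }
    if (!is.null(warm_start)) {
      stopifnot(inherits(warm_start, "traj_lcmm"),
                nrow(warm_start$beta) == G - 1)
      starts[[length(starts) + 1]] <-
        lcmm_warm_start(warm_start, G, scatter, perturb_scale)
    }
  }
  if (!is.null(start)) starts[[length(starts) + 1]] <- start

  # screen-then-refine: every start gets a short EM run; only the most
  # promising basins (plus any explicit/warm starts) get the full EM +
  # quasi-Newton treatment
  if (length(starts) > ctrl$n_refine) {
    screen_ll <- vapply(starts, function(ini) {
      em <- tryCatch(lcmm_em_run(ldata, G, ini, ctrl$screen_iter, 1e-5),
                     error = function(e) NULL)
      if (is.null(em) || !is.finite(em$loglik)) -Inf else em$loglik
    }, numeric(1))
    keep <- utils::head(order(screen_ll, decreasing = TRUE), ctrl$n_refine)
    keep <- sort(unique(c(keep,
                          setdiff(seq_along(starts), seq_len(n_starts)))))
    refine_idx <- keep
  } else {
    screen_ll <- rep(NA_real_, length(starts))
    refine_idx <- seq_along(starts)
  }

  results <- rep(list(list(loglik = -Inf, converged = FALSE)), length(starts))
  results[refine_idx] <- lapply(starts[refine_idx], function(ini) {
    tryCatch(lcmm_fit_single(ldata, G, ini, ctrl),
             error = function(e) list(loglik = -Inf, converged = FALSE,
                                      error = conditionMessage(e)))
  })
  lls <- vapply(results, function(r) r$loglik, numeric(1))
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  if (!any(conv)) {
    stop(sprintf(
      "no start converged for G = %d (best non-converged log-likelihood: %.4f)",
      G, max(lls, na.rm = TRUE)))
  }
  cand <- which(conv)
  best_idx <- cand[which.max(lls[cand])]
  best <- results[[best_idx]]
  p <- best$params

  fit <- structure(list(
    beta = p$beta, shares = p$shares, membership_logits = p$logits,
    re_cholesky = p$L, re_covariance = p$B, residual_sd = p$sigma,
    loglik = best$loglik, n_params = lcmm_n_params(G),
    n_classes = G, n_subjects = ldata$n, n_obs = ldata$n_obs,
    converged = best$converged, iterations = best$iterations,
    n_starts_used = length(starts), best_start = best_idx,
    start_logliks = lls, start_converged = conv,
    theta = best$theta, data = ldata, seed = seed,
    call = match.call()
  ), class = "traj_lcmm")
  fit
}

#' Full-parameter asymptotic covariance of a fitted LCMM
#'
#' Inverse observed information from a numeric Hessian at the optimum, on the
#' unconstrained parameterization (fixed effects, membership logits, Cholesky
#' factor with log-diagonals, log residual SD).
#'
#' @param object A `traj_lcmm` fit.
#' @param ... Unused.
#' @return Covariance matrix of the packed parameter vector.
#' @export
vcov.traj_lcmm <- function(object, ...) {
  H <- stats::optimHess(object$theta, lcmm_objective, ldata = object$data,
                        G = object$n_classes)
  solve(H)
}
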