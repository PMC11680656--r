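# helper: dense multivariate-normal log-density oracle, independent of the
# package's sufficient-statistic machinery
dmvnorm_log <- function(y, mu, V) {
  cV <- chol(V)
  w <- backsolve(cV, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(cV))) + sum(w^2))
}

test_that("single-class marginal equals the plain multivariate normal density", {
  ages <- c(20, 30, 40, 50, 57)
  t1 <- rescale_age(ages)
  Z <- cbind(1, t1, t1^2)
  beta <- matrix(c(1.5, 0.4, -0.1), 1, 3)
  B <- diag(c(0.2, 0.02, 0.002))
  sd <- 0.3
  intakes <- c(2, 4, 7, 9, 8)
  sl <- subject_loglik(ages, intakes, beta, 1, B, sd)
  oracle <- dmvnorm_log(log1p(intakes), drop(Z %*% beta[1, ]),
                        Z %*% B %*% t(Z) + diag(sd^2, 5))
  expect_equal(sl$marginal, oracle, tolerance = 1e-12)
  expect_equal(sl$class_logdens, oracle, tolerance = 1e-12)
})

test_that("zero random-effect covariance reduces to independent residuals", {
  ages <- c(20, 40, 60)
  intakes <- c(1, 5, 12)
  beta <- rbind(c(1, 0.3, 0), c(2, 0.1, -0.05))
  shares <- c(0.3, 0.7)
  sd <- 0.4
  sl <- subject_loglik(ages, intakes, beta, shares, matrix(0, 3, 3), sd)
  t1 <- rescale_age(ages)
  Z <- cbind(1, t1, t1^2)
  per_class <- vapply(1:2, function(g) {
    sum(stats::dnorm(log1p(intakes), drop(Z %*% beta[g, ]), sd, log = TRUE))
  }, numeric(1))
  expect_equal(sl$class_logdens, per_class, tolerance = 1e-12)
  expect_equal(sl$marginal, log(sum(shares * exp(per_class))), tolerance = 1e-12)
})

test_that("marginal likelihood matches Monte-Carlo integration over random effects", {
  # oracle: average the conditional density over 1e5 simulated random-effect
  # draws; agreement within 3 Monte-Carlo standard errors
  set.seed(71)
  for (case in 1:2) {
    ages <- sort(sample(20:64, 4))
    t1 <- rescale_age(ages)
    Z <- cbind(1, t1, t1^2)
    beta <- rbind(c(1.2, 0.5, -0.1), c(2.5, 0.1, 0.02))
    shares <- c(0.4, 0.6)
    B <- matrix(c(0.2, 0.03, 0, 0.03, 0.05, 0, 0, 0, 0.01), 3, 3)
    sd <- 0.35
    y <- log1p(c(2, 5, 8, 11)) + rnorm(4, 0, 0.3)
    intakes <- expm1(y)
    sl <- subject_loglik(ages, intakes, beta, shares, B, sd)

    ndraw <- 1e5
    b <- matrix(rnorm(ndraw * 3), ndraw, 3) %*% chol(B)
    dens_draws <- matrix(0, ndraw, 2)
    for (g in 1:2) {
      mu <- drop(Z %*% beta[g, ])
      cond <- sapply(seq_len(4), function(j) {
        stats::dnorm(y[j], mu[j] + b %*% Z[j, ], sd)
      })
      dens_draws[, g] <- apply(cond, 1, prod)
    }
    mix <- drop(dens_draws %*% shares)
    mc_est <- mean(mix)
    mc_se <- stats::sd(mix) / sqrt(ndraw)
    expect_lt(abs(exp(sl$marginal) - mc_est), 3 * mc_se)
  }
})

test_that("posterior probabilities agree with a closed-form Bayes computation", {
  # one measurement, two classes: hand-computable normal mixture posterior
  beta <- rbind(c(1, 0, 0), c(2, 0, 0))
  B <- diag(c(0.25, 1e-10, 1e-10))   # only the intercept effect matters at t = 0
  sd <- 0.5
  shares <- c(0.3, 0.7)
  y <- 1.4
  intake <- expm1(y)
  df <- data.frame(subject_id = "a", age_years = 35, intake_g_day = intake)
  fit <- structure(list(beta = beta, shares = shares, re_covariance = B,
                        residual_sd = sd, n_classes = 2,
                        data = lcmm_data(df)),
                   class = "traj_lcmm")
  post <- posterior_probs(fit)
  s2 <- 0.25 + 0.25                      # marginal variance of one measure
  f1 <- dnorm(y, 1, sqrt(s2)); f2 <- dnorm(y, 2, sqrt(s2))
  expect_equal(unname(post$probs[1, 1]),
               shares[1] * f1 / (shares[1] * f1 + shares[2] * f2),
               tolerance = 1e-12)
})

test_that("posterior rows sum to one and are label-permutation invariant", {
  co <- small_cohort()
  cfg <- default_config(300, seed = 7)
  # evaluate at the generating parameters; no estimation needed
  f <- structure(list(beta = cfg$class_fixed_effects,
                      shares = cfg$class_shares,
                      membership_logits = log(cfg$class_shares[-4] /
                                                cfg$class_shares[4]),
                      re_covariance = cfg$re_covariance,
                      re_cholesky = t(chol(cfg$re_covariance)),
                      residual_sd = cfg$residual_sd, n_classes = 4L,
                      data = lcmm_data(co$intakes)),
                 class = "traj_lcmm")
  post <- posterior_probs(f)
  expect_equal(unname(rowSums(post$probs)), rep(1, nrow(post$probs)),
               tolerance = 1e-10)
  expect_equal(post$modal_class, unname(max.col(post$probs, "first")))
  perm <- c(3, 1, 4, 2)
  f2 <- relabel_classes(f, perm)
  ld <- f$data
  ll1 <- alctraj:::lcmm_loglik(ld, f$beta, f$shares, f$re_covariance,
                               f$residual_sd^2)
  ll2 <- alctraj:::lcmm_loglik(ld, f2$beta, f2$shares, f2$re_covariance,
                               f2$residual_sd^2)
  expect_equal(ll1, ll2, tolerance = 1e-10)
  post2 <- posterior_probs(f2)
  expect_equal(unname(post2$probs), unname(post$probs[, perm]),
               tolerance = 1e-10)
})

test_that("a one-class fit on near-noise-free data recovers the mean curve", {
  cfg <- default_config(200, seed = 3, residual_sd = 0.02,
                        re_covariance = diag(1e-8, 3),
                        class_shares = c(0, 0, 1, 0), missing_rate = 0)
  co <- simulate_cohort(cfg)
  f <- traj_lcmm(co$intakes, 1)
  expect_true(f$converged)
  expect_equal(unname(coef(f)[1, ]), cfg$class_fixed_effects[3, ],
               tolerance = 1e-2)
})

test_that("the fitted optimum dominates the generating parameters", {
  fx <- default_fits_1_to_6()
  cfg <- fx$cohort$truth$config
  f4 <- fx$fits[[4]]
  ll_truth <- alctraj:::lcmm_loglik(f4$data, cfg$class_fixed_effects,
                                    cfg$class_shares, cfg$re_covariance,
                                    cfg$residual_sd^2)
  expect_gte(f4$loglik, ll_truth)
})

test_that("parameter recovery on the default cohort started at truth", {
  fx <- default_fits_1_to_6()
  cfg <- fx$cohort$truth$config
  ldata <- lcmm_data(fx$sets$trajectory$intakes)
  f <- traj_lcmm(ldata, 4, n_starts = 0, start = truth_start(cfg))
  perm <- match_classes_to_truth(f$beta, cfg$class_fixed_effects)
  expect_true(all(abs(f$shares[perm] - cfg$class_shares) < 0.03))
  # fixed effects within 3 asymptotic standard errors
  V <- vcov(f)
  se <- matrix(sqrt(pmax(diag(V)[1:12], 0)), 4, 3, byrow = TRUE)
  err <- abs(f$beta[perm, ] - cfg$class_fixed_effects)
  expect_true(all(err < 3 * se[perm, ] + 1e-6))
  # the variance decomposition reproduces the generator's variance ratio
  ratio_true <- cfg$re_covariance[1, 1] / cfg$residual_sd^2
  ratio_fit <- f$re_covariance[1, 1] / f$residual_sd^2
  expect_lt(abs(ratio_fit - ratio_true) / ratio_true, 0.25)
})

test_that("multistart with one class is idempotent", {
  co <- small_cohort()
  ld <- lcmm_data(co$intakes)
  f1 <- traj_lcmm(ld, 1)
  f1b <- traj_lcmm(ld, 1, n_starts = 5)
  expect_equal(f1$loglik, f1b$loglik, tolerance = 1e-6)
})

test_that("replicated starts on separated two-class data find one optimum", {
  cfg <- default_config(400, seed = 21,
                        class_shares = c(0, 0.5, 0, 0.5),
                        missing_rate = 0)
  co <- simulate_cohort(cfg)
  ld <- lcmm_data(co$intakes)
  f <- traj_lcmm(ld, 2, n_starts = 20, seed = 9,
                 control = list(n_refine = 21))
  lls <- f$start_logliks[f$start_converged]
  expect_gte(mean(lls > max(lls) - 1e-4), 0.9)
})

test_that("best log-likelihood is non-decreasing in the number of classes", {
  fx <- default_fits_1_to_6()
  lls <- vapply(fx$fits, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) > -1e-4))
})

test_that("empirical-Bayes random effects average to about zero under truth", {
  fx <- default_fits_1_to_6()
  f4 <- fx$fits[[4]]
  re <- ranef_lcmm(f4)
  n <- nrow(re)
  # means shrink as 1/sqrt(n); allow 4 standard errors of the RE scale
  for (j in 1:3) {
    expect_lt(abs(mean(re[, j])),
              4 * sqrt(f4$re_covariance[j, j] / n) + 0.01)
  }
})

test_that("class trajectory predictions evaluate the quadratic exactly", {
  fx <- default_fits_1_to_6()
  f4 <- fx$fits[[4]]
  pred <- predict(f4, ages = 35)
  expect_equal(pred$transformed, unname(f4$beta[, 1]), tolerance = 1e-12)
  expect_equal(pred$natural, pmax(expm1(f4$beta[, 1]), 0), tolerance = 1e-12)
  expect_warning(predict(f4, ages = c(10, 35)), "guard")
  zero <- structure(list(beta = matrix(0, 1, 3), n_classes = 1),
                    class = "traj_lcmm")
  expect_equal(predict(zero, ages = c(20, 50))$natural, c(0, 0))
})

test_that("the default high class stays above 10 g/day across adulthood", {
  cfg <- default_config()
  pred_nat <- function(beta, ages) {
    t1 <- rescale_age(ages)
    inverse_transform_intake(drop(cbind(1, t1, t1^2) %*% beta))
  }
  expect_true(all(pred_nat(cfg$class_fixed_effects[2, ], 20:65) > 10))
  expect_true(all(pred_nat(cfg$class_fixed_effects[4, ], 20:65) < 6))
})

test_that("weighted diagnostic matches observations exactly on noise-free data", {
  cfg <- default_config(150, seed = 17, residual_sd = 1e-6,
                        re_covariance = diag(1e-12, 3), missing_rate = 0)
  co <- simulate_cohort(cfg)
  # the generating parameters are the exact fit for noise-free data
  f <- structure(list(beta = cfg$class_fixed_effects,
                      shares = cfg$class_shares,
                      re_covariance = diag(1e-10, 3),
                      residual_sd = 1e-5, n_classes = 4L,
                      data = lcmm_data(co$intakes)),
                 class = "traj_lcmm")
  tab <- weighted_fit_diagnostic(f)
  expect_equal(tab$observed, tab$predicted, tolerance = 1e-4)
})

test_that("weighted diagnostic is calibrated on the default cohort", {
  fx <- default_fits_1_to_6()
  f4 <- fx$fits[[4]]
  tab <- weighted_fit_diagnostic(f4)
  gap <- abs(tab$observed - tab$predicted)
  bound <- 2 * f4$residual_sd / sqrt(tab$n_obs)
  expect_lt(mean(gap), mean(bound))
})

test_that("degenerate within-subject covariance is rejected", {
  expect_error(
    subject_loglik(c(30, 30), c(2, 2), matrix(c(1, 0, 0), 1, 3), 1,
                   matrix(0, 3, 3), 0),
    "singular")
})

test_that("fits serialize to JSON with their start trace", {
  co <- small_cohort()
  f <- traj_lcmm(lcmm_data(co$intakes), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_lcmm_json(f, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$loglik, f$loglik, tolerance = 1e-10)
  expect_equal(back$n_classes, 1)
  expect_length(back$start_logliks, f$n_starts_used)
})
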