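# small survival fixture with known structure
surv_fixture <- function(n = 400, seed = 99, xi = c(0.3, 0), shape = 1,
                         scale = 30) {
  set.seed(seed)
  cls <- sample(1:2, n, TRUE, prob = c(0.4, 0.6))
  entry <- runif(n, 50, 60)
  v <- runif(n) * exp(-(entry / scale)^shape * exp(xi[cls]))
  event_age <- scale * (-log(v) / exp(xi[cls]))^(1 / shape)
  censor <- entry + rexp(n, 0.05)
  admin <- entry + 15
  exit <- pmin(event_age, censor, admin)
  data.frame(subject_id = sprintf("x%03d", 1:n), entry_age = entry,
             exit_age = exit, event = as.integer(event_age <= pmin(censor, admin)),
             class = cls, recruitment_quintile = sample(1:5, n, TRUE))
}

degenerate_post <- function(data, G = 2) {
  P <- matrix(0, nrow(data), G)
  P[cbind(seq_len(nrow(data)), data$class)] <- 1
  rownames(P) <- data$subject_id
  P
}

test_that("one class reduces to the standard left-truncated likelihood", {
  d <- surv_fixture()
  P <- matrix(1, nrow(d), 1); rownames(P) <- d$subject_id
  bl <- list(family = "weibull", shape = 1.3, scale = 28)
  ll <- lc_ph_loglik(P, d, xi = 0, baseline = bl)
  w_exit <- weibull_hazard(d$exit_age, 1.3, 28)
  w_entry <- weibull_hazard(d$entry_age, 1.3, 28)
  hand <- sum(d$event * log(w_exit$hazard) - (w_exit$cumhaz - w_entry$cumhaz))
  expect_equal(ll, hand, tolerance = 1e-10)
})

test_that("degenerate posteriors equal the modal-assignment likelihood", {
  d <- surv_fixture()
  P <- degenerate_post(d)
  bl <- list(family = "weibull", shape = 1.1, scale = 32)
  xi <- c(0.4, 0)
  ll <- lc_ph_loglik(P, d, xi = xi, baseline = bl)
  w_exit <- weibull_hazard(d$exit_age, 1.1, 32)
  w_entry <- weibull_hazard(d$entry_age, 1.1, 32)
  eta <- xi[d$class]
  hand <- sum(d$event * (log(w_exit$hazard) + eta) -
                (w_exit$cumhaz - w_entry$cumhaz) * exp(eta))
  expect_equal(ll, hand, tolerance = 1e-10)
})

test_that("three-subject exponential instance matches a pocket calculation", {
  # shape 1 Weibull: h0 = 1/scale, H0(t) = t/scale
  d <- data.frame(subject_id = c("a", "b", "c"),
                  entry_age = c(50, 52, 55), exit_age = c(60, 58, 70),
                  event = c(1, 0, 1))
  P <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.1, 0.9))
  rownames(P) <- d$subject_id
  xi <- c(log(2), 0); sc <- 40
  ll <- lc_ph_loglik(P, d, xi = xi, baseline = list(family = "weibull",
                                                    shape = 1, scale = sc))
  hand <- 0
  for (i in 1:3) {
    terms <- sapply(1:2, function(g) {
      h <- exp(xi[g]) / sc
      S <- exp(-(d$exit_age[i] - d$entry_age[i]) * exp(xi[g]) / sc)
      (h^d$event[i]) * S
    })
    hand <- hand + log(sum(P[i, ] * terms))
  }
  expect_equal(ll, hand, tolerance = 1e-10)
})

test_that("posterior-weighted and joint objectives differ by a constant", {
  # the two-stage objective drops a term free of hazard parameters; check
  # the difference is invariant across hazard parameter values
  d <- surv_fixture(n = 60)
  set.seed(14)
  fY <- matrix(rgamma(120, 2), 60, 2)          # stand-in class densities f(Y|g)
  shares <- c(0.35, 0.65)
  lik_Y <- sweep(fY, 2, shares, "*")
  P <- lik_Y / rowSums(lik_Y)
  rownames(P) <- d$subject_id
  joint_minus_weighted <- function(xi, shape, scale) {
    bl <- list(family = "weibull", shape = shape, scale = scale)
    wll <- lc_ph_loglik(P, d, xi = xi, baseline = bl)
    w_exit <- weibull_hazard(d$exit_age, shape, scale)
    w_entry <- weibull_hazard(d$entry_age, shape, scale)
    jll <- 0
    for (i in 1:60) {
      fT <- sapply(1:2, function(g) {
        e <- exp(xi[g])
        (w_exit$hazard[i] * e)^d$event[i] *
          exp(-(w_exit$cumhaz[i] - w_entry$cumhaz[i]) * e)
      })
      jll <- jll + log(sum(shares * fY[i, ] * fT))
    }
    jll - wll
  }
  d1 <- joint_minus_weighted(c(0.5, 0), 1.2, 30)
  d2 <- joint_minus_weighted(c(-0.3, 0), 2.0, 45)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("entry at the support minimum reproduces the untruncated likelihood", {
  d <- surv_fixture(n = 80)
  P <- degenerate_post(d)
  bl <- list(family = "weibull", shape = 1.4, scale = 35)
  d0 <- d; d0$entry_age <- 1e-12
  ll0 <- lc_ph_loglik(P, d0, xi = c(0.2, 0), baseline = bl)
  w_exit <- weibull_hazard(d$exit_age, 1.4, 35)
  eta <- c(0.2, 0)[d$class]
  untrunc <- sum(d$event * (log(w_exit$hazard) + eta) -
                   w_exit$cumhaz * exp(eta))
  expect_equal(ll0, untrunc, tolerance = 1e-8)
})

test_that("misaligned ids and invalid intervals are rejected", {
  d <- surv_fixture(n = 30)
  P <- degenerate_post(d)
  rownames(P)[1] <- "nope"
  expect_error(lc_ph_loglik(P, d, xi = c(0, 0),
                            baseline = list(family = "weibull", shape = 1,
                                            scale = 10)),
               "misaligned")
  d2 <- surv_fixture(n = 30)
  d2$exit_age[3] <- d2$entry_age[3]
  expect_error(lc_ph_loglik(degenerate_post(d2), d2, xi = c(0, 0),
                            baseline = list(family = "weibull", shape = 1,
                                            scale = 10)),
               "exit_age > entry_age")
})

test_that("the G = 1 Weibull fit agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  # mild truncation keeps the Weibull well identified for both optimizers
  set.seed(5)
  n <- 600
  entry <- runif(n, 0.5, 3)
  v <- runif(n) * exp(-(entry / 10)^1.5)
  event_age <- 10 * (-log(v))^(1 / 1.5)
  censor <- entry + rexp(n, 0.05)
  d <- data.frame(subject_id = sprintf("x%03d", 1:n), entry_age = entry,
                  exit_age = pmin(event_age, censor),
                  event = as.integer(event_age <= censor),
                  recruitment_quintile = 1L)
  P <- matrix(1, n, 1); rownames(P) <- d$subject_id
  fit <- lc_hazard(d, P, baseline = "weibull", covariate_set = "model1",
                   reference = 1)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(entry_age, exit_age, event) ~ 1, data = d,
    dist = "weibull")
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-6)
  expect_equal(fit$baseline$shape, unname(fs$res["shape", "est"]),
               tolerance = 1e-3)
  expect_equal(fit$baseline$scale, unname(fs$res["scale", "est"]),
               tolerance = 1e-3)
})

test_that("the reference class is pinned at hazard ratio one", {
  d <- surv_fixture(n = 500, seed = 31)
  fit <- lc_hazard(d, degenerate_post(d), baseline = "weibull",
                   covariate_set = "model1", reference = 2)
  expect_equal(fit$hr_table$hr[2], 1)
  expect_true(is.na(fit$hr_table$ci_low[2]))
  expect_equal(fit$xi[2], 0)
  expect_true(fit$hr_table$ci_low[1] <= fit$hr_table$hr[1])
  expect_true(fit$hr_table$hr[1] <= fit$hr_table$ci_high[1])
})

test_that("AIC comparison picks fewer parameters on ties and checks data identity", {
  d <- surv_fixture(n = 300, seed = 77)
  P <- degenerate_post(d)
  fw <- lc_hazard(d, P, baseline = "weibull", covariate_set = "model1",
                  reference = 2)
  fm <- lc_hazard(d, P, baseline = "mspline", n_knots = 4,
                  covariate_set = "model1", reference = 2)
  cmp <- compare_baselines(list(fw, fm))
  expect_equal(cmp$table$aic, 2 * cmp$table$n_params - 2 * cmp$table$loglik)
  expect_equal(cmp$chosen$aic, min(cmp$table$aic))
  # equal log-likelihoods: fewer parameters wins through the AIC penalty
  fake <- fm; fake$loglik <- fw$loglik
  fake$aic <- 2 * fake$n_params - 2 * fake$loglik
  cmp2 <- compare_baselines(list(fw, fake))
  expect_equal(cmp2$table$model[which.min(cmp2$table$aic)], "weibull")
  # identical fits listed twice: tie goes to the first with a note
  cmp3 <- compare_baselines(list(fw, fw))
  expect_true(cmp3$tie)
  expect_equal(cmp3$chosen$aic, fw$aic)
  # different data is refused
  d2 <- surv_fixture(n = 299, seed = 78)
  f2 <- lc_hazard(d2, degenerate_post(d2), baseline = "weibull",
                  covariate_set = "model1", reference = 2)
  expect_error(compare_baselines(list(fw, f2)), "different data")
})

test_that("correction beats modal assignment under moderate separation", {
  # directional property: with overlapping classes (relative entropy ~0.6)
  # the posterior-weighted estimator's absolute bias for the high-class
  # log-HR is no worse than the modal-assignment estimator's
  n_rep <- 100
  err_corr <- err_modal <- numeric(0)
  truth <- log(1.65)
  for (r in seq_len(n_rep)) {
    cfg <- default_config(
      n_subjects = 2000, seed = 5000 + r,
      residual_sd = 0.34,                      # weaker separation on purpose
      re_covariance = matrix(c(0.2312, 0.012, 0, 0.012, 0.01, 0,
                               0, 0, 0.0013), 3, 3))
    co <- simulate_cohort(cfg)
    sets <- assemble_analysis_sets(co$intakes, co$subjects)
    ld <- lcmm_data(sets$trajectory$intakes)
    comp <- alctraj:::lcmm_logdens(ld, cfg$class_fixed_effects,
                                   cfg$re_covariance, cfg$residual_sd^2)$logdens
    lp <- sweep(comp, 2, log(cfg$class_shares), "+")
    P <- exp(lp - alctraj:::logsumexp_rows(lp))
    rownames(P) <- ld$ids
    hc <- suppressWarnings(
      lc_hazard(sets$survival, P, baseline = "weibull",
                covariate_set = "model1", reference = 4))
    Pm <- P * 0
    Pm[cbind(seq_len(nrow(P)), max.col(P, "first"))] <- 1
    rownames(Pm) <- rownames(P)
    hm <- suppressWarnings(
      lc_hazard(sets$survival, Pm, baseline = "weibull",
                covariate_set = "model1", reference = 4))
    err_corr <- c(err_corr, hc$xi[2] - truth)
    err_modal <- c(err_modal, hm$xi[2] - truth)
  }
  expect_lte(abs(mean(err_corr)), abs(mean(err_modal)) + 0.02)
})

test_that("hazard fits serialize and the HR table round-trips", {
  d <- surv_fixture(n = 300, seed = 77)
  fit <- lc_hazard(d, degenerate_post(d), baseline = "weibull",
                   covariate_set = "model1", reference = 2)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_hazard_json(fit, json)
  write_hr_table(fit, csv)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-10)
  tab <- utils::read.csv(csv)
  expect_equal(tab$hr, fit$hr_table$hr, tolerance = 1e-10)
})
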