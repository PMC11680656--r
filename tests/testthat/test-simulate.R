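test_that("invalid generator configurations are rejected with clear messages", {
  expect_error(default_config(n_subjects = 0), "positive count")
  expect_error(default_config(class_shares = c(0.5, 0.4)), "sum to 1")
  expect_error(default_config(re_covariance = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive semi-definite")
  expect_error(default_config(residual_sd = -1), "strictly positive")
  expect_error(cohort_config(n_subjects = 10), "seed")
  expect_error(default_config(class_log_hr = c(1, 2, 3, 4)), "reference entry")
})

test_that("default configuration encodes the study conditions", {
  cfg <- default_config()
  expect_equal(cfg$class_shares, c(0.163, 0.151, 0.506, 0.180))
  expect_equal(cfg$class_log_hr, c(log(1.18), log(1.65), log(1.15), 0))
  expect_equal(cfg$class_log_hr[4], 0)
  expect_equal(cfg$measure_ages, c(20, 30, 40, 50))
  # inter-subject variance at age 35 about twice the residual variance
  expect_equal(cfg$re_covariance[1, 1] / cfg$residual_sd^2, 2, tolerance = 0.01)
})

test_that("class mean curves have the documented natural-scale shapes", {
  cfg <- default_config()
  t1 <- rescale_age(20:65)
  X <- cbind(1, t1, t1^2)
  curves <- inverse_transform_intake(X %*% t(cfg$class_fixed_effects))
  expect_true(all(curves[, 2] > 10))          # consistently high class
  expect_true(all(curves[, 4] < 6))           # consistently low class
  # the two remaining classes increase from low intakes
  expect_lt(curves[1, 1], 3); expect_gt(curves[31, 1], curves[1, 1])
  expect_lt(curves[1, 3], 5); expect_gt(curves[31, 3], curves[1, 3])
})

test_that("simulation is deterministic given the seed", {
  cfg <- default_config(150, seed = 321)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$intakes, b$intakes)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth$class, b$truth$class)
  c2 <- simulate_cohort(default_config(150, seed = 322))
  expect_false(identical(a$subjects$exit_age, c2$subjects$exit_age))
})

test_that("empirical class shares converge to the configured shares", {
  co <- fixture("cohort10k", function() simulate_cohort(default_config(10000, seed = 2024)))
  shares <- default_config()$class_shares
  emp <- tabulate(co$truth$class, 4) / 10000
  tol <- 3 * sqrt(shares * (1 - shares) / 10000)
  expect_true(all(abs(emp - shares) < tol))
})

test_that("event times respect truncation and censoring logic", {
  co <- fixture("cohort10k", function() simulate_cohort(default_config(10000, seed = 2024)))
  s <- co$subjects
  expect_true(all(s$exit_age > s$entry_age))
  expect_true(all(co$truth$event_age_uncensored > s$entry_age))
  # event flag is 1 exactly when the event age precedes both censoring ages
  admin <- s$entry_age + default_config()$admin_followup_years
  expect_true(all(s$event %in% 0:1))
  expect_true(all(s$exit_age[s$event == 1] ==
                    co$truth$event_age_uncensored[s$event == 1]))
  expect_true(all(s$exit_age <= admin + 1e-9))
  expect_true(all(co$truth$event_age_uncensored[s$event == 0] >= s$exit_age[s$event == 0]))
})

test_that("intakes are non-negative and measured at the designed ages", {
  co <- small_cohort()
  expect_true(all(co$intakes$intake_g_day >= 0))
  retro <- co$intakes[co$intakes$source != "baseline_ffq", ]
  expect_true(all(retro$age_years %in% c(20, 30, 40, 50)))
  base <- co$intakes[co$intakes$source == "baseline_ffq", ]
  expect_equal(nrow(base), nrow(co$subjects))
  expect_equal(base$age_years[order(base$subject_id)],
               co$subjects$baseline_age[order(co$subjects$subject_id)])
})

test_that("noise-free limit reproduces the class mean curves exactly", {
  cfg <- default_config(80, seed = 5, residual_sd = 1e-12,
                        re_covariance = diag(1e-24, 3), missing_rate = 0)
  co <- simulate_cohort(cfg)
  t1 <- rescale_age(co$intakes$age_years)
  cls <- co$truth$class[match(co$intakes$subject_id, co$truth$subject_id)]
  mu <- rowSums(cbind(1, t1, t1^2) * cfg$class_fixed_effects[cls, ])
  expect_equal(transform_intake(co$intakes$intake_g_day), mu, tolerance = 1e-6)
})

test_that("crude event proportions order by the class hazard ratios", {
  # oracle: the generating model itself says class 2 (HR 1.65) must lead,
  # classes 1 and 3 (1.18, 1.15) sit together, class 4 (reference) trails;
  # the 1.15 vs 1.00 contrast needs a large cohort to order reliably
  co <- simulate_cohort(default_config(60000, seed = 2024))
  p <- tapply(co$subjects$event, co$truth$class, mean)
  expect_gt(p[2], p[1]); expect_gt(p[2], p[3])
  expect_gt(p[1], p[4]); expect_gt(p[3], p[4])
  expect_lt(abs(p[1] - p[3]), 0.02)
})

test_that("cohorts round-trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("intakes.csv", "subjects.csv",
                                               "truth.json")))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$intakes), nrow(co$intakes))
  expect_equal(back$subjects$exit_age, co$subjects$exit_age, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$class, co$truth$class)
})
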