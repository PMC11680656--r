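# Shared fixtures, computed lazily once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# default synthetic cohort at the study's desk-scale size
default_cohort_3000 <- function() {
  fixture("cohort3000", function() simulate_cohort(default_config(3000, seed = 42)))
}

# small cohort for quick structural tests
small_cohort <- function() {
  fixture("cohort300", function() simulate_cohort(default_config(300, seed = 7)))
}

# truth-anchored start list for a config
truth_start <- function(cfg) {
  list(beta = cfg$class_fixed_effects, shares = cfg$class_shares,
       B = cfg$re_covariance, sigma = cfg$residual_sd)
}

# G = 1..6 fits on the default 3000-subject cohort (the expensive fixture,
# shared between the estimation, selection and acceptance tests)
default_fits_1_to_6 <- function() {
  fixture("fits16", function() {
    co <- default_cohort_3000()
    sets <- assemble_analysis_sets(co$intakes, co$subjects)
    ldata <- lcmm_data(sets$trajectory$intakes)
    fits <- list()
    base1 <- NULL
    for (G in 1:6) {
      fits[[G]] <- traj_lcmm(ldata, G, n_starts = if (G == 1) 1 else 8,
                             warm_start = if (G > 1) fits[[G - 1]] else NULL,
                             base_fit = base1, seed = 100 + G)
      if (G == 1) base1 <- fits[[1]]
    }
    list(cohort = co, sets = sets, fits = fits)
  })
}

# align fitted classes to the generator truth by fixed-effect distance
match_classes_to_truth <- function(beta_fit, beta_true) {
  G <- nrow(beta_true)
  D <- as.matrix(stats::dist(rbind(beta_fit, beta_true)))[seq_len(G), G + seq_len(G)]
  perm <- apply(D, 2, which.min)
  stopifnot(length(unique(perm)) == G)
  perm
}
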