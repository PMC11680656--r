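# alctraj

Latent class alcohol-consumption trajectories and postmenopausal
breast-cancer hazards.

Cohort studies that relate alcohol to breast-cancer risk usually reduce a
woman's exposure to one baseline number. `alctraj` implements the
alternative two-stage analysis for cohorts with repeated intake reports
(retrospective measures at ages 20/30/40/50 plus a baseline food-frequency
measure):

1. **Trajectory estimation.** A latent class mixed model (LCMM) on the
   `log(intake + 1)` scale over rescaled age `t = (age − 35)/13`: each
   latent class g has a quadratic mean trajectory `β_g`, subjects carry a
   shared random intercept/slope/quadratic `b_i ~ N(0, B)`, and membership
   is an intercept-only multinomial `π_g`. Fits run EM warm-up plus
   quasi-Newton refinement from many starts (`traj_lcmm()`); the number of
   classes is chosen by BIC/ICL/entropy plus the minimum-class-share (5%)
   and minimum-mean-posterior (0.75) rules (`select_n_classes()`).
2. **Risk regression.** A parametric proportional-hazards model on the age
   timescale with delayed entry, Weibull or cubic M-spline baseline
   (compared by AIC), and the stage-1 posterior class probabilities `p_ig`
   held fixed, so the likelihood
   `Σ_i log Σ_g p_ig h_g(T_i)^δ_i S_g(T_i)/S_g(E_i)` corrects the class
   hazard ratios `exp(ξ_g)` for classification error instead of trusting
   the modal assignment (`lc_hazard()`).

A synthetic-cohort generator (`simulate_cohort()`) reproduces the data
structure — intake trajectories, menstrual-history fields for menopausal
classification, class-conditional covariates, left-truncated and
right-censored event ages — with known ground truth, so both stages are
verifiable end to end. Preprocessing utilities cover beverage-frequency
quantification (`frequency_to_grams()`), the menopausal-status cascade
(`classify_menopause()`), the 1% energy-ratio trim and the exclusion flow
(`assemble_analysis_sets()`).

## Worked example

```r
library(alctraj)

cfg    <- default_config(n_subjects = 1500, seed = 11)
cohort <- simulate_cohort(cfg)
sets   <- assemble_analysis_sets(cohort$intakes, cohort$subjects)
sets$flow
#>                    step excluded_n remaining_n
#> 1                 input          0        1500
#> 2 energy_ratio_extremes         30        1470
#> 3         premenopausal        154        1316
#> 4    missing_covariates        101        1215

fit <- traj_lcmm(sets$trajectory$intakes, n_classes = 4, n_starts = 6, seed = 2)
summary(fit)
#> Latent class mixed model (4 classes, 1470 subjects)
#>   logLik -4429.393  BIC 9019.232  entropy 0.710
#>
#> Class trajectories (intercept, slope, quadratic on log(x+1) scale):
#>          share intercept  slope quadratic mean_post
#> class 1 0.1715    1.0449 0.0841   -0.0029    0.8189
#> class 2 0.5169    1.9755 0.3005   -0.1183    0.8334
#> class 3 0.1663    1.5535 0.6073   -0.0279    0.8305
#> class 4 0.1453    3.0068 0.1595   -0.0574    0.8976
#>
#> Residual SD: 0.2815;  RE variance at t = 0: 0.1312 (ratio 1.66)

haz <- lc_hazard(sets$survival, posterior_probs(fit),
                 baseline = "weibull", covariate_set = "model2",
                 reference = order_classes_by_intake(fit, 50)[4])
haz
#> Latent-class proportional hazards (weibull baseline, model2)
#>   1215 subjects, 77 events; logLik -463.767, AIC 981.534
#>   class 1: HR 1.00 (reference)
#>   class 2: HR 1.56 (95% CI 0.53-4.53)
#>   class 3: HR 1.36 (95% CI 0.42-4.47)
#>   class 4: HR 1.73 (95% CI 0.56-5.35)
```

Reading the output: the exclusion flow drops the extreme 1% tails of the
energy-intake/requirement ratio before trajectory estimation, then removes
premenopausal women and incomplete covariate records before the hazard
stage. The four fitted classes reproduce the generating structure — a
consistently low class (fitted label 1), a moderate majority class (label
2), a low-to-moderate increasing class (label 3) and a consistently high
class (label 4) — with each class's mean posterior probability above 0.8
and the between-subject variance at age 35 about 1.7× the residual
variance. In the hazard stage the consistently low class is the reference;
at this deliberately small n (77 events) the intervals are wide, and the
consistently high class shows the largest hazard ratio, consistent with its
generating value of 1.65.
`run_full_analysis()` chains all stages (classes 1–6, both baselines, both
adjustment models) into one reproducible, manifest-tracked run, and
`inst/scripts/alctraj-pipeline.R` exposes the same as a command line.

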