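---
title: "Latent class intake trajectories and classification-error-corrected hazards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class intake trajectories and classification-error-corrected hazards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alctraj)
```

## The problem

Epidemiological studies of alcohol and breast cancer usually summarize a
woman's exposure by a single baseline measurement. When repeated intake
reports are available — here, retrospective reports at ages 20, 30, 40 and 50
plus a baseline food-frequency measure taken between ages 50 and 65 — the
drinking *history* can be modelled instead. `alctraj` implements a two-stage
analysis: latent class mixed models (LCMM) summarize adult intake histories
into a small number of trajectory classes, and a parametric
proportional-hazards model relates class membership to the age at first
primary breast cancer in postmenopausal women, correcting for the error
inherent in assigning women to classes.

## Stage 1: the latent class mixed model

Intakes $x_{ij}$ (grams ethanol/day) are transformed to $y_{ij} = \log(x_{ij}
+ 1)$, which tames the right skew and keeps zero intakes finite. Age is
rescaled to $t = (\mathrm{age} - 35)/13$, so the retrospective ages 22 and 48
map near $\pm 1$. Conditional on membership in class $g$ and random effects
$b_i$,

$$y_{ij} = X_{ij}^\top \beta_g + Z_{ij}^\top b_i + \varepsilon_{ij}, \qquad
X_{ij} = Z_{ij} = (1, t_{ij}, t_{ij}^2)^\top,$$

with $b_i \sim N(0, B)$ shared across classes, homoscedastic residuals
$\varepsilon_{ij} \sim N(0, \sigma^2)$, and an intercept-only multinomial
membership model $\pi_g$. The marginal likelihood integrates the random
effects analytically: each subject contributes a mixture of multivariate
normal densities with covariance $V_i = Z_i B Z_i^\top + \sigma^2 I$.
Internally each subject is reduced to the sufficient statistics $(k_i,
y_i^\top y_i, Z_i^\top y_i, Z_i^\top Z_i)$, so the exact likelihood is
evaluated with vectorized $3 \times 3$ closed-form algebra whatever each
woman's measurement ages — no binning or approximation.

Why shared-$B$ rather than class-specific covariances: one random-effects
structure is the standard formulation in this model family's software, keeps
the parameter count at $3G + (G-1) + 7$, and is the assumption under which
the two-stage hazard correction below is derived. Class-specific residual
variances and covariate-dependent membership are deliberately out of scope.

### Estimation

Each fit runs expectation–maximization with closed-form M-steps
(posterior-weighted least squares for $\beta_g$, conditional-moment updates
for $B$ and $\sigma^2$) until the relative log-likelihood change falls below
`1e-7`, then polishes with a quasi-Newton pass (`nlminb`) on the full
unconstrained parameter vector — Cholesky factor with log-diagonals for $B$,
log $\sigma$, membership logits — to the final tolerance of `1e-8`.
Convergence is declared on optimizer success or a numerically zero score
(max absolute gradient below $10^{-3} |\ell|$, a scale-aware criterion that
tolerates the PORT code's "false convergence" reports on flat optima).

Mixture likelihoods are multimodal, so `traj_lcmm()` is multistart. A design
point worth recording: perturbing the 1-class solution by multiples of its
*asymptotic standard errors* fails — those shrink as $1/\sqrt{n}$, all
starts become identical, and EM then collapses into a merged-classes
stationary point in which the random intercept absorbs the between-class
spread. Starts here are instead anchored at randomly permuted Gaussian
quantiles of the *subject* intercept distribution (scale: the random-effect
SD of the 1-class fit, times `perturb_scale = 1.5`), plus jitter; on a
separated two-class fixture this raises the fraction of starts reaching the
top log-likelihood from roughly half to over 90%. Every start gets a short
screening EM run; the best few basins (default 4) receive the full
treatment, and candidates with $G$ classes also get a warm start that splits
the largest class of the $(G-1)$-class fit. Ties across equally good starts
go to the earliest start index. Estimation is label-agnostic; presentation
ordering is a separate explicit step (`relabel_classes()`,
`order_classes_by_intake()`).

### Choosing the number of classes

`selection_report()` computes, per candidate $G$: the BIC
($-2\ell + p\log N$ with $N$ = subjects, the mixture-of-subjects
convention), the ICL (BIC plus twice the negative log posterior of the modal
assignments, so ICL $\ge$ BIC), and the relative entropy
$1 - \sum_{ig} -p_{ig}\log p_{ig} / (N \log G)$. The exact entropy and ICL
variants used in the source analysis live in an unavailable supplement;
these standard definitions are the documented substitutions.
`select_n_classes()` applies the reported decision rules: discard candidates
whose smallest class falls under 5% of subjects or whose mean posterior
probability in any class falls under 0.75, then take the lowest BIC among
the survivors; when BIC and ICL disagree, BIC wins (a deterministic rule is
required), and both always appear in the trace.

## Stage 2: the classification-error-corrected hazard model

Assigning each woman to her modal class and regressing on that label treats
a noisy classification as exact and biases hazard ratios toward the null.
Instead, with stage-1 parameters held fixed, the hazard likelihood
marginalizes over class membership using the posterior probabilities
$p_{ig}$:

$$\ell = \sum_i \log \sum_g p_{ig}\, h_g(T_i)^{\delta_i}
\frac{S_g(T_i)}{S_g(E_i)}, \qquad
h_g(t) = h_0(t) \exp(\xi_g + \gamma^\top W_i),$$

with age as the timescale, delayed entry at the baseline age $E_i$
(left truncation divides by $S_g(E_i)$), exit $T_i$ and event indicator
$\delta_i$. Up to a term free of hazard parameters this equals the joint
likelihood with fixed stage-1 parameters (the equivalence is asserted
numerically in the tests). The reference class has $\xi \equiv 0$; by
default the last class, which for the default generator is the consistently
low-consumption class.

Two baseline hazards are supported. The Weibull uses
$h_0(t) = (k/\lambda)(t/\lambda)^{k-1}$. The flexible alternative is a cubic
M-spline, $h_0(t) = \sum_k \eta_k M_k(t)$ with $\eta_k \ge 0$, built on
`splines::splineDesign` ($M_k$ is the B-spline rescaled to unit integral);
the cumulative hazard uses the integrated basis computed exactly by
two-point Gauss–Legendre quadrature per knot segment (exact for piecewise
cubics). Knots — totals of 5 or 4, boundary knots at the minimum entry and
maximum exit age, interior knots at equally spaced quantiles of the observed
event ages — are compared by AIC via `compare_baselines()`. Positivity is
enforced by log-reparameterization; standard errors come from the inverse
observed information *conditional on stage 1* (Wald intervals on the log-HR
scale), since the source analysis does not state its two-stage variance
variant; an optional parametric bootstrap (`boot_stage1`) redraws stage-1
parameters from their asymptotic normal distribution and adds the
between-draw variance. Adjustment sets: `model1` uses the recruitment-date
quintile only (age being the timescale, never a covariate); `model2` adds
the eight lifestyle and reproductive covariates, entered as indicator
variables with constant columns dropped.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the exact structure the estimators
assume, so every stage is testable against ground truth: class labels from
the configured shares; random effects and residuals on the transformed
scale; intakes back-transformed as $\max(e^y - 1, 0)$ (the inverse of the
modelling transform, floored at zero); event ages by inverse-transform
sampling from the class-specific Weibull proportional-hazards survival
function, drawn conditional on exceeding the baseline age so the cohort is
event-free at entry and `n_subjects` is preserved; exponential competing
censoring plus an administrative horizon; menstrual-history fields and
class-conditional categorical covariates mirroring the baseline
questionnaire.

The defaults encode the published study conditions and were calibrated once,
before any acceptance checking, to those conditions: class shares
16.3/15.1/50.6/18.0%; four trajectory shapes (one consistently high class
above 10 g/day at every adult age, one consistently low class below
6 g/day, two increasing low-to-moderate classes); an inter-subject variance
at age 35 twice the residual variance; class hazard ratios 1.18, 1.65, 1.15
against the low class; about 6.5% of postmenopausal subjects experiencing an
event over a follow-up horizon of up to 18 years with ~3.5%/year competing
censoring (median follow-up near 17 years); a ~0.5% chance that any
retrospective measure is missing; ~1% missingness per adjustment covariate;
and roughly 10% of subjects premenopausal at baseline. The Weibull scale
(122 years at shape 4.6) was solved numerically for the 6.5% event fraction.

Two calibration choices deserve emphasis. First, the zero floor in the
back-transform truncates the Gaussian model: if a class's mean curve sits
near zero on the transformed scale, a visible fraction of its measurements
lands exactly on zero and the estimator — correctly maximizing a Gaussian
likelihood the data no longer follow — misallocates class shares at *any*
sample size. The default mean curves therefore keep every class roughly two
between-subject SDs above zero (the floor binds on ~0.5% of measurements),
with $\sigma = 0.28$ and $B_{11} = 2\sigma^2$. Second, and consequently, the
generator does **not** emulate the point mass of true abstainers present in
real cohorts: passing tests show the estimators work where the model holds,
not that a zero-inflated intake distribution would leave them unbiased. Real
FFQ features the generator also does not reproduce: reporting heaping,
correlated retrospective recall errors, non-MCAR missingness, and the exact
joint covariate distribution (only its class-conditional margins are loosely
mirrored).

## Problem sizes, numerical choices and degenerate inputs

The packaged analyses and tests use desk-scale sizes chosen as adequate for
their purpose: class-number selection on $n = 3000$ subjects with candidates
$G = 1..6$, 6–8 random starts plus a warm start per candidate (well-separated
synthetic classes need far fewer than the 100 starts one would use on real
data — the pipeline default remains configurable); hazard-ratio recovery
averaged over 25–50 replicate cohorts of $n$ = 1000–2000; and null coverage
over 100 replicates. With ~65 events in an $n = 1000$ cohort (6.5% of the
postmenopausal complete cases) the reference class holds only ~10 events, and
the log-HR maximum-likelihood estimator is visibly right-skewed — an
independent Cox fit on the *true* class labels shows the same upward
small-sample bias, which shrinks at $n = 2000$ and vanishes by $n = 20{,}000$.
Recovery checks therefore compare means over replicates at their stated
sizes rather than single draws.

Other numerical conventions: posterior ties go to the lowest class index;
the energy-ratio trim uses type-7 empirical quantiles with strict
inequality, so ties at the cut are retained; a woman aged exactly 55 with an
uninformative menstrual history is postmenopausal (the $\ge 55$ clause takes
precedence over the 46–55 band); the 12 intake-frequency categories map to
servings/day by category midpoints with the open top category at 8/day;
class-trajectory prediction warns outside ages 18–70; the natural-scale
curves are plug-in back-transforms $e^{\hat y} - 1$ of the mean curve, not
the mean of the back-transformed distribution. Degenerate inputs are
rejected with named errors: non-PSD random-effect covariance, singular
within-subject covariance ($\sigma = 0$ with degenerate $B$), misaligned
posterior/survival ids, exit ages not exceeding entry ages, negative spline
coefficients, times outside the spline's boundary knots.

## Known limitations

* Stage-2 intervals condition on stage-1 estimates unless the bootstrap flag
  is used; with few events the Wald intervals inherit the usual
  small-sample optimism.
* The 1% energy-ratio trim is applied to the supplied vector as a whole; any
  sex- or centre-specific trimming must happen upstream.
* The membership model is intercept-only; covariate-dependent class
  membership, class-specific residual variances, spline link functions and
  joint longitudinal–survival estimation are out of scope.
* Only the fixed effects receive multistart scatter; membership logits and
  variance components start from the 1-class solution (configurable starts
  accept full parameter lists).
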