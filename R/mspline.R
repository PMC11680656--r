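# Non-negative spline machinery for the baseline hazard.
#
# M-splines of order k on a knot sequence are rescaled B-splines,
# M_j = k / (tau_{j+k} - tau_j) * B_j, each integrating to one over its
# support, so a non-negative coefficient vector gives a valid hazard. The
# cumulative hazard integrates the basis exactly with two-point
# Gauss-Legendre quadrature per knot segment (exact for the piecewise cubic
# integrand).

#' Weibull baseline hazard
#'
#' `h0(t) = (shape/scale) (t/scale)^(shape-1)` and
#' `H0(t) = (t/scale)^shape`, the age-timescale parametric baseline.
#'
#' @param t Positive times (ages).
#' @param shape,scale Strictly positive Weibull parameters.
#' @return List with `hazard` and `cumhaz`.
#' @export
weibull_hazard <- function(t, shape, scale) {
  if (any(t <= 0)) stop("'t' must be strictly positive")
  if (shape <= 0 || scale <= 0) stop("shape and scale must be strictly positive")
  list(hazard = (shape / scale) * (t / scale)^(shape - 1),
       cumhaz = (t / scale)^shape)
}

# augmented knot sequence for order-k M-splines
mspline_aug_knots <- function(knots, order) {
  knots <- sort(knots)
  c(rep(knots[1], order), knots[-c(1, length(knots))],
    rep(knots[length(knots)], order))
}

#' Cubic M-spline basis
#'
#' Evaluates the order-4 (cubic) M-spline basis at `t` for a full knot
#' sequence `knots` (boundary knots first/last, interior in between). Each
#' basis function is non-negative and integrates to 1 over its support.
#'
#' @param t Evaluation points within the boundary knots.
#' @param knots Increasing knot vector (length >= 2).
#' @param degree Spline degree (fixed at 3 for the analysis; kept explicit).
#' @return Matrix `length(t)` x `(length(knots) - 2 + degree + 1)`.
#' @export
mspline_basis <- function(t, knots, degree = 3) {
  order <- degree + 1
  knots <- sort(knots)
  if (any(t < knots[1] - 1e-9 | t > knots[length(knots)] + 1e-9)) {
    stop("'t' outside the boundary knots")
  }
  t <- pmin(pmax(t, knots[1]), knots[length(knots)])
  aug <- mspline_aug_knots(knots, order)
  B <- splines::splineDesign(aug, t, ord = order, outer.ok = FALSE)
  span <- aug[seq_len(ncol(B)) + order] - aug[seq_len(ncol(B))]
  sweep(B, 2, order / span, "*")
}

#' Integrated cubic M-spline basis (I-splines)
#'
#' `I_j(t) = integral of M_j from the lower boundary to t`, computed exactly
#' with per-segment two-point Gauss-Legendre quadrature (the integrand is
#' piecewise cubic). Each column rises from 0 to 1.
#'
#' @inheritParams mspline_basis
#' @return Matrix of the same dimension as [mspline_basis()].
#' @export
ispline_basis <- function(t, knots, degree = 3) {
  knots <- sort(knots)
  if (any(t < knots[1] - 1e-9 | t > knots[length(knots)] + 1e-9)) {
    stop("'t' outside the boundary knots")
  }
  t <- pmin(pmax(t, knots[1]), knots[length(knots)])
  seg_integral <- function(a, b) {
    # two-point Gauss-Legendre on [a, b]: nodes mid +- half/sqrt(3),
    # weights half each; vectorized over segments
    mid <- (a + b) / 2
    half <- (b - a) / 2
    n1 <- mid - half / sqrt(3)
    n2 <- mid + half / sqrt(3)
    half * (mspline_basis(n1, knots, degree) + mspline_basis(n2, knots, degree))
  }

  # cumulative integral at each knot (exact per full segment)
  nb <- length(knots) - 2 + degree + 1
  cum_at_knot <- matrix(0, length(knots), nb)
  for (j in seq_len(length(knots) - 1)) {
    cum_at_knot[j + 1, ] <- cum_at_knot[j, ] +
      seg_integral(knots[j], knots[j + 1])[1, ]
  }
  seg <- findInterval(t, knots, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1), length(knots) - 1)
  partial <- seg_integral(knots[seg], t)
  zero_len <- t == knots[seg]
  if (any(zero_len)) partial[zero_len, ] <- 0
  cum_at_knot[seg, , drop = FALSE] + partial
}

#' M-spline baseline hazard and cumulative hazard
#'
#' `h0(t) = sum_k eta_k M_k(t)` with non-negative coefficients and
#' `H0(t) = sum_k eta_k I_k(t)`.
#'
#' @param t Times within the boundary knots.
#' @param knots Full knot vector (boundary + interior).
#' @param coefficients Non-negative spline coefficients (one per basis
#'   function).
#' @param degree Spline degree (default 3, cubic).
#' @return List with `hazard` and `cumhaz`.
#' @export
mspline_hazard <- function(t, knots, coefficients, degree = 3) {
  nb <- length(knots) - 2 + degree + 1
  if (length(coefficients) != nb) {
    stop("need ", nb, " coefficients for this knot vector")
  }
  if (any(coefficients < 0)) stop("spline coefficients must be non-negative")
  list(hazard = drop(mspline_basis(t, knots, degree) %*% coefficients),
       cumhaz = drop(ispline_basis(t, knots, degree) %*% coefficients))
}

#' Knot placement for the M-spline baseline
#'
#' Boundary knots at the minimum entry age and maximum exit age; interior
#' knots at equally spaced quantiles of the observed event ages.
#'
#' @param entry,exit Entry and exit ages.
#' @param event Event indicator.
#' @param n_knots Total number of knots (boundary included), >= 2.
#' @return Increasing knot vector of length `n_knots`.
#' @export
place_knots <- function(entry, exit, event, n_knots) {
  if (n_knots < 2) stop("need at least 2 knots")
  boundary <- c(min(entry), max(exit))
  n_int <- n_knots - 2
  interior <- if (n_int > 0) {
    ev_ages <- exit[event == 1]
    if (length(ev_ages) < 1) stop("interior knots need observed events")
    stats::quantile(ev_ages, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
  } else numeric(0)
  sort(c(boundary[1], interior, boundary[2]))
}
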