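#' Klepsydraic reproduction function
#'
#' Closed-form prediction of the reproduced duration under the dual klepsydra
#' model (DKM). Two inflow--outflow units (lossy integrators obeying
#' \eqn{dx/dt = F - \kappa x}) represent the two intervals of a reproduction
#' trial: the first unit fills at inflow \eqn{\eta} during the encoding phase
#' of length \eqn{s}, then leaks through the inter-stimulus pause \eqn{w} and
#' the reproduction phase; the second fills at unit inflow from reproduction
#' onset. The response terminates when the two states are equal, which yields
#'
#' \deqn{r = \kappa^{-1} \log\{1 + \eta e^{-\kappa w} (1 - e^{-\kappa s})\}.}
#'
#' Only the ratio of the two inflows is identifiable, so the reproduction-phase
#' inflow is normalised to 1 and \eqn{\eta} is the encoding/reproduction inflow
#' ratio. In the lossless limit \eqn{\kappa \to 0} the formula reduces to
#' \eqn{r = \eta s}; that branch is taken analytically when
#' \eqn{\kappa s < 10^{-8}} to avoid 0/0. For \eqn{\kappa > 0} and
#' \eqn{\eta = 1} the model reproduces the classical progressive shortening of
#' \eqn{r/s} with increasing \eqn{s}.
#'
#' @param s Encoded duration(s), seconds, > 0. Recycled against `w`.
#' @param w Inter-stimulus pause(s), seconds, >= 0.
#' @param kappa Outflow (leakage) rate, 1/s, >= 0. Scalar.
#' @param eta Inflow ratio encoding/reproduction, dimensionless, > 0. Scalar.
#' @return Numeric vector of reproduced durations (seconds).
#' @seealso [simulate_reproduction_oracle()] for the independent dynamical
#'   check of this formula, [krf_inverse_eta()] for the exact inversion in
#'   `eta`.
#' @examples
#' krf(s = c(2, 4, 6), w = 2, kappa = 0.03, eta = 1)
#' krf(4, 2, kappa = 0, eta = 1) # veridical: 4
#' @export
krf <- function(s, w, kappa, eta) {
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(eta, "eta", lower = 0, strict_lower = TRUE)
  check_vector(s, "s", lower = 0, strict_lower = TRUE)
  check_vector(w, "w", lower = 0)
  n <- max(length(s), length(w))
  s <- rep_len(s, n)
  w <- rep_len(w, n)
  r <- numeric(n)
  tiny <- kappa * s < 1e-8
  r[tiny] <- eta * s[tiny]
  if (any(!tiny)) {
    r[!tiny] <- log1p(eta * exp(-kappa * w[!tiny]) *
                        (-expm1(-kappa * s[!tiny]))) / kappa
  }
  r
}

#' Invert the reproduction function in the inflow ratio
#'
#' Exact closed-form solution of `krf(s, w, kappa, eta) == r` for `eta`:
#' \deqn{\eta = (e^{\kappa r} - 1) / \{e^{-\kappa w}(1 - e^{-\kappa s})\},}
#' with the lossless limit \eqn{\eta = r/s} when \eqn{\kappa s < 10^{-8}}.
#' Used by the closed-form ("invert-mean") variant of the per-condition
#' inflow-ratio estimator and as a diagnostic.
#'
#' @param r Reproduced duration(s), seconds, > 0.
#' @inheritParams krf
#' @return The inflow ratio(s) `eta` (> 0) reproducing `r`.
#' @examples
#' eta <- krf_inverse_eta(5.16, s = 6, w = 2, kappa = 0.03)
#' krf(6, 2, 0.03, eta) # 5.16 again
#' @export
krf_inverse_eta <- function(r, s, w, kappa) {
  check_scalar(kappa, "kappa", lower = 0)
  check_vector(r, "r", lower = 0, strict_lower = TRUE)
  check_vector(s, "s", lower = 0, strict_lower = TRUE)
  check_vector(w, "w", lower = 0)
  n <- max(length(r), length(s), length(w))
  r <- rep_len(r, n)
  s <- rep_len(s, n)
  w <- rep_len(w, n)
  eta <- numeric(n)
  tiny <- kappa * s < 1e-8
  eta[tiny] <- r[tiny] / s[tiny]
  if (any(!tiny)) {
    eta[!tiny] <- expm1(kappa * r[!tiny]) /
      (exp(-kappa * w[!tiny]) * (-expm1(-kappa * s[!tiny])))
  }
  if (!all(is.finite(eta)) || any(eta <= 0)) {
    stop_domain("no finite positive inflow ratio reproduces the given r")
  }
  eta
}

# RK4 discretisation of the affine ODE dx/dt = inflow - kappa * x is itself
# affine, x[n+1] = a * x[n] + b; the coefficients are the degree-4 Taylor
# truncations of exp(-kappa*h) and inflow*(1-exp(-kappa*h))/kappa.
rk4_affine_coef <- function(inflow, kappa, h) {
  z <- kappa * h
  list(a = 1 - z + z^2 / 2 - z^3 / 6 + z^4 / 24,
       b = inflow * h * (1 - z / 2 + z^2 / 6 - z^3 / 24))
}

# State after integrating for `duration` from x0 with fixed-step RK4. The
# affine recursion is summed in closed form (geometric series), which is
# exactly the value the step-by-step loop would produce.
rk4_endpoint <- function(x0, inflow, kappa, duration, step) {
  if (duration <= 0) {
    return(x0)
  }
  n <- max(1, ceiling(duration / step))
  h <- duration / n
  co <- rk4_affine_coef(inflow, kappa, h)
  an <- co$a^n
  if (abs(co$a - 1) < 1e-14) {
    x0 + n * co$b
  } else {
    an * x0 + co$b * (an - 1) / (co$a - 1)
  }
}

#' Numerical trajectory of a single inflow--outflow unit
#'
#' Integrates the lossy-integrator dynamics \eqn{dx/dt = F - \kappa x},
#' \eqn{x(0) = 0}, with a fixed-step fourth-order Runge--Kutta scheme. For
#' \eqn{\kappa > 0} the exact solution is
#' \eqn{x(t) = (F/\kappa)(1 - e^{-\kappa t})}; the numerical trajectory is kept
#' deliberately independent of that formula so it can serve as a check.
#'
#' @param inflow Constant inflow F, flow units per second, >= 0 (only flow
#'   ratios are identifiable in the DKM).
#' @param kappa Outflow rate, 1/s, >= 0.
#' @param duration Total integration time, seconds, > 0.
#' @param step Nominal step size, seconds, > 0; the actual step divides
#'   `duration` exactly.
#' @return An object of class `iou_trajectory`: list with `times`, `states`,
#'   `inflow`, `kappa`, `step`.
#' @examples
#' tr <- iou_trajectory(inflow = 1, kappa = 0.03, duration = 6, step = 1e-3)
#' tail(tr$states, 1) # ~ (1/0.03) * (1 - exp(-0.18))
#' @export
iou_trajectory <- function(inflow, kappa, duration, step = 1e-3) {
  check_scalar(inflow, "inflow", lower = 0)
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(step, "step", lower = 0, strict_lower = TRUE)
  n <- max(1, ceiling(duration / step))
  h <- duration / n
  co <- rk4_affine_coef(inflow, kappa, h)
  states <- c(0, stats::filter(rep(co$b, n), co$a, method = "recursive"))
  structure(
    list(times = h * (0:n), states = as.numeric(states),
         inflow = inflow, kappa = kappa, step = h),
    class = "iou_trajectory"
  )
}

#' Brute-force dynamical oracle for the reproduction response
#'
#' Simulates a reproduction trial directly from the DKM dynamics, without
#' using the closed-form [krf()]: integrator 1 fills at inflow `eta` for `s`
#' seconds (RK4), leaks freely through the pause `w`, and keeps leaking during
#' reproduction while integrator 2 fills at unit inflow from reproduction
#' onset. The response is the first time the two states cross, located by
#' doubling the horizon until the state difference changes sign and then
#' bisecting to 1e-8 s. This routine is the ground truth against which the
#' closed form is validated (agreement is required to 1e-5 s).
#'
#' @inheritParams krf
#' @param step RK4 step size, seconds (default 1e-4).
#' @return Reproduced duration, seconds (scalar).
#' @examples
#' simulate_reproduction_oracle(s = 6, w = 2, kappa = 0.03, eta = 1)
#' @export
simulate_reproduction_oracle <- function(s, w, kappa, eta, step = 1e-4) {
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  check_scalar(w, "w", lower = 0)
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(eta, "eta", lower = 0, strict_lower = TRUE)
  check_scalar(step, "step", lower = 0, strict_lower = TRUE)
  x_enc <- rk4_endpoint(0, eta, kappa, s, step)
  x_rep0 <- rk4_endpoint(x_enc, 0, kappa, w, step)
  # g(t) = filling integrator minus leaking integrator, t from rep. onset
  g <- function(t) {
    rk4_endpoint(0, 1, kappa, t, step) - rk4_endpoint(x_rep0, 0, kappa, t, step)
  }
  horizon <- 10 * eta * s
  hi <- min(step, s)
  while (g(hi) < 0) {
    hi <- 2 * hi
    if (hi > horizon) {
      stop_domain("no state crossing within the horizon %.3g s; model violated",
                  horizon)
    }
  }
  lo <- hi / 2
  if (g(lo) >= 0) lo <- 0
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
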