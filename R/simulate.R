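# Ground-truth integration of the theta-modulated gamma cell.
#
# Primary coordinates are the compact phase theta_E (no blow-up at spikes);
# the QIF voltage picture V = tan(theta_E/2) is available separately for
# cross-validation of the oscillatory first-spike machinery.

tg_rhs <- function(t, y, p) {
  drive <- p$IE + p$lam * (1 + cos(y[3])) - p$gIE * y[2]
  list(c((1 - cos(y[1])) + drive * (1 + cos(y[1])),
         -p$epsI * y[2],
         p$epsTheta * p$omega))
}

#' Simulate the theta-modulated gamma cell
#'
#' Integrates the full three-variable system
#' \deqn{\dot\theta_E = (1-\cos\theta_E) +
#'   (I_E + \lambda(1+\cos\Theta) - g_{IE} s_I)(1+\cos\theta_E),\quad
#'   \dot s_I = -\epsilon_I s_I,\quad \dot\Theta = \epsilon_\Theta\omega,}
#' in theta-neuron coordinates with event detection: each upward crossing of
#' \eqn{\theta_E} through \eqn{\pi} is a spike, at which \eqn{\theta_E} wraps
#' to \eqn{-\pi} and \eqn{s_I} jumps up by one unit (the delta-function kick
#' of the instantaneously enslaved inhibitory cell; \code{gIE} absorbs the
#' kick scale). Crossing times are located by the integrator's root finder,
#' not by grid lookup. State is never reset across theta cycles, so
#' multi-cycle runs carry residual inhibition.
#'
#' @param params A [tg_params()] object.
#' @param t_end End of the integration window (dimensionless model time).
#' @param init Named numeric vector \code{c(thetaE, sI, Theta)} or
#'   \code{NULL} for the regime defaults: \code{thetaE = -pi} (oscillator,
#'   i.e. \eqn{V_E = -\infty}) or the rest state [rest_fixed_point()]
#'   (\code{IE < 0}); \code{sI = 0}; \code{Theta = -pi} (theta trough).
#' @param rtol,atol Solver tolerances. The stepper is \code{lsodar}
#'   (stiff-capable with root finding), needed near the SNIC where
#'   \eqn{\dot\theta_E \approx 0}.
#' @param n_out Number of trajectory output points.
#' @return A list of class \code{"tg_sim"}:
#'   \describe{
#'     \item{trajectory}{data frame \code{t, thetaE, sI, Theta, VE}
#'       (\code{VE = tan(thetaE/2)}).}
#'     \item{spikes}{data frame \code{j, time, phase} of spike index, spike
#'       time \eqn{T_j} and theta phase \eqn{\Theta(T_j)}.}
#'     \item{params, init, diagnostics}{inputs and solver statistics.}
#'   }
#' @examples
#' p <- tg_params(IE = 0.5, lam = 0.8, gIE = 6, epsI = 0.1,
#'                epsTheta = 0.01, omega = 4)
#' sim <- tg_simulate(p, t_end = 2 * pi / (p$epsTheta * p$omega))
#' nrow(sim$spikes)   # spikes in one theta cycle
#' @export
tg_simulate <- function(params, t_end, init = NULL,
                        rtol = 1e-9, atol = 1e-11, n_out = 2000L) {
  stopifnot(inherits(params, "tg_params"), t_end > 0)
  if (is.null(init)) {
    th0 <- if (params$IE > 0) -pi else rest_fixed_point(params)
    init <- c(thetaE = th0, sI = 0, Theta = -pi)
  } else {
    init <- stats::setNames(as.numeric(init), c("thetaE", "sI", "Theta"))
    if (init[1] < -pi || init[1] >= pi)
      stop("initial thetaE must lie in [-pi, pi)")
  }
  times <- seq(0, t_end, length.out = n_out)
  out <- deSolve::ode(
    y = init, times = times, func = tg_rhs, parms = params,
    method = "lsodar", rtol = rtol, atol = atol,
    rootfun = function(t, y, p) y[1] - pi,
    events = list(func = function(t, y, p) {
      y[1] <- y[1] - 2 * pi
      y[2] <- y[2] + 1
      y
    }, root = TRUE))
  if (any(!is.finite(out[, 2:4])))
    stop("simulation produced non-finite state; check parameters/tolerances")
  troot <- attributes(out)$troot
  troot <- troot[troot > 0 & troot <= t_end]
  traj <- data.frame(t = out[, 1], thetaE = out[, 2], sI = out[, 3],
                     Theta = out[, 4])
  traj$VE <- tan(traj$thetaE / 2)
  spikes <- data.frame(
    j = seq_along(troot), time = troot,
    phase = init[["Theta"]] + params$epsTheta * params$omega * troot)
  structure(list(trajectory = traj, spikes = spikes, params = params,
                 init = init,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    istate = attributes(out)$istate)),
            class = "tg_sim")
}

#' @export
print.tg_sim <- function(x, ...) {
  cat(sprintf(
    "theta-gamma simulation: t in [0, %g], %d spike(s), regime %s\n",
    max(x$trajectory$t), nrow(x$spikes), x$params$regime))
  invisible(x)
}

#' First spike of the uninhibited QIF equation
#'
#' Integrates the scalar quadratic integrate-and-fire voltage equation
#' \deqn{\dot V_E = V_E^2 + I_E + \lambda(1+\cos(\epsilon_\Theta\omega t - \pi))}
#' from \eqn{V_E(0) = -\infty} and returns the first blow-up time. The
#' infinite reset is handled with a finite cap: integration runs from
#' \eqn{-V_{cap}} to \eqn{+V_{cap}} and the time spent beyond the cap is
#' restored analytically as \eqn{2/V_{cap}} (for pure \eqn{\dot V = V^2}
#' flow the tail from \eqn{V_{cap}} to \eqn{\infty} takes \eqn{1/V_{cap}},
#' and likewise the entry from \eqn{-\infty}). Inhibition plays no role
#' before the first spike, so this is an independent oracle for the
#' Mathieu-equation first-spike solver.
#'
#' @param params A [tg_params()] object in the oscillator regime.
#' @param t_end Upper bound on the search window; default one theta period.
#' @param V_cap Blow-up detection cap. Default \code{1e3}.
#' @param rtol,atol Solver tolerances.
#' @return The first spike time \eqn{T_1}.
#' @export
tg_simulate_qif <- function(params, t_end = NULL, V_cap = 1e3,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "tg_params"))
  if (params$regime != "oscillator")
    stop("tg_simulate_qif() requires the oscillator regime (IE > 0).")
  if (is.null(t_end)) t_end <- 2 * pi / (params$epsTheta * params$omega)
  rhs <- function(t, y, p)
    list(y[1]^2 + p$IE + p$lam * (1 + cos(p$epsTheta * p$omega * t - pi)))
  out <- deSolve::ode(
    y = c(V = -V_cap), times = c(0, t_end), func = rhs, parms = params,
    method = "lsodar", rtol = rtol, atol = atol,
    rootfun = function(t, y, p) y[1] - V_cap)
  troot <- attributes(out)$troot
  if (is.null(troot) || !length(troot))
    stop("no blow-up before t_end; increase t_end")
  troot[1] + 2 / V_cap
}
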