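# Semi-analytic time to first spike.
#
# Oscillator regime: the Riccati substitution V = -u'/u turns the QIF
# voltage equation into the linear second-order equation
#   u'' = -(IE + lam*(1 + cos(epsTheta*omega*t - pi))) u,
# a Mathieu equation after rescaling; spike times (no inhibition before the
# first spike) are the zeros of u. Excitable regime: slow passage through
# the SNIC gives T1 = (Theta0 + pi)/(epsTheta*omega) + C0*epsTheta^(-1/3);
# both the log-order and O(1) corrections vanish for this model (see
# verify_log_term_vanishes), so the remainder is O(epsTheta^(1/3)).

#' Mathieu-equation coefficients of the oscillatory first-spike problem
#'
#' Rescaling time as \eqn{z = \epsilon_\Theta\omega t/2} puts the linearised
#' first-spike equation into standard Mathieu form
#' \eqn{u''(z) = -(a - 2q\cos 2z)\,u} with
#' \deqn{a = 4(I_E+\lambda)/(\epsilon_\Theta^2\omega^2),\qquad
#'       q = 2\lambda/(\epsilon_\Theta^2\omega^2).}
#' The \eqn{-\pi} phase offset of the theta drive becomes the sign of the
#' \eqn{\cos 2z} term (\eqn{\cos(\epsilon_\Theta\omega t - \pi) = -\cos 2z}),
#' and the drive period in \eqn{z} is \eqn{\pi}. In the oscillator regime
#' \eqn{a - 2q = 4 I_E/(\epsilon_\Theta^2\omega^2) > 0}.
#'
#' @inheritParams classify_regime
#' @return List with \code{a_m}, \code{q}, and \code{z_scale}
#'   (\eqn{= \epsilon_\Theta\omega/2}, the \eqn{t \to z} factor).
#' @export
mathieu_coeffs <- function(params) {
  if (params$regime != "oscillator")
    stop("mathieu_coeffs() requires the oscillator regime (IE > 0).")
  s2 <- (params$epsTheta * params$omega)^2
  list(a_m = 4 * (params$IE + params$lam) / s2,
       q = 2 * params$lam / s2,
       z_scale = params$epsTheta * params$omega / 2)
}

# Integrate u'' = -(IE + lam*(1 - cos(epsTheta*omega*t))) u from
# u(0)=0, u'(0)=1 and return the first positive zero of u.
# Grid sign-scan plus bracketed refinement by short re-integration.
mathieu_first_zero_time <- function(params, rtol = 1e-12, atol = 1e-14) {
  coef_t <- function(t)
    params$IE + params$lam * (1 - cos(params$epsTheta * params$omega * t))
  rhs <- function(t, y, p) list(c(y[2], -coef_t(t) * y[1]))
  t_max <- 2 * pi / (params$epsTheta * params$omega)
  # u oscillates no faster than sqrt(IE + 2 lam); resolve that period well
  h <- (2 * pi / sqrt(params$IE + 2 * params$lam)) / 100
  times <- seq(0, t_max, by = h)
  sol <- deSolve::ode(c(0, 1), times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  u <- sol[, 2]
  i <- which(u[-1] <= 0 & u[-length(u)] > 0)[1]
  if (is.na(i))
    stop("no zero of the Mathieu solution found within one theta period")
  y_lo <- c(sol[i, 2], sol[i, 3])
  t_lo <- sol[i, 1]
  f <- function(t) {
    if (t == t_lo) return(y_lo[1])
    s <- deSolve::ode(y_lo, c(t_lo, t), rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
    s[2, 2]
  }
  stats::uniroot(f, c(t_lo, sol[i + 1, 1]), f.lower = y_lo[1],
                 tol = 1e-13 * sol[i + 1, 1])$root
}

#' Time to first spike, oscillator regime (Mathieu branch)
#'
#' Solves the initial-value Mathieu problem \eqn{u(0) = 0, u'(0) = 1}
#' (encoding \eqn{V_E(0) = -\infty}: \eqn{V_E = -u'/u \to -\infty} as
#' \eqn{t \downarrow 0}; any positive \eqn{u'(0)} gives the same zeros) by
#' direct numerical integration, and returns the first positive zero of
#' \eqn{u} — the time to the first spike in the absence of inhibition. The
#' equation is integrated in the original time variable; general-order
#' Mathieu functions \eqn{Ce, Se} are never evaluated, only the one zero of
#' the one solution that matters.
#'
#' @inheritParams classify_regime
#' @param rtol,atol Integration tolerances for the linear ODE.
#' @return First spike time \eqn{T_1}.
#' @examples
#' p <- tg_params(IE = 0.05, lam = 0.5)
#' first_spike_oscillator(p)
#' @export
first_spike_oscillator <- function(params, rtol = 1e-12, atol = 1e-14) {
  if (params$regime != "oscillator")
    stop("first_spike_oscillator() requires the oscillator regime.")
  mathieu_first_zero_time(params, rtol = rtol, atol = atol)
}

#' Time to first spike, excitable regime (slow-passage branch)
#'
#' The theta drive must grow from the trough \eqn{\Theta = -\pi} to the SNIC
#' phase \eqn{\Theta_0}, taking \eqn{T_1^* = (\Theta_0+\pi)/
#' (\epsilon_\Theta\omega)}; escape from the saddle-node is then delayed by
#' the slow-passage correction \eqn{C_0\,\epsilon_\Theta^{-1/3}} with
#' \eqn{C_0} from [critical_quantities()]. Both the \eqn{\ln\epsilon_\Theta}
#' and \eqn{O(1)} terms of the passage expansion vanish for this vector
#' field, so the remainder is \eqn{O(\epsilon_\Theta^{1/3})}.
#'
#' @inheritParams classify_regime
#' @return List with \code{T1}, \code{leading} (\eqn{T_1^*}) and
#'   \code{correction} (\eqn{C_0\epsilon_\Theta^{-1/3}}).
#' @examples
#' p <- tg_params(IE = -0.5, lam = 1)
#' first_spike_excitable(p)$T1
#' @export
first_spike_excitable <- function(params) {
  if (params$regime != "excitable")
    stop("first_spike_excitable() requires the excitable regime.")
  cq <- critical_quantities(params)
  leading <- (cq$Theta0 + pi) / (params$epsTheta * params$omega)
  corr <- cq$C0 * params$epsTheta^(-1/3)
  list(T1 = leading + corr, leading = leading, correction = corr)
}

#' Time to first spike, branch selected by regime
#'
#' Dispatches to [first_spike_oscillator()] (\code{IE > 0}) or
#' [first_spike_excitable()] (excitable regime).
#'
#' @inheritParams classify_regime
#' @return List with \code{T1}, \code{branch}, and the branch's extra terms.
#' @export
first_spike <- function(params) {
  if (params$regime == "oscillator")
    return(list(T1 = first_spike_oscillator(params), branch = "mathieu"))
  if (params$regime == "excitable") {
    fs <- first_spike_excitable(params)
    return(list(T1 = fs$T1, branch = "blowup", leading = fs$leading,
                correction = fs$correction))
  }
  stop("silent regime: the cell never spikes")
}
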