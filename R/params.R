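#' Model parameters for the theta-modulated gamma circuit
#'
#' Constructs and validates the parameter vector of the theta-driven gamma
#' cell. The model is a theta neuron (phase variable \eqn{\theta_E} on
#' \eqn{[-\pi,\pi)}, spike at \eqn{\theta_E=\pi}) receiving a constant drive
#' \code{IE}, a sinusoidal theta-band drive \eqn{\lambda(1+\cos\Theta)}, and
#' delayed self-inhibition \eqn{-g_{IE} s_I} where \eqn{s_I} decays at rate
#' \code{epsI} and is kicked by one unit at each spike (the inhibitory cell
#' of the PING pair is taken to fire instantaneously with the excitatory
#' one). The theta phase advances as \eqn{d\Theta/dt = \epsilon_\Theta\omega}.
#'
#' @param IE Constant (dimensionless) drive to the gamma cell. Sign selects
#'   the dynamical regime; \code{IE = 0} is rejected as degenerate.
#' @param lam Theta-gamma coupling strength \eqn{\lambda \ge 0}.
#' @param gIE Inhibitory synaptic strength \eqn{g_{IE} \ge 0}.
#' @param epsI Inverse time constant of synaptic inhibition,
#'   \eqn{\epsilon_I > 0}. This is the \eqn{\epsilon} of the interspike
#'   interval formulas.
#' @param epsTheta Slow scaling parameter \eqn{\epsilon_\Theta > 0}; the
#'   theta angular frequency is \code{epsTheta * omega}. The time-scale
#'   separation underlying the asymptotics assumes
#'   \eqn{\epsilon_\Theta \approx \epsilon_I^2}; a warning flag (not an
#'   error) is set when the two differ by more than 50 percent.
#' @param omega Theta frequency factor \eqn{\omega > 0}.
#'
#' @return An object of class \code{"tg_params"}: a named list with the six
#'   parameters plus \code{regime} (see [classify_regime()]) and
#'   \code{scale_warn}, \code{TRUE} when
#'   \eqn{|\epsilon_\Theta-\epsilon_I^2|/\epsilon_I^2 > 0.5}.
#'
#' @examples
#' p <- tg_params(IE = 0.5, lam = 0.8, gIE = 6, epsI = 0.1,
#'                epsTheta = 0.01, omega = 4)
#' p$regime
#' @seealso [classify_regime()], [critical_quantities()], [tg_simulate()]
#' @export
tg_params <- function(IE, lam = 0, gIE = 0, epsI = 0.1,
                      epsTheta = 0.01, omega = 4) {
  stopifnot(is.numeric(IE), length(IE) == 1L, is.finite(IE),
            is.numeric(lam), length(lam) == 1L, lam >= 0,
            is.numeric(gIE), length(gIE) == 1L, gIE >= 0,
            is.numeric(epsI), length(epsI) == 1L, epsI > 0,
            is.numeric(epsTheta), length(epsTheta) == 1L, epsTheta > 0,
            is.numeric(omega), length(omega) == 1L, omega > 0)
  if (IE == 0)
    stop("IE = 0 is degenerate: both analytic spike-time branches are ",
         "singular there. Choose IE > 0 (oscillator) or IE < 0 (excitable).")
  p <- structure(
    list(IE = IE, lam = lam, gIE = gIE, epsI = epsI,
         epsTheta = epsTheta, omega = omega),
    class = "tg_params")
  p$regime <- classify_regime(p)
  p$scale_warn <- abs(epsTheta - epsI^2) / epsI^2 > 0.5
  p
}

#' @export
print.tg_params <- function(x, ...) {
  cat("Theta-modulated gamma cell parameters\n")
  cat(sprintf("  IE = %g, lambda = %g, gIE = %g\n", x$IE, x$lam, x$gIE))
  cat(sprintf("  epsI = %g, epsTheta = %g, omega = %g  (theta freq %g)\n",
              x$epsI, x$epsTheta, x$omega, x$epsTheta * x$omega))
  cat(sprintf("  regime: %s%s\n", x$regime,
              if (isTRUE(x$scale_warn))
                "  [note: epsTheta far from epsI^2]" else ""))
  invisible(x)
}

#' Classify the dynamical regime of the gamma cell
#'
#' With theta drive alone (no inhibition), the net input to the gamma cell is
#' \eqn{I_E + \lambda(1+\cos\Theta)}, ranging over \eqn{[I_E, I_E+2\lambda]}.
#' Three regimes follow:
#' \describe{
#'   \item{oscillator}{\code{IE > 0}: net input positive at every theta
#'     phase; the cell fires intrinsically and theta only modulates its rate.}
#'   \item{excitable}{\code{IE < 0} and \code{2*lam + IE > 0}: the net input
#'     changes sign along the theta cycle, sweeping the cell back and forth
#'     across a SNIC bifurcation; spikes are gated to a theta-phase window.}
#'   \item{silent}{\code{IE <= -2*lam}: net input never positive, no spikes.}
#' }
#'
#' @param params A [tg_params()] object (or a bare list with the same
#'   fields, used internally during construction).
#' @return One of \code{"oscillator"}, \code{"excitable"}, \code{"silent"}.
#' @export
classify_regime <- function(params) {
  IE <- params$IE; lam <- params$lam
  if (IE == 0) stop("IE = 0 is degenerate; no regime assigned.")
  if (IE > 0) return("oscillator")
  if (2 * lam + IE > 0) return("excitable")
  "silent"
}

#' Resting fixed point of the gamma cell at the theta trough
#'
#' For \code{IE < 0} and the theta drive at its minimum (\eqn{\Theta=-\pi},
#' where \eqn{1+\cos\Theta = 0}) the phase equation
#' \eqn{\dot\theta_E = (1-\cos\theta_E) + I_E(1+\cos\theta_E)} has a stable
#' rest state \eqn{\theta_0 \in (-\pi, 0)} determined by
#' \eqn{(1-I_E)\cos\theta_0 = 1+I_E}. The cell relaxes there during the
#' silent part of the theta cycle and it is the canonical initial condition
#' for excitable-regime runs.
#'
#' @inheritParams classify_regime
#' @return \eqn{\theta_0} in radians, in \eqn{(-\pi, 0)}.
#' @export
rest_fixed_point <- function(params) {
  IE <- params$IE
  if (IE >= 0)
    stop("rest_fixed_point() requires IE < 0 (excitable or silent regime); ",
         "for IE > 0 the cell has no rest state.")
  -acos((1 + IE) / (1 - IE))
}

#' Theta phase of the SNIC crossing
#'
#' In the excitable regime the net drive \eqn{F(\Theta) = I_E +
#' \lambda(1+\cos\Theta)} vanishes at \eqn{\cos\Theta_0 =
#' -(\lambda+I_E)/\lambda}: the saddle-node-on-invariant-circle bifurcation
#' that the rising theta drive pushes the cell through. The stored solution
#' is the ascending-side crossing \eqn{\Theta_0 \in (-\pi, 0)}; the
#' descending-side exit crossing is \eqn{-\Theta_0}.
#'
#' @inheritParams classify_regime
#' @return \eqn{\Theta_0} in radians, in \eqn{(-\pi, 0)}.
#' @export
snic_phase <- function(params) {
  if (params$regime != "excitable")
    stop("snic_phase() requires the excitable regime (IE < 0 < 2*lam + IE): ",
         "an oscillator never reaches the SNIC under theta drive alone and ",
         "a silent cell never crosses it.")
  -acos(-(params$lam + params$IE) / params$lam)
}

#' Critical quantities of the excitable regime
#'
#' Collects the constants entering the slow-passage first-spike asymptotics:
#' the rest state \eqn{\theta_0}, the SNIC phase \eqn{\Theta_0}, the local
#' normal-form coefficient
#' \eqn{a = 2\sqrt{-I_E(2\lambda+I_E)}}
#' (twice the slope of \eqn{F(\Theta)} at \eqn{\Theta_0}; the factor 2 is the
#' value of \eqn{1+\cos\theta_E} at the saddle-node point \eqn{\theta_E=0}),
#' the universal slow-passage constant \eqn{\Omega_0 \approx -2.33811} (see
#' [slow_passage_constant()]) and the first-spike correction coefficient
#' \deqn{C_0 = -2^{1/3}\,\Omega_0 / (\omega a)^{1/3} > 0.}
#'
#' @inheritParams classify_regime
#' @return A list of class \code{"tg_critical"} with fields \code{theta0},
#'   \code{Theta0}, \code{a_snic}, \code{Omega0}, \code{C0}.
#' @export
critical_quantities <- function(params) {
  if (params$regime != "excitable")
    stop("critical_quantities() requires the excitable regime.")
  a <- 2 * sqrt(-params$IE * (2 * params$lam + params$IE))
  Om0 <- slow_passage_constant()
  structure(
    list(theta0 = rest_fixed_point(params),
         Theta0 = snic_phase(params),
         a_snic = a,
         Omega0 = Om0,
         C0 = -2^(1/3) * Om0 / (params$omega * a)^(1/3)),
    class = "tg_critical")
}

#' @export
print.tg_critical <- function(x, ...) {
  cat(sprintf(
    "SNIC critical quantities: theta0 = %.6f, Theta0 = %.6f\n  a = %.6f, Omega0 = %.6f, C0 = %.6f\n",
    x$theta0, x$Theta0, x$a_snic, x$Omega0, x$C0))
  invisible(x)
}

#' Verify that the logarithmic slow-passage correction vanishes
#'
#' The passage-time expansion through a dynamically crossed saddle-node
#' carries, in general, a term of order \eqn{\ln\epsilon_\Theta} whose
#' coefficient is built from \eqn{\partial\varphi/\partial x},
#' \eqn{\partial^3\varphi/\partial x^3} and \eqn{\partial\psi/\partial x}
#' evaluated at the singular point \eqn{S = (0, \Theta_0)}, where
#' \eqn{\varphi(x, y) = (1-\cos x) + (I_E+\lambda(1+\cos y))(1+\cos x)} is
#' the fast vector field and \eqn{\psi \equiv \omega} the slow one. For this
#' model all odd x-derivatives of \eqn{\varphi} are proportional to
#' \eqn{\sin x} and vanish at \eqn{x = 0}, and \eqn{\psi} is constant, so the
#' log coefficient is exactly zero and the first-spike formula needs no
#' \eqn{\ln\epsilon_\Theta} term. Derivatives are evaluated from their exact
#' trigonometric closed forms so the tolerance can sit at machine scale.
#'
#' @inheritParams classify_regime
#' @param tol Tolerance on each derivative magnitude. Default \code{1e-10}.
#' @return A list: \code{ok} (logical), \code{phi_x}, \code{phi_xxx},
#'   \code{psi_x} (the evaluated derivatives at \eqn{S}).
#' @export
verify_log_term_vanishes <- function(params, tol = 1e-10) {
  if (params$regime != "excitable")
    stop("verify_log_term_vanishes() requires the excitable regime.")
  Theta0 <- snic_phase(params)
  # phi_x = sin(x) * (1 - IE - lam*(1+cos y)); odd derivatives carry sin(x)
  g <- 1 - params$IE - params$lam * (1 + cos(Theta0))
  phi_x <- sin(0) * g
  phi_xxx <- -sin(0) * g
  psi_x <- 0           # psi(x, y) = omega, constant
  list(ok = abs(phi_x) < tol && abs(phi_xxx) < tol && abs(psi_x) < tol,
       phi_x = phi_x, phi_xxx = phi_xxx, psi_x = psi_x)
}

#' Read model parameters from a flat key-value config file
#'
#' Accepts a plain-text file of \code{key = value} or \code{key: value}
#' lines (\code{#} comments allowed) with keys \code{IE}, \code{lambda},
#' \code{gIE}, \code{epsI}, \code{epsTheta}, \code{omega}. Missing keys fall
#' back to the [tg_params()] defaults.
#'
#' @param path Path to the config file.
#' @return A [tg_params()] object.
#' @export
tg_params_from_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "[=:]")
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2])), 0)
  named <- stats::setNames(as.list(vals), keys)
  args <- list()
  map <- c(IE = "IE", lambda = "lam", lam = "lam", gIE = "gIE",
           epsI = "epsI", epsTheta = "epsTheta", omega = "omega")
  for (k in names(named)) if (k %in% names(map)) args[[map[[k]]]] <- named[[k]]
  do.call(tg_params, args)
}
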