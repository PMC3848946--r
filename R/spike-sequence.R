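# Subsequent spikes under strong feedback inhibition.
#
# After each spike the synapse jumps and the cell is pushed below the SNIC
# (inhibition dominance, gIE > IE + 2*lam). The next spike waits for the
# inhibition to decay back to the bifurcation level — a log-time of order
# 1/eps — plus the universal slow-passage delay of order eps^(-1/3). All
# formulas here use eps = epsI; the theta phase advances with epsTheta.

# net theta drive at phase Theta
tg_drive <- function(params, Theta)
  params$IE + params$lam * (1 + cos(Theta))

#' Does inhibition dominate the maximal drive?
#'
#' The subsequent-spike analysis requires a single spike's inhibition to
#' push the cell below the SNIC bifurcation at any theta phase:
#' \eqn{g_{IE} > I_E + 2\lambda} (strict). All interspike-interval and
#' spike-count formulas assume this; their wrappers raise an applicability
#' error when it fails.
#'
#' @inheritParams classify_regime
#' @return \code{TRUE} or \code{FALSE}.
#' @export
check_inhibition_dominance <- function(params)
  params$gIE > params$IE + 2 * params$lam

stop_if_not_dominant <- function(params) {
  if (!check_inhibition_dominance(params))
    stop("inhibition does not dominate (requires gIE > IE + 2*lam): ",
         "the cell never re-crosses the SNIC and the interspike formulas ",
         "do not apply.")
}

#' Phase-modulated interspike interval
#'
#' Given the theta phase \eqn{\Theta_{j-1}} at the previous spike, the next
#' interval is the inhibition-decay time back to the bifurcation plus the
#' slow-passage delay:
#' \deqn{\Delta T_j = \frac{1}{\epsilon}\ln\frac{g_{IE}}{F(\Theta_{j-1})}
#'   - \frac{\Omega_0}{\epsilon^{1/3} F(\Theta_{j-1})^{1/3}},}
#' where \eqn{F(\Theta) = I_E + \lambda(1+\cos\Theta)} is the net theta
#' drive and \eqn{\epsilon = \epsilon_I}. Both terms are positive
#' (\eqn{\Omega_0 < 0}); \eqn{\Delta T} is smallest at the theta peak
#' (\eqn{\Theta = 0}) and largest at the trough.
#'
#' @inheritParams classify_regime
#' @param Theta_prev Theta phase at the previous spike, radians.
#' @return The interval \eqn{\Delta T_j}.
#' @export
isi <- function(params, Theta_prev) {
  stop_if_not_dominant(params)
  F <- tg_drive(params, Theta_prev)
  if (F <= 0)
    stop("net drive is non-positive at Theta_prev = ", signif(Theta_prev, 4),
         ": phase outside the active window, no next spike predicted.")
  eps <- params$epsI
  Om0 <- slow_passage_constant()
  log(params$gIE / F) / eps - Om0 / (eps^(1/3) * F^(1/3))
}

#' Intrinsic PING period (no theta modulation)
#'
#' The interval of the unmodulated inhibition-gated loop,
#' \deqn{\Delta T^{IN} = \frac{1}{\epsilon}\ln\frac{g_{IE}}{I_E}
#'   - \frac{\Omega_0}{\epsilon^{1/3} I_E^{1/3}},}
#' i.e. [isi()] with the coupling switched off. Requires \code{IE > 0}.
#'
#' @inheritParams classify_regime
#' @return The intrinsic period.
#' @export
isi_intrinsic <- function(params) {
  if (params$IE <= 0)
    stop("isi_intrinsic() requires the oscillator regime (IE > 0).")
  stop_if_not_dominant(params)
  eps <- params$epsI
  Om0 <- slow_passage_constant()
  log(params$gIE / params$IE) / eps -
    Om0 / (eps^(1/3) * params$IE^(1/3))
}

#' Quadratic expansions of the interspike interval at its extremes
#'
#' Second-order Taylor expansions of [isi()] in the theta phase about the
#' trough (\eqn{\Theta = -\pi}, where the interval is longest) and the peak
#' (\eqn{\Theta = 0}, where it is shortest). Writing
#' \eqn{u = \Theta + \pi} and \eqn{F_2 = I_E + 2\lambda}:
#' \deqn{\Delta T^{max}(u) = \Delta T^{IN}
#'   - \frac{\lambda u^2}{2\epsilon I_E}
#'   + \frac{\Omega_0\lambda u^2}{6\,\epsilon^{1/3} I_E^{4/3}},}
#' \deqn{\Delta T^{min}(\Theta) = \Delta T^{IN}
#'   - \frac{1}{\epsilon}\Big[\ln\frac{F_2}{I_E}
#'     - \frac{\lambda\Theta^2}{2F_2}\Big]
#'   - \frac{\Omega_0}{\epsilon^{1/3}}\Big[\frac{1}{F_2^{1/3}}
#'     - \frac{1}{I_E^{1/3}} + \frac{\lambda\Theta^2}{6F_2^{4/3}}\Big].}
#' Both are re-derived term by term from [isi()] (the curvature of
#' \eqn{F^{-1/3}} enters with the sign the chain rule gives, which at the
#' trough is \eqn{+\Omega_0}, a negative contribution). At the expansion
#' points themselves they reduce to \eqn{\Delta T^{IN}} and to the global
#' minimum interval; the reciprocals \eqn{1/\Delta T} bound the attainable
#' instantaneous gamma frequencies.
#'
#' @inheritParams classify_regime
#' @param Theta_prev Phase at which to evaluate the expansions, radians.
#' @return List with \code{isi_max} (trough expansion at \code{Theta_prev})
#'   and \code{isi_min} (peak expansion at \code{Theta_prev}).
#' @export
isi_extrema <- function(params, Theta_prev = c(-pi, 0)) {
  if (params$IE <= 0)
    stop("isi_extrema() requires the oscillator regime (IE > 0).")
  stop_if_not_dominant(params)
  eps <- params$epsI; IE <- params$IE; lam <- params$lam
  Om0 <- slow_passage_constant()
  dTin <- isi_intrinsic(params)
  th <- if (length(Theta_prev) == 2) Theta_prev else rep(Theta_prev, 2)
  u <- th[1] + pi
  dTmax <- dTin - lam * u^2 / (2 * eps * IE) +
    Om0 * lam * u^2 / (6 * eps^(1/3) * IE^(4/3))
  F2 <- IE + 2 * lam
  dTmin <- dTin -
    (log(F2 / IE) - lam * th[2]^2 / (2 * F2)) / eps -
    (Om0 / eps^(1/3)) * (F2^(-1/3) - IE^(-1/3) +
                           lam * th[2]^2 / (6 * F2^(4/3)))
  list(isi_max = dTmax, isi_min = dTmin)
}

#' Predicted number of gamma spikes per theta cycle
#'
#' Averages the interval formula over the firing window and inverts it: the
#' count \eqn{M} is the largest integer satisfying
#' \deqn{\frac{M}{L}\Big[\epsilon\int_W \ln\frac{g_{IE}}{F(\Theta)}\,d\Theta
#'   + \epsilon^{5/3}\int_W \frac{-\Omega_0}{F(\Theta)^{1/3}}\,d\Theta\Big]
#'   < \frac{L}{\omega},}
#' where the window \eqn{W = \{\Theta : F(\Theta) > 0\}} is the full circle
#' (oscillator regime, \eqn{L = 2\pi}) or the supra-threshold phase band
#' \eqn{(\Theta_0, -\Theta_0)} of length \eqn{L = 2|\Theta_0|} (excitable
#' regime). Integrals are adaptive quadratures; in the excitable case the
#' integrands have integrable endpoint singularities (\eqn{F \to 0}), which
#' the quadrature handles.
#'
#' The bound counts interspike intervals: a train spanning \eqn{M}
#' intervals contains \eqn{M+1} spikes, the first arriving near the start
#' of the active epoch. The returned count is therefore the number of
#' spikes, \eqn{\lceil x\rceil} where \eqn{x} solves the equality (an exact
#' integer tie gives \eqn{x} itself: \eqn{x-1} strict intervals plus the
#' initial spike). In the excitable regime the count is zero whenever the
#' analytic first spike does not fit inside the supra-threshold window
#' (the slow-passage delay exceeding the window closes the burst entirely,
#' as happens for \eqn{\lambda \to -I_E/2^+}). The estimate is a
#' cycle-average: it is known to over-predict for very small \eqn{\lambda}
#' and under-predict when \eqn{\lambda} is large enough that inhibition no
#' longer times the spikes.
#'
#' @inheritParams classify_regime
#' @return Integer count \eqn{M \ge 0}.
#' @examples
#' p <- tg_params(IE = 0.5, lam = 0.8, gIE = 6)
#' spike_count(p)
#' @export
spike_count <- function(params) {
  stop_if_not_dominant(params)
  if (params$regime == "silent") return(0L)
  Om0 <- slow_passage_constant()
  eps <- params$epsI
  if (params$regime == "oscillator") {
    lo <- -pi; hi <- pi; L <- 2 * pi
  } else {
    Theta0 <- snic_phase(params)
    lo <- Theta0; hi <- -Theta0; L <- 2 * abs(Theta0)
    # the first spike must land inside the window: entry-to-exit time
    # L/(epsTheta*omega) must exceed the slow-passage escape delay
    if (first_spike_excitable(params)$correction >=
          L / (params$epsTheta * params$omega))
      return(0L)
  }
  I1 <- stats::integrate(function(th) log(params$gIE / tg_drive(params, th)),
                         lo, hi, rel.tol = 1e-10, abs.tol = 1e-10)$value
  I2 <- stats::integrate(function(th) -Om0 * tg_drive(params, th)^(-1/3),
                         lo, hi, rel.tol = 1e-10, abs.tol = 1e-10)$value
  x <- L^2 / (params$omega * (eps * I1 + eps^(5/3) * I2))
  max(0L, as.integer(ceiling(x)))
}

#' Second spike in the excitable regime
#'
#' Just after the first spike the drive is barely above threshold and the
#' inhibition must decay almost completely, so the second interval is
#' logarithmically long. Solving the threshold-crossing balance for
#' \eqn{\epsilon T_2^* = -\ln\epsilon - \ln(-\ln\epsilon) + A} with
#' \deqn{A = \ln\frac{g_{IE}}{-\lambda\,\omega\sin\Theta_0}}
#' (well defined: \eqn{\sin\Theta_0 < 0}) gives the refined estimate; the
#' leading-order version keeps only \eqn{-\ln\epsilon/\epsilon}. The phase
#' advances by \eqn{\Theta_2 - \Theta_1 \approx -\omega\epsilon\ln\epsilon}
#' (using \eqn{\epsilon_\Theta = \epsilon^2} for the phase increment of the
#' leading gap).
#'
#' @inheritParams classify_regime
#' @param T1 First spike time to which the gap is added (analytic or
#'   simulated).
#' @return List with \code{T2_leading}, \code{T2_refined}, \code{A}, and
#'   \code{dTheta} (the leading phase advance).
#' @export
second_spike_excitable <- function(params, T1) {
  if (params$regime != "excitable")
    stop("second_spike_excitable() requires the excitable regime.")
  stop_if_not_dominant(params)
  eps <- params$epsI
  if (eps >= 1)
    stop("second-spike asymptotics require epsI < 1 (so -log(epsI) > 0).")
  Theta0 <- snic_phase(params)
  A <- log(params$gIE / (-params$lam * params$omega * sin(Theta0)))
  list(T2_leading = T1 - log(eps) / eps,
       T2_refined = T1 + (-log(eps) - log(-log(eps)) + A) / eps,
       A = A,
       dTheta = -params$omega * eps * log(eps))
}

#' Assemble the full predicted spike sequence for one theta cycle
#'
#' Chains the first-spike branch, the recursive interval formula and (in
#' the excitable regime) the second-spike asymptotics into a predicted
#' spike train: \eqn{T_1} from the regime-matched branch, then
#' \eqn{\Theta_j = \Theta_{j-1} + \epsilon_\Theta\omega\,\Delta T_j},
#' \eqn{T_j = T_{j-1} + \Delta T_j}, appending while the next spike stays
#' inside one theta period (oscillator) or inside the supra-threshold phase
#' window (excitable; the sequence also stops if the interval formula stops
#' applying). The independent count estimate [spike_count()] is attached
#' and a warning is emitted when the assembled train disagrees with it.
#'
#' @inheritParams classify_regime
#' @return A list of class \code{"tg_prediction"}: \code{T1}, \code{times},
#'   \code{isis}, \code{phases}, \code{M} (count from [spike_count()]),
#'   \code{isi_intrinsic} (oscillator only), \code{isi_min}, \code{isi_max}
#'   (oscillator only), \code{branch}.
#' @examples
#' p <- tg_params(IE = 0.5, lam = 0.8, gIE = 6)
#' pred <- predict_spike_sequence(p)
#' pred$times
#' @export
predict_spike_sequence <- function(params) {
  stop_if_not_dominant(params)
  period <- 2 * pi / (params$epsTheta * params$omega)
  dphase <- function(dt) params$epsTheta * params$omega * dt
  if (params$regime == "oscillator") {
    T1 <- first_spike_oscillator(params)
    times <- T1
    phases <- -pi + dphase(T1)
    repeat {
      dT <- isi(params, phases[length(phases)])
      t_next <- times[length(times)] + dT
      if (t_next >= period) break
      times <- c(times, t_next)
      phases <- c(phases, phases[length(phases)] + dphase(dT))
    }
    ex <- isi_extrema(params)
    out <- list(T1 = T1, times = times, isis = diff(times),
                phases = phases, M = spike_count(params),
                isi_intrinsic = isi_intrinsic(params),
                isi_max = ex$isi_max, isi_min = ex$isi_min,
                branch = "mathieu")
  } else if (params$regime == "excitable") {
    Theta0 <- snic_phase(params)
    fs <- first_spike_excitable(params)
    T1 <- fs$T1
    times <- T1
    phases <- -pi + dphase(T1)
    s2 <- second_spike_excitable(params, T1)
    ph2 <- phases[1] + dphase(s2$T2_refined - T1)
    if (s2$T2_refined < period && ph2 < -Theta0) {
      times <- c(times, s2$T2_refined)
      phases <- c(phases, ph2)
      repeat {
        ph <- phases[length(phases)]
        if (tg_drive(params, ph) <= 0) break
        dT <- isi(params, ph)
        t_next <- times[length(times)] + dT
        ph_next <- ph + dphase(dT)
        if (t_next >= period || ph_next >= -Theta0) break
        times <- c(times, t_next)
        phases <- c(phases, ph_next)
      }
    }
    out <- list(T1 = T1, times = times, isis = diff(times),
                phases = phases, M = spike_count(params),
                branch = "blowup")
  } else {
    stop("silent regime: no spikes to predict")
  }
  if (length(out$times) != out$M)
    warning(sprintf(
      "assembled sequence has %d spike(s) but the count estimate gives %d",
      length(out$times), out$M))
  class(out) <- "tg_prediction"
  out
}

#' @export
print.tg_prediction <- function(x, ...) {
  cat(sprintf("predicted spike sequence (%s branch): %d spike(s), M = %d\n",
              x$branch, length(x$times), x$M))
  cat("  times:", paste(signif(x$times, 5), collapse = ", "), "\n")
  invisible(x)
}
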