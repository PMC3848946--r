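# Shared parameter fixtures: the published figure-style parameter sets.
# All angles radians, time in the dimensionless units of the model.

theta_period <- function(p) 2 * pi / (p$epsTheta * p$omega)

# oscillator sets with strong inhibition (per-cycle dynamics figures)
fig_osc_strong <- tg_params(IE = 0.5, lam = 0.8, gIE = 6, epsI = 0.1,
                            epsTheta = 0.01, omega = 4)
fig_osc_weakdrive <- tg_params(IE = 0.1, lam = 0.5, gIE = 6, epsI = 0.1,
                               epsTheta = 0.01, omega = 4)
# excitable sets (burst-in-window figures)
fig_exc_shallow <- tg_params(IE = -0.1, lam = 1, gIE = 6, epsI = 0.1,
                             epsTheta = 0.01, omega = 4)
fig_exc_deep <- tg_params(IE = -0.5, lam = 1, gIE = 6, epsI = 0.1,
                          epsTheta = 0.01, omega = 4)

# model RHS for theta_E alone (used as an independent oracle in root checks)
thetaE_rhs <- function(theta, IE, lam = 0, Theta = -pi, sI = 0, gIE = 0) {
  (1 - cos(theta)) + (IE + lam * (1 + cos(Theta)) - gIE * sI) *
    (1 + cos(theta))
}
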