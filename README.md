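# thetagamma

Semi-analytic spike-time prediction for a theta-modulated gamma cell,
validated against exact numerical simulation.

## The problem

Cross-frequency coupling between slow theta-band (1–8 Hz) and fast
gamma-band (30–100 Hz) rhythms is a central motif in hippocampal and
cortical dynamics: the phase of the slow rhythm gates or modulates the
fast one. For a minimal model of this motif — a single excitatory gamma
cell with delayed self-inhibition (a reduced PING loop), driven by a
sinusoidal theta oscillator — the timing of every gamma spike within a
theta cycle can be predicted in closed or semi-closed form. This package
implements both sides of that program for computational neuroscientists:
the predictions, and the ground-truth simulator they are tested against.

The model, in theta-neuron (type I / quadratic integrate-and-fire) form:

$$\dot\theta_E = (1-\cos\theta_E) + \bigl(I_E + \lambda(1+\cos\Theta) -
g_{IE}s_I\bigr)(1+\cos\theta_E), \qquad
\dot s_I = -\epsilon_I s_I + \delta(\theta_E-\pi), \qquad
\dot\Theta = \epsilon_\Theta\omega.$$

Depending on the sign of the constant drive $I_E$ the cell is an
intrinsic **oscillator** whose rate theta modulates, or an **excitable**
unit that fires only in the theta-phase window where the net drive
$F(\Theta) = I_E + \lambda(1+\cos\Theta)$ is positive, entered through a
SNIC bifurcation.

The prediction stack:

* **First spike, oscillator:** the no-inhibition voltage equation
  linearises to a Mathieu equation $u'' = -(a - 2q\cos 2z)u$; the first
  zero of the initial-value solution is the spike time
  (`first_spike_oscillator()`).
* **First spike, excitable:** slow passage through the SNIC gives
  $T_1 = (\Theta_0+\pi)/(\epsilon_\Theta\omega) +
  C_0\epsilon_\Theta^{-1/3}$ with
  $C_0 = -2^{1/3}\Omega_0/(\omega a)^{1/3}$, where
  $\Omega_0 \approx -2.33811$ is the universal Airy/Bessel slow-passage
  constant (`first_spike_excitable()`, `slow_passage_constant()`).
* **Later spikes:** interval recursion
  $\Delta T_j = \epsilon^{-1}\ln(g_{IE}/F) - \Omega_0\epsilon^{-1/3}F^{-1/3}$,
  its phase expansions (`isi()`, `isi_extrema()`), log-time second-spike
  asymptotics in the excitable regime (`second_spike_excitable()`), and a
  per-cycle spike-count bound (`spike_count()`), assembled into a full
  predicted train by `predict_spike_sequence()`.
* **Ground truth:** `tg_simulate()` integrates the full system with
  root-finding spike detection; `tg_simulate_qif()` is an independent
  voltage-coordinate check. Sweep drivers (`run_first_spike_sweep()`,
  `run_count_sweep()`) compare the two over parameter grids and
  round-trip provenance-stamped CSV tables.

See the vignette `vignettes/theta-gamma-predictions.Rmd` for the science
and the numerical choices.

## Worked example

An excitable cell ($I_E=-0.5$, $\lambda=1$, $g_{IE}=6$, $\epsilon_I=0.1$,
$\epsilon_\Theta=0.01$, $\omega=4$), one theta period:

```r
library(thetagamma)
p <- tg_params(IE = -0.5, lam = 1, gIE = 6, epsI = 0.1,
               epsTheta = 0.01, omega = 4)
critical_quantities(p)
#> SNIC critical quantities: theta0 = -1.230959, Theta0 = -2.094395
#>   a = 1.732051, Omega0 = -2.338107, C0 = 1.545258

first_spike_excitable(p)$T1
#> [1] 33.35239

sim <- tg_simulate(p, t_end = 2 * pi / (p$epsTheta * p$omega))
round(sim$spikes$time, 3)
#> [1] 33.248 56.238 75.870 97.331
spike_count(p)
#> [1] 4
```

Reading: the theta drive crosses the SNIC phase
$\Theta_0 = -2\pi/3$ after $26.18$ time units and the slow-passage delay
adds $C_0\,\epsilon_\Theta^{-1/3} = 7.17$, predicting the first spike at
$33.35$ — the simulation fires at $33.25$ (0.3% off). The count bound
predicts the simulated burst of 4 spikes exactly, confined to the
supra-threshold phase window.

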