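test_that("inhibition dominance condition and boundary", {
  expect_true(check_inhibition_dominance(fig_osc_strong))
  expect_false(check_inhibition_dominance(
    tg_params(IE = 0.5, lam = 0.8, gIE = 0.5 + 2 * 0.8)))  # exact boundary
  p_weak <- tg_params(IE = 0.5, lam = 0.8, gIE = 1)
  expect_error(isi(p_weak, 0), "dominate")
  expect_error(spike_count(p_weak), "dominate")
})

test_that("interval formula: intrinsic limit, extrema in phase", {
  # at the theta peak with coupling off the interval is the intrinsic one
  p0 <- tg_params(IE = 0.5, lam = 0, gIE = 6, epsI = 0.1)
  expect_equal(isi(p0, 0), isi_intrinsic(p0), tolerance = 1e-12)
  expect_equal(isi_intrinsic(p0),
               10 * log(12) + 2.33810741 / (0.1^(1/3) * 0.5^(1/3)),
               tolerance = 1e-6)
  # intrinsic period decreases with drive
  ivals <- vapply(c(0.1, 0.3, 0.5, 1), function(i)
    isi_intrinsic(tg_params(IE = i, lam = 0, gIE = 6)), 0)
  expect_true(all(diff(ivals) < 0))
  # gIE -> IE+: log term vanishes
  p_close <- tg_params(IE = 0.5, lam = 0, gIE = 0.5 + 1e-9)
  expect_equal(isi_intrinsic(p_close),
               -slow_passage_constant() / (0.1^(1/3) * 0.5^(1/3)),
               tolerance = 1e-6)
  # modulated interval is minimal at the peak, maximal at the trough
  p <- fig_osc_strong
  phases <- seq(-pi + 1e-6, pi - 1e-6, length.out = 41)
  iv <- vapply(phases, function(th) isi(p, th), 0)
  expect_equal(phases[which.min(iv)], 0, tolerance = 0.1)
  expect_true(all(iv >= isi(p, 0) - 1e-12))
  expect_true(all(iv <= isi(p, -pi + 1e-9) + 1e-12))
  # outside the active window the formula refuses
  p_exc <- fig_exc_deep
  expect_error(isi(p_exc, -pi), "active window")
})

test_that("quadratic expansions agree with the interval formula to 2nd order", {
  p <- fig_osc_strong
  # at the expansion points: trough expansion = intrinsic period exactly,
  # peak expansion = global minimum
  ex <- isi_extrema(p)
  expect_equal(ex$isi_max, isi_intrinsic(p), tolerance = 1e-12)
  expect_equal(ex$isi_min, isi(p, 0), tolerance = 1e-12)
  # second-order agreement near each expansion point: residual is O(u^3)
  for (u in c(0.1, 0.05, 0.025)) {
    e_tr <- abs(isi_extrema(p, c(-pi + u, 0))$isi_max - isi(p, -pi + u))
    e_pk <- abs(isi_extrema(p, c(-pi, u))$isi_min - isi(p, u))
    expect_lt(e_tr, 5 * u^3 / p$epsI)
    expect_lt(e_pk, 5 * u^3 / p$epsI)
  }
  # explicit closed form of the minimum
  Om0 <- slow_passage_constant()
  dTin <- isi_intrinsic(p)
  expect_equal(ex$isi_min,
               dTin - log((p$IE + 2 * p$lam) / p$IE) / p$epsI -
                 (Om0 / p$epsI^(1/3)) *
                 ((p$IE + 2 * p$lam)^(-1/3) - p$IE^(-1/3)),
               tolerance = 1e-12)
})

test_that("spike count bound: applicability limits and window collapse", {
  # excitable window collapsing (lam -> -IE/2): no supra-threshold phase
  expect_identical(spike_count(tg_params(IE = -0.5, lam = 0.2501, gIE = 6)),
                   0L)
  expect_identical(spike_count(tg_params(IE = -1, lam = 10, gIE = 30,
                                         epsI = 0.1)) > 0, TRUE)
})

test_that("count bound matches simulation on strong-inhibition sets", {
  for (p in list(fig_osc_strong, fig_osc_weakdrive, fig_exc_deep)) {
    sim <- tg_simulate(p, t_end = theta_period(p))
    expect_identical(spike_count(p), nrow(sim$spikes))
  }
})

test_that("second-spike asymptotics in the excitable regime", {
  p <- fig_exc_deep
  s2 <- second_spike_excitable(p, T1 = 0)
  expect_equal(s2$T2_leading, -log(0.1) / 0.1, tolerance = 1e-12)
  expect_equal(s2$A, log(6 / (1 * 4 * sin(2 * pi / 3))), tolerance = 1e-12)
  expect_equal(s2$T2_refined,
               (-log(0.1) - log(-log(0.1)) + s2$A) / 0.1, tolerance = 1e-12)
  expect_equal(s2$dTheta, -4 * 0.1 * log(0.1), tolerance = 1e-12)
  expect_error(second_spike_excitable(fig_osc_strong, 0), "excitable")
  expect_error(second_spike_excitable(
    tg_params(IE = -0.5, lam = 1, gIE = 6, epsI = 1.5), 0), "epsI < 1")
})

test_that("second-spike gap follows the threshold-crossing balance", {
  # independent oracle: solve the crossing equation
  #   F(Theta1 + epsTheta*omega*t) - gIE exp(-epsI t) = 0
  # at the idealised post-spike phase Theta1 = Theta0; the refined
  # asymptotic approximates this root closely, the leading one does not
  p <- fig_exc_deep
  Th0 <- snic_phase(p)
  g <- function(t) p$IE + p$lam * (1 + cos(Th0 + p$epsTheta * p$omega * t)) -
    p$gIE * exp(-p$epsI * t)
  t_star <- uniroot(g, c(5, 40), tol = 1e-10)$root
  s2 <- second_spike_excitable(p, T1 = 0)
  expect_lt(abs(s2$T2_refined - t_star), 1.5)
  expect_gt(abs(s2$T2_leading - t_star), 2.5)
})

test_that("assembled sequences: uniform trains and windowed bursts", {
  # lam = 0 oscillator: spikes equally spaced at the intrinsic period
  p0 <- tg_params(IE = 0.5, lam = 0, gIE = 6)
  pred0 <- suppressWarnings(predict_spike_sequence(p0))
  expect_equal(pred0$T1, pi / sqrt(0.5), tolerance = 1e-6)
  expect_equal(pred0$isis, rep(isi_intrinsic(p0), length(pred0$isis)),
               tolerance = 1e-9)
  # modulated oscillator: predicted times track simulated times to within
  # half the mean simulated interval; the final spike of the cycle is
  # excluded (the phase-frozen interval formula accumulates drift error
  # over the cycle, largest at the trough-side boundary)
  p <- fig_osc_strong
  pred <- suppressWarnings(predict_spike_sequence(p))
  sim <- tg_simulate(p, t_end = theta_period(p))
  n <- min(length(pred$times), nrow(sim$spikes)) - 1
  half_isi <- mean(diff(sim$spikes$time)) / 2
  expect_true(all(abs(pred$times[1:n] - sim$spikes$time[1:n]) < half_isi))
  # predicted and simulated counts agree to within one spike
  pw <- fig_osc_weakdrive
  predw <- suppressWarnings(predict_spike_sequence(pw))
  simw <- tg_simulate(pw, t_end = theta_period(pw))
  expect_lte(abs(length(predw$times) - nrow(simw$spikes)), 1)
  # excitable burst stays inside the supra-threshold phase window
  pe <- fig_exc_shallow
  prede <- suppressWarnings(predict_spike_sequence(pe))
  Th0 <- snic_phase(pe)
  expect_true(all(prede$phases > Th0 & prede$phases < -Th0))
  expect_true(all(diff(prede$times) > 0))
  # burst approximately symmetric about the theta peak
  expect_lt(abs(mean(range(prede$phases))), 0.35)
})

test_that("simulated intervals lie between the predicted extrema", {
  p <- fig_osc_strong
  sim <- tg_simulate(p, t_end = theta_period(p))
  ex <- isi_extrema(p)
  isis <- diff(sim$spikes$time)
  expect_true(all(isis > 0.9 * ex$isi_min))
  expect_true(all(isis < 1.1 * ex$isi_max))
})
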