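Package: thetagamma
Title: Spike-Time Prediction for Theta-Modulated Gamma Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a minimal theta-modulated gamma spiking
    circuit: a theta (type I, quadratic integrate-and-fire) neuron driven
    by a slow sinusoidal theta oscillator with delayed self-inhibition
    standing in for a PING loop. Provides a ground-truth numerical
    simulator with exact spike-event detection, semi-analytic predictions
    of the time to first spike (Mathieu-equation zero finding in the
    oscillatory regime; saddle-node-on-invariant-circle slow-passage
    asymptotics with the Airy/Bessel constant in the excitable regime),
    recursive interspike-interval formulas, per-theta-cycle spike-count
    estimators, and reproducible sweep drivers comparing the analytic
    predictions against simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
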