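Package: speLearn
Title: Uncertainty-Guided Reward Learning with Scaled Prediction Errors
Version: 0.1.0
Authors@R:
    person("speLearn", "Developers", email = "spelearn@example.org",
           role = c("aut", "cre"))
Description: Trial-level reward-learning rules that track both the mean and
    the standard deviation of a reward signal and use prediction errors
    scaled by the estimated spread as the teaching signal, together with
    Rescorla-Wagner and Kalman-filter baselines (exact, steady-state and
    high-noise approximations). Includes the equivalent direct/indirect
    basal-ganglia pathway-weight formulation of the learning rules, a
    continuous-time leaky-integrator model of the dopamine-thalamus
    feedback loop that computes scaled prediction errors, synthetic reward
    generators (drifting-mean Gaussian processes, balanced Pavlovian
    schedules, discrete reward distributions), and drivers that reproduce
    the associated tracking benchmarks and dopamine-response simulations
    from the command line.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
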