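---
title: "Scaled prediction errors: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaled prediction errors: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speLearn)
```

## The model and its assumptions

The scaled-prediction-error (SPE) learner maintains two scalars: `m`, an
estimate of the mean reward, and `s`, an estimate of the reward standard
deviation. Each observed reward `r` produces a scaled error
$\delta = (r - m)/s$, after which both estimates are updated from that same
pre-update error:

$$m' = m + \alpha_m\,\delta, \qquad s' = s + \alpha_s(\delta^2 - 1).$$

The update order matters and is fixed throughout the package: $\delta$ is
computed from the state *before* the update, then `m` and `s` move
simultaneously. If rewards are i.i.d. with mean $\mu$ and sd $\sigma$ (any
distribution with finite second moment, not only Gaussian), then
$(m, s) = (\mu, \sigma)$ is a stochastic fixed point: the expected
increments of both estimates vanish there. The suite verifies this by
direct Monte Carlo at $10^6$ draws, for Gaussian and uniform rewards.

The learner is derived for stationary rewards but is applied to
drifting-mean signals ($\mu_{t+1} \sim N(\mu_t, \nu)$,
$r_t \sim N(\mu_t, \sigma)$). In that setting its effective learning rate,
$\alpha_m / s$, self-tunes towards $\nu/\sigma$, which is the high-noise
limit of the steady-state Kalman gain

$$k_\infty = \frac{\sqrt{4\sigma^2/\nu^2+1}+1}
                  {\sqrt{4\sigma^2/\nu^2+1}+1+2\sigma^2/\nu^2}.$$

So with $\alpha_m$ playing the role of $\nu$, the SPE learner behaves like
an adaptive steady-state Kalman filter wherever $\sigma \gtrsim \nu$; the
approximation error $|k_\infty - \nu/\sigma|/k_\infty$ is about 28% at
$\sigma/\nu = 2$ and shrinks monotonically as $\sigma/\nu$ grows. Below
$\sigma/\nu \approx 1$ the approximation (and the learner's advantage)
breaks down — the optimal gain saturates at 1 while $\nu/\sigma$ keeps
growing.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `alpha_m` | unitless, (0, 1] | — (1 in the tracking benchmark) | encodes the assumed volatility; `alpha_m = 1` makes the effective rate $1/s \to \nu/\sigma$ when $\nu = 1$ |
| `alpha_s` | unitless, ≥ 0 | — (0.1 benchmark, 0.0067 Pavlovian) | speed of spread tracking; 0 recovers Rescorla–Wagner exactly |
| `m0`, `s0` | reward units | 0, 1 | neutral start: zero mean, unit spread (so the first error is unscaled) |
| `s_floor` | reward units | 1e-3 | the raw spread update can cross zero for large `alpha_s`; the floor keeps $\delta$ defined (see below) |
| `nu`, `sigma` | reward units | — | generating process; the Kalman baseline receives the true values |
| `w0` | reward units² | 1 | Kalman initial posterior variance |
| `lam` ($\lambda$) | unitless, > 0 | 1 | accuracy/cost trade-off of encoding the spread in the weight sum; larger $\lambda$ widens the range of representable spreads at the price of larger weights |
| `tau_delta`, `tau_T` | ms | 300, 10 | dopamine-transient decay time and thalamic membrane time constant |

Two published parameterisations of the benchmark SPE learner circulate
(`alpha_s` 0.01 vs 0.1); the package defaults to 0.1 and exposes the value
in `benchmark_config()`, so either can be reproduced.

## What the synthetic generators emulate — and what they do not

`generate_drifting_rewards()` produces exactly the process the learners
are scored on: a Gaussian random walk observed through Gaussian noise,
with the latent mean returned alongside the rewards because the benchmark
metric compares estimates to $\mu_t$, never to $r_t$.
`generate_pavlovian_schedule()` emulates partial reinforcement with the
balanced pseudorandom constraint — every *aligned* block of four trials
holds exactly two rewarded trials (whether the original constraint was
aligned or sliding is unstated; aligned blocks are the minimal
construction and are what the generator enforces). The discrete reward
distributions used for the unequal-spread comparison are *synthetic
stand-ins*: the original probabilities were published only graphically, so
`rothenhoefer_distributions()` ships a uniform (1/3, 1/3, 1/3) and a
peaked (0.1, 0.8, 0.1) distribution on the support {0.1, 0.3, 0.5} ml with
equal mean and range but different sd — the only features the qualitative
comparison uses. None of the generators model cue compounds, continuous
time between trials, satiety, or any behavioural policy; a green test
therefore establishes properties of the learning rules under their stated
reward processes, not agreement with any particular recorded neuron.

## Numerical choices

* **Spread positivity.** The $s$ update is clipped from below at
  `s_floor` (default 1e-3 reward units). The trial-wise equations are
  silent on what happens when $s$ would cross zero, but $\delta$ divides
  by $s$, so some floor is mandatory; 1e-3 is far below any spread
  arising in the shipped experiments, so the clip is inert except in
  deliberately abusive configurations.
* **Benchmark scoring.** "Prediction" is read as the post-update estimate
  $m_t$ compared against $\mu_t$. The pre-update convention merely adds
  one step of process noise to every learner's error and changes no
  ordering; the package uses the post-update reading consistently.
  Reported logarithms are base 10 (display only).
* **RW learning-rate grid.** Ten values linearly spaced over
  [0.007, 0.993]; the spacing between the two published endpoints is not
  stated, and linear is the simpler choice. Each (learner, σ) cell draws
  its own trajectory from a sub-seed derived deterministically from the
  base seed, so tables are exactly reproducible.
* **Pavlovian normalisation.** The six condition-by-outcome mean errors
  per model are divided by their *population* (divide-by-n) standard
  deviation. Which n-convention was used originally is unstated; with six
  values the choice rescales both models identically and affects no
  comparison.
* **ODE integration.** The two-unit feedback loop is integrated with a
  package-local adaptive Dormand–Prince RK45 (rtol 1e-8, atol 1e-10),
  since no stiff solver is a hard dependency: with $\tau_T/\tau_\delta =
  1/30$ the system is only mildly stiff and the step controller handles
  it directly. Integration is split exactly at the input onset
  (right-continuous steps), so the discontinuity never falls inside a
  step, and output is sampled on a fixed 1-ms grid regardless of internal
  steps. Tests pin the terminal dopamine level to the closed-form
  equilibrium within 1e-4 relative.
* **Oscillation claim.** The linearised circuit actually has weakly
  complex eigenvalues, so a minute overshoot (~0.5% of equilibrium with
  default parameters) is genuine dynamics, not solver error. "Settles
  without oscillation" is therefore formalised as: monotone approach up
  to the first equilibrium crossing, overshoot below 5% of the
  equilibrium value, and permanent entry into the 5% band well before the
  end of the window (`settling_time()` reports 42 ms at defaults).
* **Degenerate limits.** `steady_state_gain(0, sigma)` and
  `steady_state_posterior_var(0, sigma)` return the documented limits 0
  rather than raising on the indeterminate closed forms; with perfect
  observations (`sigma = 0`) the gain is 1. Both noise levels zero is an
  error everywhere.

## Open design points and how they were resolved

* **Weight clipping.** Indirect-pathway weights cannot be negative in the
  constrained (biological) mode; the clip at zero is applied *after* the
  full additive update, the simplest projection consistent with the
  trial-wise rules. Unconstrained mode exists because the algebraic
  equivalence with the (m, s) learner is exact only without clipping —
  the suite checks that equivalence to 1e-12 over 1000 trials. With
  clipping active, spread tracking is accurate only when
  $\sigma \ge |\mu|/\lambda + 1$; below that bound the decoded spread is
  biased upward, which the tests demonstrate rather than hide.
* **A worked-example discrepancy.** The step-input weights G = 10, N = 6
  with $\lambda = 1$ decode to $s = 1 + (G+N)/2\lambda = 9$, while the
  accompanying prose gives 8. The weights are treated as primary
  (`decode_stats()` returns 9); the decoded mean m = 2 is unaffected.
* **Dopamine below baseline.** $\delta(t)$ is allowed to go negative in
  the circuit; no rectification is applied, as none is present in the
  equations.

## Known limitations

* Single action channel, scalar rewards: no action selection, no
  cue-compound generalisation, no vector-valued (Kalman-TD-style)
  extensions.
* The volatility parameter ($\nu$, alias `alpha_m`) is supplied, not
  tracked; tracking it is explicitly out of scope.
* The full-scale tracking benchmark (100 noise levels × 12 learners ×
  $10^5$ trials) runs in minutes from the CLI, but the test suite and the
  acceptance checks use the documented scaled-down sizes (one noise
  level, $2\times10^4$ trials) and assert orderings only — stochastic
  curve shapes, not exact values.
* Experimental dopamine recordings are not shipped or fitted; the
  per-reward "responses" are asymptotic model quantities
  ($r-\mu$ and $(r-\mu)/\sigma$), suitable for qualitative comparison
  only.
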