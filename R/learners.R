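# Trial-level learning rules: scaled-prediction-error (SPE) learner,
# Rescorla-Wagner delta rule, and the exact / steady-state Kalman filter.

#' Parameters for the scaled-prediction-error learner
#'
#' The SPE learner maintains running estimates `m` (mean reward) and `s`
#' (reward standard deviation) and updates them from the scaled prediction
#' error \eqn{\delta = (r - m)/s}:
#' \deqn{m' = m + \alpha_m \delta, \qquad s' = s + \alpha_s (\delta^2 - 1).}
#' With `alpha_s = 0` and `s0 = 1` the learner reduces exactly to the
#' Rescorla-Wagner rule with learning rate `alpha_m`.
#'
#' @param alpha_m Learning rate for the mean, in (0, 1]. In the high
#'   observation-noise regime `alpha_m` plays the role of the process-noise
#'   level \eqn{\nu} of a steady-state Kalman filter.
#' @param alpha_s Learning rate for the standard deviation, >= 0.
#' @param m0,s0 Initial estimates of mean and spread. Defaults 0 and 1.
#' @param s_floor Smallest admissible spread (> 0). The raw `s` update can
#'   cross zero for large `alpha_s`; the estimate is clipped at this floor so
#'   the scaled error stays defined.
#' @return An object of class `spe_params`.
#' @seealso [spe_update()], [run_spe()]
#' @export
spe_params <- function(alpha_m, alpha_s, m0 = 0, s0 = 1, s_floor = 1e-3) {
  stopifnot(is.numeric(alpha_m), length(alpha_m) == 1L, alpha_m > 0, alpha_m <= 1,
            is.numeric(alpha_s), length(alpha_s) == 1L, alpha_s >= 0,
            is.numeric(s_floor), s_floor > 0, is.finite(m0), s0 > 0)
  structure(list(alpha_m = alpha_m, alpha_s = alpha_s,
                 m0 = m0, s0 = s0, s_floor = s_floor),
            class = "spe_params")
}

#' Current state of an SPE learner
#'
#' @param m Estimated mean reward.
#' @param s Estimated reward standard deviation (> 0).
#' @param delta Last scaled prediction error used, or `NA` before the first
#'   update. Carried on the state so experiment drivers can log
#'   dopamine-response analogues without recomputation.
#' @return An object of class `spe_state`.
#' @export
spe_state <- function(m, s, delta = NA_real_) {
  stopifnot(is.finite(m), is.finite(s), s > 0)
  structure(list(m = m, s = s, delta = delta), class = "spe_state")
}

#' Scaled prediction error for an observed reward
#'
#' Computes \eqn{\delta = (r - m)/s} from the current state, without
#' mutating it.
#'
#' @param state An [spe_state()].
#' @param r Observed reward (finite scalar).
#' @return The scaled prediction error (unitless).
#' @export
spe_delta <- function(state, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("reward 'r' must be a finite numeric scalar")
  (r - state$m) / state$s
}

#' One SPE update step
#'
#' The scaled error is computed from the pre-update state; `m` and `s` are
#' then both updated from that same error. The spread update is clipped at
#' `params$s_floor` from below.
#'
#' @param state An [spe_state()].
#' @param params An [spe_params()].
#' @param r Observed reward.
#' @return The new [spe_state()]; its `delta` field holds the error used.
#' @export
spe_update <- function(state, params, r) {
  d <- spe_delta(state, r)
  m_new <- state$m + params$alpha_m * d
  s_new <- max(params$s_floor, state$s + params$alpha_s * (d^2 - 1))
  spe_state(m_new, s_new, delta = d)
}

#' Rescorla-Wagner parameters and state
#'
#' The classic constant-learning-rate delta rule:
#' \eqn{\delta = r - m}, \eqn{m' = m + \alpha\delta}.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param m0 Initial mean estimate.
#' @return An object of class `rw_params`.
#' @export
rw_params <- function(alpha, m0 = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.finite(m0))
  structure(list(alpha = alpha, m0 = m0), class = "rw_params")
}

#' @param m Current mean estimate.
#' @param delta Last (unscaled) prediction error.
#' @rdname rw_params
#' @export
rw_state <- function(m, delta = NA_real_) {
  stopifnot(is.finite(m))
  structure(list(m = m, delta = delta), class = "rw_state")
}

#' One Rescorla-Wagner update step
#'
#' @param state An [rw_state()].
#' @param params An [rw_params()].
#' @param r Observed reward.
#' @return The new [rw_state()], carrying the `delta` used.
#' @export
rw_update <- function(state, params, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("reward 'r' must be a finite numeric scalar")
  d <- r - state$m
  rw_state(state$m + params$alpha * d, delta = d)
}

#' Kalman filter parameters and state
#'
#' One-dimensional Kalman filter tracking a latent mean that drifts with
#' process noise sd `nu` and is observed with noise sd `sigma`:
#' \deqn{k_t = (w + \nu^2) / (w + \nu^2 + \sigma^2)}
#' \deqn{m' = m + k_t (r - m), \qquad w' = (1 - k_t)(w + \nu^2).}
#'
#' @param nu Process-noise standard deviation, >= 0.
#' @param sigma Observation-noise standard deviation, >= 0. `nu` and `sigma`
#'   must not both be zero.
#' @param w0 Initial posterior variance (default 1).
#' @return An object of class `kalman_params`.
#' @export
kalman_params <- function(nu, sigma, w0 = 1) {
  stopifnot(is.numeric(nu), nu >= 0, is.numeric(sigma), sigma >= 0, w0 >= 0)
  if (nu == 0 && sigma == 0)
    stop("'nu' and 'sigma' must not both be zero")
  structure(list(nu = nu, sigma = sigma, w0 = w0), class = "kalman_params")
}

#' @param m Posterior mean.
#' @param w Posterior variance (>= 0).
#' @param k Last Kalman gain, in \[0, 1\] (or `NA` before the first update).
#' @param delta Last innovation `r - m` (pre-update).
#' @rdname kalman_params
#' @export
kalman_state <- function(m, w, k = NA_real_, delta = NA_real_) {
  stopifnot(is.finite(m), is.finite(w), w >= 0)
  structure(list(m = m, w = w, k = k, delta = delta), class = "kalman_state")
}

#' One Kalman filter update step
#'
#' The gain is computed from the pre-update posterior variance, then the mean
#' and variance are updated.
#'
#' @param state A [kalman_state()].
#' @param params A [kalman_params()].
#' @param r Observed reward.
#' @return The new [kalman_state()] with fields `m`, `w`, `k`, `delta`.
#' @export
kalman_update <- function(state, params, r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("reward 'r' must be a finite numeric scalar")
  prior_var <- state$w + params$nu^2
  denom <- prior_var + params$sigma^2
  if (denom == 0)
    stop("degenerate Kalman gain: w, nu and sigma are all zero")
  k <- prior_var / denom
  d <- r - state$m
  kalman_state(state$m + k * d, (1 - k) * prior_var, k = k, delta = d)
}

#' Steady-state Kalman gain
#'
#' Closed-form limit of the Kalman gain for the drifting-mean tracking
#' problem:
#' \deqn{k_\infty = \frac{\sqrt{4\sigma^2/\nu^2 + 1} + 1}
#'                       {\sqrt{4\sigma^2/\nu^2 + 1} + 1 + 2\sigma^2/\nu^2}.}
#' `nu = 0` is exposed as the documented limit `k = 0` (with `sigma > 0`);
#' `sigma = 0` gives `k = 1`.
#'
#' @param nu Process-noise sd.
#' @param sigma Observation-noise sd. Not both zero.
#' @return The steady-state gain, in (0, 1\] (0 in the `nu = 0` limit).
#' @export
steady_state_gain <- function(nu, sigma) {
  stopifnot(nu >= 0, sigma >= 0)
  if (nu == 0 && sigma == 0)
    stop("'nu' and 'sigma' must not both be zero")
  if (nu == 0) return(0)
  if (sigma == 0) return(1)
  q <- sigma^2 / nu^2
  root <- sqrt(4 * q + 1)
  (root + 1) / (root + 1 + 2 * q)
}

#' Steady-state posterior variance of the Kalman filter
#'
#' Closed form \eqn{w_\infty = (\nu^2/2)(\sqrt{4\sigma^2/\nu^2 + 1} - 1)}.
#' For large \eqn{\sigma/\nu} this tends to \eqn{\nu\sigma}; at `nu = 0` the
#' posterior variance vanishes.
#'
#' @inheritParams steady_state_gain
#' @return The steady-state posterior variance (reward units squared).
#' @export
steady_state_posterior_var <- function(nu, sigma) {
  stopifnot(nu >= 0, sigma >= 0)
  if (nu == 0 && sigma == 0)
    stop("'nu' and 'sigma' must not both be zero")
  if (nu == 0) return(0)
  (nu^2 / 2) * (sqrt(4 * sigma^2 / nu^2 + 1) - 1)
}

#' High-noise approximation to the steady-state Kalman gain
#'
#' Returns \eqn{\nu/\sigma}, the limit of [steady_state_gain()] for
#' \eqn{\sigma/\nu \to \infty}. This is the effective learning rate of an SPE
#' learner with `alpha_m = nu` once its spread estimate has converged to
#' `sigma`.
#'
#' @inheritParams steady_state_gain
#' @return The approximate gain \eqn{\nu/\sigma}.
#' @export
high_noise_gain <- function(nu, sigma) {
  stopifnot(nu >= 0)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("'sigma' must be positive for the high-noise approximation")
  nu / sigma
}

# ---- sequence drivers ------------------------------------------------------

#' Run a learner over a reward sequence
#'
#' Apply a learning rule trial by trial to a numeric reward vector, recording
#' the full trajectory. `m` (and `s`, `w`, `k` where applicable) are the
#' post-update estimates at each trial; `delta` is the prediction error
#' computed from the pre-update state.
#'
#' @param rewards Numeric vector of observed rewards.
#' @param params A `spe_params`, `rw_params` or `kalman_params` object.
#' @return A data frame with one row per trial: `trial`, `r`, `delta`, `m`,
#'   plus `s` (SPE) or `w`, `k` (Kalman).
#' @examples
#' r <- rnorm(100, mean = 2, sd = 5)
#' head(run_spe(r, spe_params(alpha_m = 1, alpha_s = 0.1)))
#' @export
run_spe <- function(rewards, params) {
  stopifnot(inherits(params, "spe_params"), is.numeric(rewards),
            all(is.finite(rewards)))
  n <- length(rewards)
  m <- numeric(n); s <- numeric(n); d <- numeric(n)
  m_cur <- params$m0; s_cur <- params$s0
  am <- params$alpha_m; as_ <- params$alpha_s; fl <- params$s_floor
  for (t in seq_len(n)) {
    d[t] <- (rewards[t] - m_cur) / s_cur
    m_cur <- m_cur + am * d[t]
    s_cur <- max(fl, s_cur + as_ * (d[t]^2 - 1))
    m[t] <- m_cur; s[t] <- s_cur
  }
  data.frame(trial = seq_len(n), r = rewards, delta = d, m = m, s = s)
}

#' @rdname run_spe
#' @export
run_rw <- function(rewards, params) {
  stopifnot(inherits(params, "rw_params"), is.numeric(rewards),
            all(is.finite(rewards)))
  n <- length(rewards)
  m <- numeric(n); d <- numeric(n)
  m_cur <- params$m0; a <- params$alpha
  for (t in seq_len(n)) {
    d[t] <- rewards[t] - m_cur
    m_cur <- m_cur + a * d[t]
    m[t] <- m_cur
  }
  data.frame(trial = seq_len(n), r = rewards, delta = d, m = m)
}

#' @rdname run_spe
#' @param m0 Initial mean estimate for the Kalman run (default 0).
#' @export
run_kalman <- function(rewards, params, m0 = 0) {
  stopifnot(inherits(params, "kalman_params"), is.numeric(rewards),
            all(is.finite(rewards)))
  n <- length(rewards)
  m <- numeric(n); w <- numeric(n); k <- numeric(n); d <- numeric(n)
  m_cur <- m0; w_cur <- params$w0
  nu2 <- params$nu^2; s2 <- params$sigma^2
  for (t in seq_len(n)) {
    prior <- w_cur + nu2
    k[t] <- prior / (prior + s2)
    d[t] <- rewards[t] - m_cur
    m_cur <- m_cur + k[t] * d[t]
    w_cur <- (1 - k[t]) * prior
    m[t] <- m_cur; w[t] <- w_cur
  }
  data.frame(trial = seq_len(n), r = rewards, delta = d, m = m, w = w, k = k)
}
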