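# Simulation studies: the value-tracking benchmark, the Pavlovian
# magnitude-invariance simulation, discrete-distribution dopamine responses,
# the log-scale (reward-taxis) comparison, and Kalman-approximation curves.

#' Configuration for the value-tracking benchmark
#'
#' Rescorla-Wagner learners over a grid of learning rates, one SPE learner,
#' and a Kalman filter given the true generating parameters, all scored by
#' the mean squared difference between their estimate of the latent mean and
#' the true latent mean of a drifting-mean Gaussian reward process.
#'
#' @param rw_alphas RW learning-rate grid; default 10 values linearly spaced
#'   from 0.007 to 0.993.
#' @param sigma_grid Observation-noise grid; default 100 values log-spaced
#'   from 0.1353 to 1096.6.
#' @param nu Process-noise sd (default 1).
#' @param n_trials Trials per cell (default 1e5).
#' @param spe_alpha_m,spe_alpha_s SPE learning rates (defaults 1 and 0.1).
#' @param kalman_w0 Kalman initial posterior variance (default 1).
#' @param seed Base RNG seed; each (learner, sigma) cell derives its own
#'   sub-seed deterministically from it.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(rw_alphas = seq(0.007, 0.993, length.out = 10),
                             sigma_grid = exp(seq(log(0.1353), log(1096.6),
                                                  length.out = 100)),
                             nu = 1, n_trials = 1e5,
                             spe_alpha_m = 1, spe_alpha_s = 0.1,
                             kalman_w0 = 1, seed = 1L) {
  stopifnot(length(rw_alphas) >= 1, all(rw_alphas >= 0 & rw_alphas <= 1),
            length(sigma_grid) >= 1, all(sigma_grid >= 0), nu >= 0,
            n_trials >= 1)
  structure(list(rw_alphas = rw_alphas, sigma_grid = sigma_grid, nu = nu,
                 n_trials = as.integer(n_trials), spe_alpha_m = spe_alpha_m,
                 spe_alpha_s = spe_alpha_s, kalman_w0 = kalman_w0,
                 seed = as.integer(seed)), class = "benchmark_config")
}

# deterministic per-cell sub-seed, kept within 32-bit integer range
cell_seed <- function(seed, i, j) {
  as.integer((as.numeric(seed) + 104729 * i + 7919 * j) %% 2147483647)
}

#' Run the value-tracking benchmark
#'
#' For every (learner, sigma) cell an independent drifting-mean reward
#' trajectory is simulated, the learner is run over it, and the mean over
#' trials of `(m_t - mu_t)^2` is recorded together with its base-10
#' logarithm. The Kalman filter is parameterised with the true `(nu, sigma)`
#' of each cell, providing the normative performance bound.
#'
#' @param config A [benchmark_config()].
#' @return A tidy data frame (one row per learner x sigma) with columns
#'   `experiment`, `learner`, `alpha`, `sigma`, `nu`, `n_trials`, `seed`,
#'   `mse`, `log10_mse`.
#' @export
run_tracking_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  learners <- c(paste0("rw_", seq_along(config$rw_alphas)), "spe", "kalman")
  rows <- vector("list", length(config$sigma_grid) * length(learners))
  idx <- 1L
  for (i in seq_along(config$sigma_grid)) {
    sigma <- config$sigma_grid[i]
    for (j in seq_along(learners)) {
      sd_ij <- cell_seed(config$seed, i, j)
      traj <- generate_drifting_rewards(config$n_trials, nu = config$nu,
                                        sigma = sigma, seed = sd_ij)
      lrn <- learners[j]
      if (startsWith(lrn, "rw_")) {
        alpha <- config$rw_alphas[j]
        fit <- run_rw(traj$r, rw_params(alpha))
        name <- "rw"
      } else if (lrn == "spe") {
        alpha <- config$spe_alpha_m
        fit <- run_spe(traj$r, spe_params(config$spe_alpha_m,
                                          config$spe_alpha_s))
        name <- "spe"
      } else {
        alpha <- NA_real_
        fit <- run_kalman(traj$r, kalman_params(config$nu, sigma,
                                                w0 = config$kalman_w0))
        name <- "kalman"
      }
      mse <- mean((fit$m - traj$mu)^2)
      rows[[idx]] <- data.frame(experiment = "tracking_benchmark",
                                learner = name, alpha = alpha, sigma = sigma,
                                nu = config$nu, n_trials = config$n_trials,
                                seed = sd_ij, mse = mse,
                                log10_mse = log10(mse))
      idx <- idx + 1L
    }
  }
  do.call(rbind, rows)
}

#' Pavlovian magnitude-invariance simulation
#'
#' For each reward magnitude, a balanced 50%-reward schedule is simulated
#' and a learner is run over it with small learning rates; prediction errors
#' from the post-burn-in trials are averaged separately for rewarded and
#' unrewarded outcomes. The six condition-by-outcome means per model are
#' then divided by their (population) standard deviation, so that models
#' with differently scaled error signals can be compared on one axis. Under
#' the plain delta rule the rewarded-trial response grows in proportion to
#' magnitude; under spread-scaled errors it is approximately
#' magnitude-invariant.
#'
#' @param magnitudes Reward magnitudes (default `c(0.05, 0.15, 0.5)`).
#' @param models Subset of `c("rw", "spe")`.
#' @param alpha Learning rate(s): used for the RW rate and for both SPE
#'   rates (default 0.0067).
#' @param n_trials Trials per magnitude (default 2000).
#' @param n_discard Burn-in trials excluded from the averages (default 500),
#'   standing in for pretraining.
#' @param seed Base RNG seed.
#' @return A tidy data frame with columns `model`, `magnitude`, `outcome`,
#'   `mean_delta`, `normalized`, plus provenance columns.
#' @export
run_tobler_experiment <- function(magnitudes = c(0.05, 0.15, 0.5),
                                  models = c("rw", "spe"),
                                  alpha = 0.0067, n_trials = 2000,
                                  n_discard = 500, seed = 1L) {
  stopifnot(all(magnitudes > 0), all(models %in% c("rw", "spe")),
            n_discard < n_trials)
  rows <- list()
  for (mdl in models) {
    for (i in seq_along(magnitudes)) {
      mag <- magnitudes[i]
      sched <- generate_pavlovian_schedule(n_trials, magnitude = mag,
                                           seed = cell_seed(seed, i,
                                                            match(mdl, models)))
      fit <- if (mdl == "rw") run_rw(sched$reward, rw_params(alpha, m0 = 0))
             else run_spe(sched$reward, spe_params(alpha, alpha, m0 = 0, s0 = 1))
      keep <- fit$trial > n_discard
      rewarded <- sched$reward > 0
      for (oc in c("rewarded", "unrewarded")) {
        sel <- keep & (rewarded == (oc == "rewarded"))
        rows[[length(rows) + 1L]] <-
          data.frame(model = mdl, magnitude = mag, outcome = oc,
                     mean_delta = mean(fit$delta[sel]),
                     alpha = alpha, n_trials = n_trials,
                     n_discard = n_discard, seed = seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  # normalize the six means by their population sd, per model
  out$normalized <- NA_real_
  for (mdl in unique(out$model)) {
    sel <- out$model == mdl
    v <- out$mean_delta[sel]
    sd_pop <- sqrt(mean((v - mean(v))^2))
    out$normalized[sel] <- v / sd_pop
  }
  out
}

#' Analytic dopamine responses to a discrete reward distribution
#'
#' After exhaustive training on a distribution with mean `mu` and sd
#' `sigma`, the asymptotic per-reward response is `r - mu` for the plain
#' delta rule and `(r - mu)/sigma` for the spread-scaled rule. Distributions
#' with equal mean and range but smaller sd therefore yield larger scaled
#' responses at the extreme rewards.
#'
#' @param dist A [discrete_reward_dist()].
#' @param model One of `"rw"` or `"spe"`.
#' @return A data frame with columns `r`, `prob`, `response`, `model`.
#' @export
rothenhoefer_responses <- function(dist, model = c("spe", "rw")) {
  model <- match.arg(model)
  mom <- distribution_moments(dist, require_spread = (model == "spe"))
  resp <- if (model == "rw") dist$support - mom$mean
          else (dist$support - mom$mean) / mom$sd
  data.frame(r = dist$support, prob = dist$probs, response = resp,
             model = model)
}

#' Log-scale (reward-taxis) prediction error
#'
#' If rewards and expectations are both log-transformed, the prediction
#' error to a surprising reward `r` delivered with probability `p_reward` is
#' `log(r) - log(p_reward * r) = -log(p_reward)`, independent of reward
#' size; at 50% reinforcement it equals `log 2` for every magnitude.
#'
#' @param r Reward magnitude(s), > 0.
#' @param p_reward Reward probability, in (0, 1\].
#' @return The log-scale prediction error, recycled to `length(r)`.
#' @export
reward_taxis_response <- function(r, p_reward) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be positive")
  if (!is.numeric(p_reward) || p_reward <= 0 || p_reward > 1)
    stop("'p_reward' must be in (0, 1]")
  log(r) - log(p_reward * r)
}

#' Posterior-variance and gain curves of the Kalman filter
#'
#' Tabulates (a) the transient posterior variance `w_t` over the first
#' `n_steps` observations for each process-noise level in `nu_list`
#' (at observation noise `sigma_transient`), alongside its steady-state
#' limit, and (b) the steady-state gain and its high-noise approximation
#' `nu/sigma` across `sigma_grid` at `nu = nu_gain`.
#'
#' @param sigma_grid Observation-noise grid for the gain curves.
#' @param nu_list Process-noise levels for the transient curves
#'   (default `c(0, 0.5, 1)`).
#' @param n_steps Number of observations for the transients (default 30).
#' @param sigma_transient Observation noise for the transients (default 1).
#' @param nu_gain Process noise for the gain curves (default 1).
#' @param w0 Initial posterior variance (default 1).
#' @return A list of two data frames: `posterior_var` (columns `nu`, `step`,
#'   `w`, `w_inf`) and `gains` (columns `sigma`, `k_inf`, `approx`,
#'   `rel_diff`).
#' @export
kalman_curves <- function(sigma_grid = exp(seq(log(0.1353), log(1096.6),
                                               length.out = 100)),
                          nu_list = c(0, 0.5, 1), n_steps = 30,
                          sigma_transient = 1, nu_gain = 1, w0 = 1) {
  stopifnot(n_steps >= 1, all(sigma_grid > 0), nu_gain > 0)
  pv <- do.call(rbind, lapply(nu_list, function(nu) {
    w <- numeric(n_steps)
    w_cur <- w0
    for (t in seq_len(n_steps)) {
      prior <- w_cur + nu^2
      k <- prior / (prior + sigma_transient^2)
      w_cur <- (1 - k) * prior
      w[t] <- w_cur
    }
    data.frame(nu = nu, step = seq_len(n_steps), w = w,
               w_inf = steady_state_posterior_var(nu, sigma_transient))
  }))
  k_inf <- vapply(sigma_grid, function(s) steady_state_gain(nu_gain, s),
                  numeric(1))
  approx <- nu_gain / sigma_grid
  gains <- data.frame(sigma = sigma_grid, k_inf = k_inf, approx = approx,
                      rel_diff = abs(k_inf - approx) / k_inf)
  list(posterior_var = pv, gains = gains)
}
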