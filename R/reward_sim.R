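# Synthetic reward processes: drifting-mean Gaussian signals, balanced
# Pavlovian schedules, and discrete reward distributions.

#' Generate a drifting-mean Gaussian reward trajectory
#'
#' The latent mean performs a Gaussian random walk,
#' \eqn{\mu_{t+1} \sim N(\mu_t, \nu)}, and each observed reward is the
#' current mean corrupted by observation noise, \eqn{r_t \sim N(\mu_t, \sigma)}.
#' The latent means are returned alongside the rewards because tracking
#' benchmarks score predictions against \eqn{\mu_t}, not against the noisy
#' \eqn{r_t}.
#'
#' @param n_trials Number of trials (>= 1).
#' @param nu Process-noise standard deviation (>= 0): typical per-trial change
#'   of the latent mean.
#' @param sigma Observation-noise standard deviation (>= 0).
#' @param mu0 Latent mean at the first trial (default 0).
#' @param seed Optional integer seed; when given the trajectory is
#'   reproducible.
#' @return A data frame of class `reward_trajectory` with columns `trial`,
#'   `mu`, `r`; the generating parameters are attached as attribute `params`.
#' @examples
#' traj <- generate_drifting_rewards(500, nu = 1, sigma = 5, seed = 1)
#' @export
generate_drifting_rewards <- function(n_trials, nu, sigma, mu0 = 0,
                                      seed = NULL) {
  stopifnot(is.numeric(n_trials), n_trials >= 1, nu >= 0, sigma >= 0,
            is.finite(mu0))
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)
  mu <- mu0 + c(0, cumsum(stats::rnorm(n_trials - 1L, sd = nu)))
  r <- mu + stats::rnorm(n_trials, sd = sigma)
  out <- data.frame(trial = seq_len(n_trials), mu = mu, r = r)
  attr(out, "params") <- list(n_trials = n_trials, nu = nu, sigma = sigma,
                              mu0 = mu0, seed = seed)
  class(out) <- c("reward_trajectory", "data.frame")
  out
}

#' Generate a balanced Pavlovian reward schedule
#'
#' Emulates partial reinforcement at a fixed magnitude: in every aligned
#' block of `block_size` consecutive trials, exactly
#' `block_size * p_reward` trials deliver `magnitude` and the rest deliver 0,
#' with the within-block order shuffled independently per block. With the
#' defaults (blocks of 4, p = 0.5) every aligned block of four trials
#' contains exactly two rewarded trials.
#'
#' @param n_trials Total number of trials; padded internally to a whole
#'   number of blocks and truncated to `n_trials`.
#' @param magnitude Reward size on rewarded trials (> 0).
#' @param p_reward Reward probability per trial (default 0.5);
#'   `block_size * p_reward` must be a whole number.
#' @param block_size Trials per balanced block (default 4).
#' @param seed Optional integer seed.
#' @return A data frame with columns `trial`, `reward`; attribute `params`
#'   records the configuration.
#' @export
generate_pavlovian_schedule <- function(n_trials, magnitude, p_reward = 0.5,
                                        block_size = 4L, seed = NULL) {
  stopifnot(n_trials >= 1, magnitude > 0, p_reward >= 0, p_reward <= 1,
            block_size >= 1)
  n_trials <- as.integer(n_trials); block_size <- as.integer(block_size)
  n_rewarded <- block_size * p_reward
  if (abs(n_rewarded - round(n_rewarded)) > 1e-9)
    stop("block_size * p_reward must be an integer (got ", n_rewarded, ")")
  n_rewarded <- as.integer(round(n_rewarded))
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_trials / block_size)
  block <- c(rep(magnitude, n_rewarded), rep(0, block_size - n_rewarded))
  rewards <- unlist(lapply(seq_len(n_blocks), function(i) {
    if (block_size == 1L) block else sample(block)
  }), use.names = FALSE)[seq_len(n_trials)]
  out <- data.frame(trial = seq_len(n_trials), reward = rewards)
  attr(out, "params") <- list(n_trials = n_trials, magnitude = magnitude,
                              p_reward = p_reward, block_size = block_size,
                              seed = seed)
  out
}

#' Discrete reward distribution
#'
#' A finite-support reward distribution given by magnitudes and matching
#' probabilities, as used in Pavlovian designs that manipulate reward spread
#' at fixed mean and range.
#'
#' @param support Numeric vector of reward magnitudes, strictly increasing.
#' @param probs Matching probabilities; nonnegative, summing to 1 within
#'   1e-12.
#' @return An object of class `discrete_reward_dist`.
#' @seealso [distribution_moments()], [rothenhoefer_distributions()]
#' @export
discrete_reward_dist <- function(support, probs) {
  stopifnot(is.numeric(support), is.numeric(probs),
            length(support) == length(probs), length(support) >= 1,
            all(is.finite(support)), all(probs >= 0))
  if (any(diff(support) <= 0))
    stop("'support' must be strictly increasing")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("'probs' must sum to 1 (got ", sum(probs), ")")
  structure(list(support = support, probs = probs),
            class = "discrete_reward_dist")
}

#' Exact moments of a discrete reward distribution
#'
#' @param dist A [discrete_reward_dist()].
#' @param require_spread If `TRUE`, a zero-variance distribution is an error
#'   (its sd cannot be used to scale prediction errors downstream).
#' @return A list with `mean` and `sd`.
#' @export
distribution_moments <- function(dist, require_spread = FALSE) {
  stopifnot(inherits(dist, "discrete_reward_dist"))
  mu <- sum(dist$support * dist$probs)
  sigma <- sqrt(sum((dist$support - mu)^2 * dist$probs))
  if (require_spread && sigma == 0)
    stop("distribution has zero variance; spread-scaled responses undefined")
  list(mean = mu, sd = sigma)
}

#' Default reward distributions for the equal-range, unequal-spread design
#'
#' Two synthetic stand-in distributions on the juice-magnitude support
#' \{0.1, 0.3, 0.5\} ml: a "uniform" one (probabilities 1/3 each) and a
#' "normal" (peaked) one (0.1, 0.8, 0.1). They share mean (0.3) and range
#' but differ in standard deviation, which is the feature the
#' dopamine-response comparison needs; the exact probabilities of the
#' original experiment are not published as numbers, so these defaults are
#' synthetic and fully user-overridable.
#'
#' @return A named list with elements `uniform` and `normal`, each a
#'   [discrete_reward_dist()].
#' @export
rothenhoefer_distributions <- function() {
  list(uniform = discrete_reward_dist(c(0.1, 0.3, 0.5), rep(1 / 3, 3)),
       normal  = discrete_reward_dist(c(0.1, 0.3, 0.5), c(0.1, 0.8, 0.1)))
}

#' Write a reward trajectory or schedule to CSV
#'
#' @param x A data frame from [generate_drifting_rewards()] or
#'   [generate_pavlovian_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rewards_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
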