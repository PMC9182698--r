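# Pathway-weight formulation of SPE learning: the reward mean is encoded in
# the difference of direct (Go) and indirect (No-go) cortico-striatal inputs,
# the spread in their sum:
#   m = (G - N) / 2,   lambda * (s - 1) = (G + N) / 2.

#' Pathway weights
#'
#' Direct- and indirect-pathway synaptic inputs together with the encoding
#' coefficient `lam` (lambda), which sets the accuracy/metabolic-cost
#' trade-off of storing the spread in the weight sum.
#'
#' @param G Direct-pathway (Go) synaptic input.
#' @param N Indirect-pathway (No-go) synaptic input.
#' @param lam Encoding coefficient lambda (> 0), default 1.
#' @return An object of class `pathway_weights`.
#' @export
pathway_weights <- function(G, N, lam = 1) {
  stopifnot(is.finite(G), is.finite(N), is.numeric(lam), lam > 0)
  structure(list(G = G, N = N, lam = lam), class = "pathway_weights")
}

#' Encode mean and spread as pathway weights
#'
#' Inverts the encoding assumptions to `G = m + lam*(s-1)` and
#' `N = lam*(s-1) - m`. In constrained mode both weights must be
#' nonnegative, which requires `s >= |m|/lam + 1`; infeasible inputs raise an
#' error reporting that bound. Unconstrained mode places no sign restriction
#' and is the exact algebraic inverse of [decode_stats()].
#'
#' @param m Mean reward estimate.
#' @param s Reward-spread estimate.
#' @param lam Encoding coefficient lambda (> 0).
#' @param constrained Enforce `G >= 0` and `N >= 0`? Default `FALSE`.
#' @return A [pathway_weights()] object.
#' @export
encode_weights <- function(m, s, lam = 1, constrained = FALSE) {
  stopifnot(is.finite(m), is.finite(s), lam > 0)
  G <- m + lam * (s - 1)
  N <- lam * (s - 1) - m
  if (constrained && (G < 0 || N < 0))
    stop("cannot encode (m = ", m, ", s = ", s, ") in nonnegative weights; ",
         "requires s >= |m|/lam + 1 = ", abs(m) / lam + 1)
  pathway_weights(G, N, lam)
}

#' Decode mean and spread from pathway weights
#'
#' @param weights A [pathway_weights()] object.
#' @return A list with `m = (G - N)/2` and `s = 1 + (G + N)/(2*lam)`.
#' @export
decode_stats <- function(weights) {
  stopifnot(inherits(weights, "pathway_weights"))
  list(m = (weights$G - weights$N) / 2,
       s = 1 + (weights$G + weights$N) / (2 * weights$lam))
}

#' Plasticity parameters for the pathway-weight learner
#'
#' @param alpha_m,alpha_s Learning rates for mean and spread; `alpha_m` must
#'   be positive (the plasticity nonlinearity divides by it).
#' @param lam Encoding coefficient lambda (> 0).
#' @param constrained If `TRUE`, weights are clipped at 0 after each update
#'   (synaptic weights cannot be negative); if `FALSE` the updates follow the
#'   unconstrained algebra and reproduce the (m, s) learner exactly.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(alpha_m, alpha_s, lam = 1, constrained = FALSE) {
  stopifnot(alpha_m > 0, alpha_s >= 0, lam > 0, is.logical(constrained))
  structure(list(alpha_m = alpha_m, alpha_s = alpha_s, lam = lam,
                 constrained = constrained), class = "plasticity_params")
}

#' Plasticity nonlinearity
#'
#' The transformation of the dopaminergic error applied at direct-pathway
#' synapses, \eqn{f(\delta) = \delta + (\lambda\alpha_s/\alpha_m)\delta^2};
#' indirect-pathway synapses see `f(-delta)`. The quadratic term makes the
#' slope steeper for positive than for negative errors, and satisfies
#' `f(delta) - f(-delta) = 2*delta` so the weight difference still performs
#' the plain mean update.
#'
#' @param delta Scaled prediction error (may be a vector).
#' @param params A [plasticity_params()].
#' @return The transformed error.
#' @export
nonlinearity_f <- function(delta, params) {
  stopifnot(inherits(params, "plasticity_params"))
  delta + (params$lam * params$alpha_s / params$alpha_m) * delta^2
}

#' One pathway-weight plasticity step
#'
#' Applies `dG = alpha_m * f(delta) - lam * alpha_s` and
#' `dN = alpha_m * f(-delta) - lam * alpha_s`. The `-lam*alpha_s` terms are
#' activity-dependent decay: both weight sets shrink slightly whenever the
#' synapses are active with no prediction error. In constrained mode the
#' updated weights are clipped at 0 after the full update.
#'
#' @param weights A [pathway_weights()].
#' @param delta The scaled prediction error driving plasticity.
#' @param params A [plasticity_params()].
#' @return The updated [pathway_weights()].
#' @export
weight_update <- function(weights, delta, params) {
  stopifnot(inherits(weights, "pathway_weights"),
            inherits(params, "plasticity_params"))
  decay <- params$lam * params$alpha_s
  G <- weights$G + params$alpha_m * nonlinearity_f(delta, params) - decay
  N <- weights$N + params$alpha_m * nonlinearity_f(-delta, params) - decay
  if (params$constrained) {
    G <- max(0, G); N <- max(0, N)
  }
  pathway_weights(G, N, weights$lam)
}

#' Scaled prediction error read out from pathway weights
#'
#' \deqn{\delta = \frac{r - (G - N)/2}{1 + (G + N)/(2\lambda)}}
#' This equals `spe_delta()` on the decoded `(m, s)`; it is also the
#' equilibrium dopamine level of the feedback circuit (see
#' [equilibrium_delta()]). The constant 1 in the denominator keeps the error
#' bounded when the encoded spread is small.
#'
#' @param r Observed reward.
#' @param weights A [pathway_weights()].
#' @return The scaled prediction error.
#' @export
scaled_pe_from_weights <- function(r, weights) {
  stopifnot(inherits(weights, "pathway_weights"))
  if (!is.numeric(r) || !all(is.finite(r)))
    stop("reward 'r' must be finite")
  denom <- 1 + (weights$G + weights$N) / (2 * weights$lam)
  if (denom <= 0)
    stop("nonpositive denominator 1 + (G+N)/(2*lam) = ", denom,
         "; encoded spread is not positive")
  (r - (weights$G - weights$N) / 2) / denom
}

#' Run the pathway-weight learner over a reward sequence
#'
#' Trial loop over [scaled_pe_from_weights()] and [weight_update()], starting
#' from the weights encoding `(m0, s0)`. In unconstrained mode the decoded
#' `(m, s)` trajectory is algebraically identical to [run_spe()] with the
#' same learning rates (up to floating-point rounding); constrained mode adds
#' the biological nonnegativity clip.
#'
#' @param rewards Numeric reward vector.
#' @param params A [plasticity_params()].
#' @param m0,s0 Initial decoded state (defaults 0 and 1, i.e. `G = N = 0`).
#' @return A data frame with columns `trial`, `r`, `delta`, `G`, `N`,
#'   `decoded_m`, `decoded_s`.
#' @export
run_pathway_learner <- function(rewards, params, m0 = 0, s0 = 1) {
  stopifnot(inherits(params, "plasticity_params"), is.numeric(rewards),
            all(is.finite(rewards)))
  n <- length(rewards)
  w <- encode_weights(m0, s0, params$lam, constrained = params$constrained)
  G <- numeric(n); N <- numeric(n); d <- numeric(n)
  for (t in seq_len(n)) {
    d[t] <- scaled_pe_from_weights(rewards[t], w)
    w <- weight_update(w, d[t], params)
    G[t] <- w$G; N[t] <- w$N
  }
  lam <- params$lam
  data.frame(trial = seq_len(n), r = rewards, delta = d, G = G, N = N,
             decoded_m = (G - N) / 2, decoded_s = 1 + (G + N) / (2 * lam))
}
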