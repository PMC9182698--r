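# Continuous-time leaky-integrator model of the dopamine--thalamus feedback
# loop. Dopamine activity delta relaxes towards (r - T); thalamic activity T
# relaxes towards the dopamine-modulated difference of the two pathway
# drives. At equilibrium delta equals the scaled prediction error read out
# from the weights.

#' Circuit time constants and encoding coefficient
#'
#' @param tau_delta Time constant of striatal dopamine release, ms
#'   (default 300, the decay time of striatal dopamine transients).
#' @param tau_T Thalamic membrane time constant, ms (default 10).
#' @param lam Encoding coefficient lambda (> 0).
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(tau_delta = 300, tau_T = 10, lam = 1) {
  stopifnot(tau_delta > 0, tau_T > 0, lam > 0)
  structure(list(tau_delta = tau_delta, tau_T = tau_T, lam = lam),
            class = "circuit_params")
}

#' Step inputs to the circuit
#'
#' Cortical drive is modelled as step functions: `G`, `N` and `r` are zero
#' before `t_on` and jump to their step values at `t_on` (right-continuous).
#'
#' @param G_step,N_step Post-onset pathway inputs (defaults 10 and 6).
#' @param r_step Post-onset reward input (default 4).
#' @param t_on Onset time in ms (default 0).
#' @return An object of class `step_inputs`.
#' @export
step_inputs <- function(G_step = 10, N_step = 6, r_step = 4, t_on = 0) {
  stopifnot(is.finite(G_step), is.finite(N_step), is.finite(r_step),
            is.finite(t_on))
  structure(list(G_step = G_step, N_step = N_step, r_step = r_step,
                 t_on = t_on), class = "step_inputs")
}

#' Time derivatives of the circuit state
#'
#' \deqn{\tau_\delta \dot\delta = -\delta + r - T}
#' \deqn{\tau_T \dot T = -T + \frac{1 + \delta/\lambda}{2} G
#'                          - \frac{1 - \delta/\lambda}{2} N}
#'
#' @param delta Dopamine signal.
#' @param T Thalamic activity.
#' @param G,N,r Instantaneous input levels.
#' @param params A [circuit_params()].
#' @return Numeric vector `c(ddelta_dt, dT_dt)` (per ms).
#' @export
circuit_derivatives <- function(delta, T, G, N, r, params) {
  stopifnot(inherits(params, "circuit_params"))
  lam <- params$lam
  ddelta <- (-delta + r - T) / params$tau_delta
  dT <- (-T + (1 + delta / lam) / 2 * G - (1 - delta / lam) / 2 * N) /
    params$tau_T
  c(ddelta, dT)
}

#' Closed-form equilibrium dopamine level
#'
#' Solving the two nullclines gives
#' \eqn{\delta^* = (r - (G-N)/2) / (1 + (G+N)/(2\lambda))}, i.e. exactly the
#' weight-readout scaled prediction error; the time constants drop out.
#'
#' @param r Reward input level.
#' @param G,N Pathway input levels.
#' @param lam Encoding coefficient lambda.
#' @return The equilibrium dopamine signal.
#' @export
equilibrium_delta <- function(r, G, N, lam = 1) {
  scaled_pe_from_weights(r, pathway_weights(G, N, lam))
}

# Dormand-Prince RK45 with adaptive step size; integrates the autonomous
# circuit ODE with constant inputs from y0 at t0 to the times in `times`
# (sorted, times[1] == t0). Returns a matrix of states at `times`.
rk45_segment <- function(y0, times, G, N, r, params, rtol, atol, h_init) {
  a <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  f <- function(y) circuit_derivatives(y[1], y[2], G, N, r, params)
  n_out <- length(times)
  out <- matrix(NA_real_, n_out, 2)
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- h_init
  k <- matrix(0, 7, 2)
  for (i in seq_len(n_out - 1L)) {
    t_end <- times[i + 1L]
    while (t < t_end) {
      h <- min(h, t_end - t)
      k[1, ] <- f(y)
      for (s in 1:6) {
        ys <- y + h * drop(a[[s]] %*% k[seq_along(a[[s]]), , drop = FALSE])
        k[s + 1L, ] <- f(ys)
      }
      y5 <- y + h * drop(b5 %*% k)
      y4 <- y + h * drop(b4 %*% k)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        t <- t + h
        y <- y5
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- h * min(5, max(0.2, fac))
      if (h < 1e-12)
        stop("circuit integrator step size underflow at t = ", t, " ms")
    }
    out[i + 1L, ] <- y
  }
  list(y = out, h = h)
}

#' Simulate the dopamine--thalamus feedback circuit
#'
#' Integrates the two leaky-integrator equations from rest,
#' `(delta, T) = (0, 0)`, under step inputs, with an adaptive
#' Dormand-Prince RK45 scheme. Integration is split exactly at the input
#' onset so the discontinuity never falls inside a step, and the solution is
#' reported on a fixed 1-ms grid regardless of the internal adaptive steps.
#'
#' @param params A [circuit_params()].
#' @param inputs A [step_inputs()].
#' @param t_span Length-2 vector, simulation window in ms
#'   (default `c(-200, 500)`); must cover the onset.
#' @param dt_out Output grid spacing in ms (default 1).
#' @param rtol,atol Integrator tolerances (defaults 1e-8, 1e-10).
#' @return A data frame of class `circuit_trajectory` with columns `t`,
#'   `delta`, `T`; attributes `params`, `inputs` and `equilibrium` (the
#'   closed-form post-onset equilibrium dopamine level).
#' @examples
#' traj <- simulate_circuit(circuit_params(), step_inputs())
#' tail(traj$delta, 1)  # ~ 2/9
#' @export
simulate_circuit <- function(params = circuit_params(),
                             inputs = step_inputs(),
                             t_span = c(-200, 500), dt_out = 1,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"), inherits(inputs, "step_inputs"),
            length(t_span) == 2, t_span[1] < t_span[2], dt_out > 0)
  if (inputs$t_on < t_span[1] || inputs$t_on > t_span[2])
    stop("t_span must cover the input onset t_on = ", inputs$t_on)
  t_grid <- seq(t_span[1], t_span[2], by = dt_out)
  if (t_grid[length(t_grid)] < t_span[2]) t_grid <- c(t_grid, t_span[2])
  pre <- t_grid[t_grid < inputs$t_on]
  post <- t_grid[t_grid >= inputs$t_on]
  h0 <- min(params$tau_T, params$tau_delta) / 10

  y <- c(0, 0)
  n <- length(t_grid)
  sol <- matrix(NA_real_, n, 2)
  if (length(pre) > 0) {
    seg <- rk45_segment(y, c(pre, inputs$t_on), 0, 0, 0, params,
                        rtol, atol, h0)
    sol[seq_along(pre), ] <- seg$y[seq_along(pre), ]
    y <- seg$y[nrow(seg$y), ]
  }
  if (length(post) > 0) {
    seg_times <- c(inputs$t_on, post[post > inputs$t_on])
    seg <- rk45_segment(y, seg_times, inputs$G_step, inputs$N_step,
                        inputs$r_step, params, rtol, atol, h0)
    # first grid point at/after onset may coincide with t_on itself
    post_vals <- if (post[1] == inputs$t_on) seg$y else seg$y[-1, , drop = FALSE]
    sol[length(pre) + seq_along(post), ] <- post_vals
  }
  eq <- tryCatch(
    equilibrium_delta(inputs$r_step, inputs$G_step, inputs$N_step, params$lam),
    error = function(e) NA_real_)
  out <- data.frame(t = t_grid, delta = sol[, 1], T = sol[, 2])
  attr(out, "params") <- params
  attr(out, "inputs") <- inputs
  attr(out, "equilibrium") <- eq
  class(out) <- c("circuit_trajectory", "data.frame")
  out
}

#' Settling time of the dopamine signal
#'
#' First time at or after input onset from which `|delta(t) - delta*|` stays
#' within `rel_tol * |delta*|` for all remaining samples (an absolute band
#' `rel_tol` is used when `delta* == 0`). Returns `NA` with a warning if the
#' trajectory never settles within its time span.
#'
#' @param traj A [simulate_circuit()] trajectory.
#' @param rel_tol Relative tolerance band (default 0.05).
#' @param delta_star Equilibrium value; defaults to the trajectory's
#'   `equilibrium` attribute.
#' @return Settling time in ms, or `NA_real_`.
#' @export
settling_time <- function(traj, rel_tol = 0.05, delta_star = NULL) {
  stopifnot(inherits(traj, "circuit_trajectory"), rel_tol > 0)
  if (is.null(delta_star)) delta_star <- attr(traj, "equilibrium")
  stopifnot(is.finite(delta_star))
  t_on <- attr(traj, "inputs")$t_on
  band <- if (delta_star == 0) rel_tol else rel_tol * abs(delta_star)
  idx <- which(traj$t >= t_on)
  dev <- abs(traj$delta[idx] - delta_star)
  inside <- rev(cumprod(rev(dev <= band))) > 0  # inside band until the end
  if (!any(inside)) {
    warning("trajectory does not settle within its time span")
    return(NA_real_)
  }
  traj$t[idx[which(inside)[1]]]
}

#' Write a circuit trajectory to CSV with a JSON parameter sidecar
#'
#' @param traj A [simulate_circuit()] trajectory.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_circuit_csv <- function(traj, path) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  df <- data.frame(t_ms = traj$t, delta = traj$delta, T = traj$T)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(unclass(attr(traj, "params")), unclass(attr(traj, "inputs")),
            list(equilibrium_delta = attr(traj, "equilibrium")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
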