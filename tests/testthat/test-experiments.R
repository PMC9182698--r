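# Experiment drivers and CLI.

test_that("benchmark tables are fully reproducible from config + seed", {
  cfg <- benchmark_config(rw_alphas = c(0.1, 0.9), sigma_grid = c(1, 15),
                          n_trials = 2000, seed = 4L)
  a <- run_tracking_benchmark(cfg)
  b <- run_tracking_benchmark(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 4)  # (2 rw + spe + kalman) x 2 sigmas
  expect_true(all(c("learner", "alpha", "sigma", "seed", "mse",
                    "log10_mse") %in% names(a)))
  expect_true(all(is.finite(a$log10_mse)))
})

test_that("benchmark reproduces the plateau/slope ordering at the extremes", {
  cfg <- benchmark_config(rw_alphas = c(0.007, 0.993),
                          sigma_grid = c(0.14, 1000),
                          n_trials = 1e4, seed = 3L)
  res <- subset(run_tracking_benchmark(cfg), learner == "rw")
  mse <- function(a, s) res$mse[res$alpha == a & res$sigma == s]
  # small alpha underfits at low noise, wins at high noise
  expect_gt(mse(0.007, 0.14), mse(0.993, 0.14))
  expect_lt(mse(0.007, 1000), mse(0.993, 1000))
})

test_that("pavlovian simulation separates the two models' signatures", {
  res <- run_tobler_experiment(seed = 1L)
  rew <- subset(res, outcome == "rewarded")
  unr <- subset(res, outcome == "unrewarded")
  # prediction lies between the outcomes: opposite signs
  expect_true(all(rew$mean_delta > 0))
  expect_true(all(unr$mean_delta < 0))
  # RW rewarded response scales ~ linearly with magnitude (m -> r/2)
  rw <- rew[rew$model == "rw", ]
  rw <- rw[order(rw$magnitude), ]
  ratio <- rw$mean_delta[3] / rw$mean_delta[1]
  expect_lt(abs(ratio / (0.5 / 0.05) - 1), 0.2)
  # SPE rewarded response approximately magnitude-invariant
  spe <- rew$mean_delta[rew$model == "spe"]
  expect_lt(max(spe) / min(spe), 1.2)
  # normalization uses the population sd of the six means, per model
  for (mdl in c("rw", "spe")) {
    v <- res$mean_delta[res$model == mdl]
    expect_equal(res$normalized[res$model == mdl],
                 v / sqrt(mean((v - mean(v))^2)))
  }
})

test_that("per-reward responses follow r - mu and (r - mu)/sigma", {
  dists <- rothenhoefer_distributions()
  for (nm in names(dists)) {
    mom <- distribution_moments(dists[[nm]])
    rw <- rothenhoefer_responses(dists[[nm]], "rw")
    spe <- rothenhoefer_responses(dists[[nm]], "spe")
    expect_equal(rw$response, dists[[nm]]$support - mom$mean)
    expect_equal(spe$response, (dists[[nm]]$support - mom$mean) / mom$sd)
    # response to the mean reward is zero under both models
    expect_equal(rw$response[rw$r == mom$mean], 0)
  }
  # smaller-sd distribution: larger scaled response at the common extreme
  hi <- rothenhoefer_responses(dists$normal, "spe")
  lo <- rothenhoefer_responses(dists$uniform, "spe")
  expect_gt(max(hi$response), max(lo$response))
  # unscaled responses identical across distributions (equal means)
  expect_equal(rothenhoefer_responses(dists$normal, "rw")$response,
               rothenhoefer_responses(dists$uniform, "rw")$response)
  expect_error(rothenhoefer_responses(discrete_reward_dist(2, 1), "spe"),
               "variance")
})

test_that("log-scale prediction error is magnitude-invariant", {
  expect_equal(reward_taxis_response(0.05, 0.5), log(2))
  expect_equal(reward_taxis_response(0.5, 0.5), log(2))
  expect_equal(reward_taxis_response(c(0.1, 1, 10), 0.25), rep(log(4), 3))
  expect_equal(reward_taxis_response(3, 1), 0)
  expect_error(reward_taxis_response(-1, 0.5), "positive")
  expect_error(reward_taxis_response(1, 0), "0, 1")
})

test_that("kalman curves converge to their steady-state limits", {
  cur <- kalman_curves(sigma_grid = c(1, 2, 5, 15, 100),
                       nu_list = c(0, 0.5, 1), n_steps = 200)
  pv <- cur$posterior_var
  for (nu in c(0.5, 1)) {
    sub <- pv[pv$nu == nu, ]
    expect_equal(tail(sub$w, 1), sub$w_inf[1], tolerance = 1e-6)
  }
  # nu = 0: posterior variance decreases monotonically towards 0
  sub0 <- pv[pv$nu == 0, ]
  expect_true(all(diff(sub0$w) < 0))
  expect_lt(tail(sub0$w, 1), 0.01)
  expect_equal(sub0$w_inf[1], 0)
  # approximation error below 30% at sigma/nu = 2 and shrinking with sigma
  g <- cur$gains
  expect_lt(g$rel_diff[g$sigma == 2], 0.30)
  expect_true(all(diff(g$rel_diff) < 0))
})

test_that("CLI subcommands write CSV results with JSON provenance", {
  out <- withr::local_tempdir()
  spe_cli(c("tobler", "--seed", "2", "--out-dir", out))
  res <- read.csv(file.path(out, "tobler.csv"))
  expect_equal(nrow(res), 12)
  ref <- run_tobler_experiment(seed = 2L)
  expect_equal(res$mean_delta, ref$mean_delta, tolerance = 1e-10)
  expect_equal(res$model, ref$model)
  prov <- jsonlite::read_json(file.path(out, "tobler.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$alpha, 0.0067)

  spe_cli(c("circuit", "--out-dir", out))
  circ <- read.csv(file.path(out, "circuit.csv"))
  expect_equal(tail(circ$delta, 1), 2 / 9, tolerance = 1e-4)

  spe_cli(c("rothenhoefer", "--out-dir", out))
  expect_true(file.exists(file.path(out, "rothenhoefer.csv")))

  cfg <- file.path(out, "cfg.json")
  jsonlite::write_json(list(sigma_grid = c(1, 15), nu_list = 1, n_steps = 5),
                       cfg, auto_unbox = TRUE)
  spe_cli(c("kalman-curves", "--config", cfg, "--out-dir", out))
  expect_true(file.exists(file.path(out, "kalman_gains.csv")))

  bad <- file.path(out, "bad.json")
  jsonlite::write_json(list(nonsense = 1), bad, auto_unbox = TRUE)
  expect_error(spe_cli(c("tobler", "--config", bad)), "unknown config")
  expect_error(spe_cli("frobnicate"), "usage")
})

test_that("CLI benchmark honours config scaling", {
  out <- withr::local_tempdir()
  cfg <- file.path(out, "bench.json")
  jsonlite::write_json(list(rw_alphas = c(0.1, 0.9), sigma_grid = c(1, 15),
                            n_trials = 1000),
                       cfg, auto_unbox = TRUE)
  spe_cli(c("benchmark", "--seed", "5", "--config", cfg, "--out-dir", out))
  res <- read.csv(file.path(out, "benchmark.csv"))
  expect_equal(nrow(res), 8)
  expect_equal(unique(res$n_trials), 1000)
})
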