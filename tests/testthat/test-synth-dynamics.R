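# Synthetic generator: latent simulation, observation maps, noise, masking,
# stimulus datasets.

test_that("linear_discrete dynamics advances exactly", {
  sys <- latent_system("linear_discrete", parameters = list(M = diag(2)),
                       x0 = c(1, 2))
  traj <- simulate_latent(sys, 3)
  expect_equal(traj, matrix(c(1, 2), 3, 2, byrow = TRUE))

  sys2 <- latent_system("linear_discrete",
                        parameters = list(M = diag(c(0.5, 1))), x0 = c(4, 4))
  expect_equal(simulate_latent(sys2, 3),
               rbind(c(4, 4), c(2, 4), c(1, 4)))
})

test_that("slow-manifold RK4 integration matches the closed-form solution", {
  mu <- -0.05; lambda <- -1
  sys <- latent_system("slow_manifold",
                       parameters = list(mu = mu, lambda = lambda),
                       dt = 0.01, x0 = c(1, 1))
  traj <- simulate_latent(sys, 101)   # t = 0 .. 1
  exact <- slow_manifold_exact(seq(0, 1, by = 0.01), c(1, 1), mu, lambda)
  expect_equal(traj[1, ], c(1, 1))
  expect_lt(max(abs(traj - exact)), 1e-9)
  # spot-check the t = 1 closed form explicitly
  cc <- lambda / (lambda - 2 * mu)
  expect_equal(traj[101, 1], exp(-0.05), tolerance = 1e-9)
  expect_equal(traj[101, 2], (1 - cc) * exp(-1) + cc * exp(-0.1),
               tolerance = 1e-9)
})

test_that("RK4 agrees with an adaptive ODE oracle on a custom system", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, x) c(-0.3 * x[1] + 0.5 * x[2], -0.5 * x[1] - 0.3 * x[2])
  sys <- latent_system("custom_ode", parameters = list(rhs = rhs),
                       dt = 0.05, x0 = c(1, -1))
  traj <- simulate_latent(sys, 81)
  sol <- deSolve::ode(y = c(1, -1), times = seq(0, 4, by = 0.05),
                      func = function(t, y, parms) list(rhs(t, y)),
                      rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(traj - sol[, 2:3])), 1e-7)
})

test_that("divergent dynamics raises an error naming the step", {
  sys <- latent_system("linear_discrete",
                       parameters = list(M = matrix(1e200, 1, 1)), x0 = 1)
  expect_error(simulate_latent(sys, 5), "step 3")
})

test_that("observation maps, delays and alignment follow the definitions", {
  latent <- cbind(seq(-2, 3, by = 1), rep(1, 6))
  # identity, no delay, no noise: equals the latent trajectory
  obs <- observation_spec(modality_spec("a", "identity", channels = 2))
  out <- observe_modalities(latent, obs)
  expect_equal(out$a$values, latent, ignore_attr = TRUE)

  # square map is applied pointwise
  obs2 <- observation_spec(
    modality_spec("sq", list(type = "polynomial", coefficients = c(0, 0, 1))))
  expect_equal(as.numeric(observe_modalities(cbind(c(-2, 3)), obs2)$sq$values),
               c(4, 9))

  # two identity modalities with delays 0 and 3: B at step k equals A at k-3,
  # and both series share length T - 3
  traj <- cbind(stats::rnorm(50))
  obs3 <- observation_spec(modality_spec("A", "identity"),
                           modality_spec("B", "identity", delay_steps = 3))
  out3 <- observe_modalities(traj, obs3)
  expect_equal(nrow(out3$A$values), 47)
  expect_equal(out3$B$values[4:47, 1], out3$A$values[1:44, 1])
  expect_error(observe_modalities(traj[1:3, , drop = FALSE],
                                  observation_spec(modality_spec("x", delay_steps = 5))),
               "delay")
})

test_that("cross-correlation peaks at the configured delay difference", {
  sys <- rotation_system(period = 24)
  traj <- simulate_latent(sys, 300)
  obs <- observation_spec(modality_spec("A", "identity"),
                          modality_spec("B", "identity", delay_steps = 5))
  out <- observe_modalities(traj, obs)
  cc <- stats::ccf(out$A$values[, 1], out$B$values[, 1], lag.max = 10,
                   plot = FALSE)
  # ccf(A, B) correlates A(t + k) with B(t); B lagging A by 5 peaks at k = -5
  expect_equal(cc$lag[which.max(cc$acf)], -5)
})

test_that("noise is calibrated to the requested SNR", {
  # definition of dB: power 1 channel at 10 dB -> noise variance 0.1
  x <- sin(2 * pi * (1:10000) / 40) * sqrt(2)   # unit power
  noisy <- add_noise_snr(matrix(x), 10, seed = 1)
  expect_equal(stats::var(as.numeric(noisy - x)), 0.1, tolerance = 0.05)
  # realized SNR within +/- 1 dB at T = 1e4
  p_sig <- mean((x - mean(x))^2)
  p_noise <- mean((noisy - x)^2)
  expect_lt(abs(10 * log10(p_sig / p_noise) - 10), 1)
  # no-noise passthrough and zero-variance error
  expect_identical(add_noise_snr(matrix(x), Inf), matrix(x))
  expect_error(add_noise_snr(matrix(rep(1, 10)), 10, seed = 1), "zero variance")
})

test_that("masking fills with the sentinel, is isolated and idempotent", {
  batch <- list(hr = modal_series(cbind(1:5), "hr"),
                eda = modal_series(cbind(6:10), "eda"))
  masked <- mask_modality(batch, "hr", -1)
  expect_true(all(masked$hr$values == -1))
  expect_true(all(masked$hr$missing))
  expect_identical(masked$eda, batch$eda)
  expect_identical(mask_modality(masked, "hr", -1)$hr, masked$hr)
  expect_error(mask_modality(batch, "resp"), "unknown modality")
})

test_that("stimulus datasets hand off state continuously and record onsets", {
  pre <- rotation_system(period = 40)
  post <- rotation_system(period = 10)
  obs <- observation_spec(modality_spec("A", "identity"),
                          modality_spec("B", "identity", delay_steps = 5))
  ds <- make_stimulus_dataset(pre, post, obs, stimulus_step = 60,
                              n_steps = 120, seed = 9)
  expect_equal(ds$event$onset_latent[["B"]] - ds$event$onset_latent[["A"]], 5)
  expect_equal(ds$event$onset_index[["B"]] - ds$event$onset_index[["A"]], 5)
  # continuous handoff: no jump at the stimulus row
  jumps <- abs(diff(ds$latent[, 1]))
  expect_lt(jumps[60], 3 * max(jumps[1:59]))
  # identical pre/post specs reduce to plain simulate + observe
  ds0 <- make_stimulus_dataset(pre, pre, obs, 60, 120, seed = 9)
  plain <- observe_modalities(simulate_latent(pre, 120), obs, seed = 9)
  expect_equal(ds0$series$A$values, plain$A$values)
  # deterministic regeneration
  ds2 <- make_stimulus_dataset(pre, post, obs, 60, 120, seed = 9)
  expect_identical(ds$series, ds2$series)
  # incompatible state dimensions
  bad <- latent_system("linear_discrete", parameters = list(M = diag(3)),
                       x0 = c(1, 1, 1))
  expect_error(make_stimulus_dataset(pre, bad, obs, 60, 120),
               "incompatible state dimensions")
})

test_that("generator operations are deterministic given a seed", {
  obs <- benchmark_obs(snr_db = 10)
  traj <- simulate_latent(rotation_system(), 100)
  a <- observe_modalities(traj, obs, seed = 4)
  b <- observe_modalities(traj, obs, seed = 4)
  expect_identical(a, b)
  c <- observe_modalities(traj, obs, seed = 5)
  expect_false(identical(a$ident$values, c$ident$values))
})
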