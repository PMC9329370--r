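# Metrics, restoration, rollout, loss traces and the reaction-time detector.

test_that("rmse follows its definition and is a metric", {
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(rep(0, 7), rep(2.5, 7)), 2.5)
  a <- matrix(stats::rnorm(20), 5); b <- matrix(stats::rnorm(20), 5)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:4, 1:5), "shape mismatch")
})

test_that("restoration ignores the masked modality's stored values", {
  fit <- cached_small_fit()
  dat <- .subset2(fit, "data")
  r1 <- restore_missing(fit, dat, "b")
  poisoned <- dat
  poisoned$b$values[] <- -1
  r2 <- restore_missing(fit, poisoned, "b")
  expect_identical(r1$b$values, r2$b$values)
  expect_error(restore_missing(fit, dat, c("a", "b")), "all modalities")
})

test_that("restoration from duplicate modalities is near-exact", {
  # two modalities that are exact copies: restoring one from the other should
  # be as accurate as reconstructing it directly
  obs <- observation_spec(modality_spec("u", "identity", channels = 2),
                          modality_spec("v", "identity", channels = 2))
  series <- observe_modalities(simulate_latent(rotation_system(), 300), obs)
  fit <- kmmae(series, d = 1, tau = 1, p = 3, m = 1, epochs = 150,
               snr_db = Inf, mask_probability = 0.5, seed = 13,
               learning_rate = 3e-3, patience = 150)
  rec <- predict(fit, type = "reconstruct")
  res <- restore_missing(fit, series, "v")
  ks_rec <- attr(rec$v, "k"); ks_res <- attr(res$v, "k")
  rmse_rec <- rmse(series$v$values[ks_rec, ], rec$v$values)
  rmse_res <- rmse(series$v$values[ks_res, ], res$v$values)
  expect_lt(rmse_res, 3 * max(rmse_rec, 0.02))
})

test_that("rollout composes the propagator and degenerates correctly", {
  fit <- cached_small_fit()
  dat <- .subset2(fit, "data")
  # A = I makes every horizon equal the fused reconstruction at k
  fit_id <- fit
  fit_id$model$params$A <- diag(fit$model$arch$p)
  ro <- rollout_predict(fit_id, dat, horizon = 3)
  expect_equal(ro$a[1, ], ro$a[3, ], tolerance = 1e-10)
  # two one-step rollouts equal one two-step rollout (same start)
  emb <- kmmae:::.prepare_embedded(fit, dat)
  fs <- kmmae:::.fused_states(fit, emb)
  k0 <- fs$ks[length(fs$ks)]
  ro2 <- rollout_predict(fit, dat, horizon = 2, from = k0)
  y <- fs$ybar[, ncol(fs$ybar)]
  y2 <- step_linear(fit, step_linear(fit, y, 1), 1)
  dec <- decode(fit, "a", y2)
  C <- length(fit$standardizers$a$mean)
  expect_equal(ro2$a[2, ],
               as.numeric(unstandardize(matrix(dec[seq_len(C)], 1),
                                        fit$standardizers$a)),
               tolerance = 1e-10)
})

test_that("loss traces have the documented shape and stay flat in-distribution", {
  fit <- cached_small_fit()
  dat <- .subset2(fit, "data")
  tr <- loss_trace(fit, dat, horizon = 1)
  emb <- kmmae:::.prepare_embedded(fit, dat)
  K <- length(kmmae:::.align_embedded(emb)$ks)
  expect_equal(nrow(tr$loss1), K)
  expect_true(all(is.na(tr$loss2[1, ])))
  expect_true(all(!is.na(tr$loss2[-1, ])))
  # in-distribution: no systematic trend in the reconstruction trace
  tau_k <- stats::cor(seq_len(K), tr$loss1[, "a"], method = "kendall")
  expect_lt(abs(tau_k), 0.35)
})

test_that("reaction-time detection matches the constructed example", {
  loss1 <- c(rep(1, 10), 1, 1.2, rep(2, 8))
  loss2 <- loss1
  tr <- event_trace(loss1, loss2, stimulus_index = 10)
  expect_equal(tr$baseline1, 1)
  ri <- detect_reaction_time(tr, ratio = 1.5, consec_len = 3)
  expect_equal(as.integer(ri), 13)
  # flat traces: no detection
  flat <- event_trace(rep(1, 20), rep(1, 20), 10)
  expect_true(is.na(detect_reaction_time(flat, ratio = 1.5)))
  # both losses must exceed: spike in one alone is not enough
  tr1 <- event_trace(loss1, rep(1, 20), 10)
  expect_true(is.na(detect_reaction_time(tr1, ratio = 1.5)))
  expect_error(event_trace(loss1, loss2, 1), "pre-stimulus")
})

test_that("raising the ratio never yields an earlier reaction", {
  set.seed(31)
  for (i in 1:10) {
    base <- abs(stats::rnorm(30, 1, 0.1))
    spike <- abs(stats::rnorm(30, 1, 0.1)) * c(rep(1, 12), seq(1, 6, length.out = 18))
    tr <- event_trace(spike, spike * stats::runif(1, 0.5, 2), 12)
    prev <- -Inf
    for (ratio in c(1.2, 1.5, 2, 3)) {
      ri <- suppressWarnings(detect_reaction_time(tr, ratio = ratio))
      cur <- if (is.na(ri)) Inf else as.integer(ri)
      expect_gte(cur, prev)
      prev <- cur
    }
  }
})

test_that("pre-stimulus exceedances are flagged as a warning, not a detection", {
  loss <- c(rep(1, 5), 10, rep(1, 4), rep(5, 10))
  tr <- event_trace(loss, loss, 11)
  expect_warning(ri <- detect_reaction_time(tr, ratio = 1.5), "before the stimulus")
  expect_gte(as.integer(ri), 11)
})

test_that("edmd recovers exact propagators and spectra", {
  # linear system: dmd is exact
  M <- matrix(c(0.9, 0.05, -0.1, 0.8), 2)
  x <- matrix(0, 40, 2); x[1, ] <- c(1, -2)
  for (k in 2:40) x[k, ] <- M %*% x[k - 1, ]
  f <- dmd(x)
  expect_lt(max(abs(f$A - M)), 1e-10)
  expect_lt(f$residual_rmse, 1e-12)
  # slow manifold with the exact dictionary {x1, x2, x1^2}
  sys <- latent_system("slow_manifold", parameters = list(mu = -0.05, lambda = -1),
                       dt = 0.01, x0 = c(1, 1))
  traj <- simulate_latent(sys, 500)
  fe <- edmd(traj, dictionary = function(z) cbind(z, z[, 1]^2))
  expect_equal(sort(Mod(fe$eigenvalues)),
               sort(exp(c(-0.05, -1, -0.1) * 0.01)), tolerance = 1e-6)
})
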