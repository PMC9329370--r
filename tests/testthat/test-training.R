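# Data splitting, window construction and the optimization loop.

test_that("random session split gives 8/1/1 on ten sessions and is seeded", {
  sp <- split_dataset(10, "random", seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$val, 1)
  expect_length(sp$test, 1)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:10)
  expect_identical(sp, split_dataset(10, "random", seed = 1))
  expect_false(identical(sp, split_dataset(10, "random", seed = 2)))
})

test_that("stratified split keeps every condition in every set", {
  labels <- rep(c("ND", "CD", "ED", "MD"), each = 5)
  sp <- split_dataset(20, "random", labels = labels, seed = 3)
  for (part in sp) expect_setequal(unique(labels[part]), unique(labels))
  expect_error(split_dataset(4, "random", labels = c("a", "a", "a", "b"),
                             seed = 1),
               "fewer than 3")
})

test_that("temporal split cuts at the stated fractions in time order", {
  sp <- split_dataset(100, "temporal")
  expect_equal(sp$train, 1:70)
  expect_equal(sp$val, 71:80)
  expect_equal(sp$test, 81:100)
  expect_error(split_dataset(5, "temporal", fractions = c(0.98, 0.01, 0.01)),
               "too short")
})

test_that("window counts and alignment follow the horizon", {
  emb <- list(a = delay_embed(stats::rnorm(12), d = 1, tau = 1))
  w <- make_training_windows(emb, m = 5)
  expect_equal(w$n, 7)                     # k = 1..7 have 5-step targets
  w1 <- make_training_windows(list(a = delay_embed(stats::rnorm(2), 1, 1)), m = 1)
  expect_equal(w1$n, 1)
  expect_error(make_training_windows(
    list(a = delay_embed(stats::rnorm(3), 1, 1)), m = 5), "windows")

  # mixed embeddings stay aligned on the source index
  x <- stats::rnorm(30)
  emb2 <- list(a = delay_embed(x, d = 3, tau = 2), b = delay_embed(x, d = 1, tau = 1))
  w2 <- make_training_windows(emb2, m = 2)
  expect_equal(ncol(w2$x0$a), ncol(w2$x0$b))
  # modality b's current sample equals modality a's first lag block
  expect_equal(w2$x0$b[1, ], w2$x0$a[1, ])
})

test_that("zero training epochs returns the freshly initialized model", {
  series <- observe_modalities(
    simulate_latent(rotation_system(), 120),
    observation_spec(modality_spec("a", "identity", channels = 2)))
  fit <- kmmae(series, d = 1, tau = 1, p = 2, m = 1, epochs = 0, seed = 9)
  ref <- kmmae_model(c(a = 2L), p = 2L, seed = 9)
  expect_identical(fit$model$params, ref$params)
  expect_equal(nrow(fit$history), 0)
})

test_that("training is reproducible and tracks the best validation epoch", {
  series <- observe_modalities(
    simulate_latent(rotation_system(), 200),
    observation_spec(modality_spec("a", "identity", channels = 2),
                     modality_spec("b", list(type = "affine", scale = 2), channels = 1)))
  fit1 <- kmmae(series, d = 1, tau = 1, p = 3, m = 1, epochs = 25,
                snr_db = 20, mask_probability = 0.5, seed = 7)
  fit2 <- kmmae(series, d = 1, tau = 1, p = 3, m = 1, epochs = 25,
                snr_db = 20, mask_probability = 0.5, seed = 7)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$best_val, min(fit1$history$val_total))
  expect_equal(fit1$history$val_total[fit1$best_epoch], fit1$best_val)
  # loss-report identity holds row by row in the history
  with(fit1$history, expect_equal(
    val_total,
    val_recon + val_predict + val_linear + val_modality + 1e-8 * val_reg,
    tolerance = 1e-6))
})

test_that("training a linear system approaches the DMD least-squares solution", {
  sys <- latent_system("linear_discrete",
                       parameters = list(M = diag(c(0.9, 0.5))), x0 = c(4, 4))
  series <- observe_modalities(simulate_latent(sys, 500),
    observation_spec(modality_spec("x", "identity", channels = 2)))
  fit <- kmmae(series, d = 1, tau = 1, p = 2, m = 3, activation = "identity",
               epochs = 250, snr_db = Inf, mask_probability = 0, seed = 3,
               learning_rate = 3e-3, patience = 250)
  # one-step prediction RMSE on the validation windows, standardized scale
  emb <- kmmae:::.prepare_embedded(fit, series)
  wv <- make_training_windows(emb, 1, k_range = range(fit$split$val))
  model_rmse <- sqrt(predict_loss(fit, wv, m = 1) / 2)
  expect_lt(model_rmse, 0.05)
  # Koopman-consistency smoke test: exactly-embeddable system drives the
  # linearity loss far down
  expect_lt(linear_loss(fit, wv, m = 1), 1e-3)
})

test_that("noise augmentation keeps the clean targets (denoising setup)", {
  series <- observe_modalities(
    simulate_latent(rotation_system(), 150),
    observation_spec(modality_spec("a", "identity", channels = 2)))
  fit_noisy <- kmmae(series, d = 1, tau = 1, p = 2, m = 1, epochs = 10,
                     snr_db = 0, mask_probability = 0, seed = 2)
  fit_clean <- kmmae(series, d = 1, tau = 1, p = 2, m = 1, epochs = 10,
                     snr_db = Inf, mask_probability = 0, seed = 2)
  # different augmentation, different parameters, same shapes
  expect_false(identical(fit_noisy$model$params, fit_clean$model$params))
  expect_identical(lapply(fit_noisy$model$params, dim),
                   lapply(fit_clean$model$params, dim))
})
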