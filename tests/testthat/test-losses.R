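# The four loss components and their weighted combination.

# identity autoencoder for one 2-channel modality (p = 2, linear layers)
identity_model <- function(ids = "a", width = 2L) {
  iw <- stats::setNames(rep(width, length(ids)), ids)
  m <- kmmae_model(iw, p = width, hidden = c(width, width),
                   activation = "identity", seed = 1)
  for (id in ids) {
    for (pre in c(paste0("enc_", id), paste0("dec_", id))) {
      for (i in 1:3) {
        m$params[[sprintf("%s_W%d", pre, i)]] <- diag(width)
        m$params[[sprintf("%s_b%d", pre, i)]] <- numeric(width)
      }
    }
  }
  m
}

test_that("reconstruction loss reproduces the worked example", {
  # x = [1, 2] reconstructed as [1, 0]: loss ||(0, 2)||^2 = 4.
  # Decoder projects onto the first coordinate to produce [1, 0].
  m <- identity_model()
  m$params$dec_a_W3 <- diag(c(1, 0))
  batch <- kmmae_batch(list(a = c(1, 2)))
  expect_equal(recon_loss(m, batch), 4, tolerance = 1e-12)
  # perfect identity pipeline reconstructs exactly
  expect_equal(recon_loss(identity_model(), batch), 0, tolerance = 1e-12)
})

test_that("masked modalities contribute nothing to the reconstruction loss", {
  m <- identity_model(c("a", "b"))
  b1 <- kmmae_batch(list(a = c(1, 2), b = c(5, 5)))
  b2 <- kmmae_batch(list(a = c(1, 2), b = c(-3, 9)))
  m$params$dec_a_W3 <- diag(c(1, 0))
  expect_equal(recon_loss(m, b1, missing = "b"),
               recon_loss(m, b2, missing = "b"))
  expect_equal(recon_loss(m, b1, missing = "b"), 4)
})

test_that("prediction loss follows the m-step propagator formula", {
  m <- identity_model()
  # constant series under A = I: zero loss
  const <- kmmae_batch(list(a = rbind(c(1, 1), c(1, 1))),
                       targets = list(a = list(rbind(c(1, 1), c(1, 1)))))
  expect_equal(predict_loss(m, const, m = 1), 0, tolerance = 1e-12)
  # x(k) = k scalar ramp, m = 1: each term ||(k+1) - k||^2 = 1
  m1 <- identity_model(width = 1L)
  ramp <- kmmae_batch(list(a = rbind(1, 2, 3)),
                      targets = list(a = list(rbind(2, 3, 4))))
  expect_equal(predict_loss(m1, ramp, m = 1), 1, tolerance = 1e-12)
  # invariant under batch permutation
  perm <- kmmae_batch(list(a = rbind(3, 1, 2)),
                      targets = list(a = list(rbind(4, 2, 3))))
  expect_equal(predict_loss(m1, ramp, m = 1), predict_loss(m1, perm, m = 1))
  expect_error(predict_loss(m1, ramp, m = 5), "target steps")
})

test_that("linear loss vanishes for exactly embeddable linear dynamics", {
  # encoders identity, data following x(k+1) = M x(k), A = M
  M <- diag(c(0.5, 2))
  m <- identity_model()
  m$params$A <- M
  x0 <- rbind(c(1, 1), c(2, -1), c(-0.5, 3))
  x1 <- t(M %*% t(x0)); x2 <- t(M %*% t(x1))
  b <- kmmae_batch(list(a = x0), targets = list(a = list(x1, x2)))
  expect_equal(linear_loss(m, b, m = 2), 0, tolerance = 1e-12)
  expect_equal(predict_loss(m, b, m = 2), 0, tolerance = 1e-12)
  # quadratic form: scaling the residual by c scales the loss by c^2
  m_off <- m; m_off$params$A <- M * 1.1      # residual prop. to 0.1*M x
  m_off2 <- m; m_off2$params$A <- M * 1.2    # residual prop. to 0.2*M x
  l1 <- linear_loss(m_off, b, m = 1)
  l2 <- linear_loss(m_off2, b, m = 1)
  expect_equal(l2 / l1, 4, tolerance = 1e-9)
})

test_that("modality (center) loss matches the worked example", {
  expect_equal(modality_loss(list(a = c(0, 0), b = c(2, 0))), 1)
  expect_equal(modality_loss(list(a = c(1, 2), b = c(1, 2), c = c(1, 2))), 0)
  # single surviving modality: the center equals it
  expect_equal(modality_loss(list(a = c(0, 0), b = c(2, 0)), missing = "a"), 0)
})

test_that("the weighted total follows the published combination", {
  w <- loss_weights(m = 1)
  comp <- list(recon = 1, predict = 1, linear = 1, modality = 1, reg = 0)
  expect_equal(total_loss(comp, w)$total, 4, tolerance = 1e-12)
  # reg contribution: lambda 1e-8 times ||W||^2 = 1e8 contributes exactly 1
  w2 <- loss_weights(lambda_reg = 1e-8, m = 1)
  comp2 <- list(recon = 0, predict = 0, linear = 0, modality = 0, reg = 1e8)
  expect_equal(total_loss(comp2, w2)$total, 1, tolerance = 1e-12)
  # all lambdas zero: total zero regardless of components
  w0 <- loss_weights(0, 0, 0, 0, 0, m = 1)
  expect_equal(total_loss(comp, w0)$total, 0)
  expect_error(loss_weights(lambda_recon = -1), "nonnegative")
})

test_that("total is linear in each lambda holding components fixed", {
  comp <- list(recon = 0.3, predict = 0.7, linear = 0.2, modality = 0.9,
               reg = 10)
  for (lam in c("lambda_recon", "lambda_linear", "lambda_modality", "lambda_reg")) {
    tot_at <- function(v) {
      args <- list(m = 1L); args[[lam]] <- v
      total_loss(comp, do.call(loss_weights, args))$total
    }
    # equal increments in lambda give equal increments in the total
    expect_equal(tot_at(5) - tot_at(3), 2 * (tot_at(2) - tot_at(1)),
                 tolerance = 1e-9)
  }
})

test_that("all components are nonnegative on random models and batches", {
  set.seed(21)
  for (i in 1:5) {
    m <- kmmae_model(c(a = 3L, b = 4L), p = 3L, seed = i)
    b <- kmmae_batch(
      list(a = matrix(stats::rnorm(15), 5), b = matrix(stats::rnorm(20), 5)),
      targets = list(a = list(matrix(stats::rnorm(15), 5)),
                     b = list(matrix(stats::rnorm(20), 5))))
    rep <- kmmae_loss(m, b, loss_weights(m = 1))
    expect_true(all(unlist(rep[c("recon", "predict", "linear",
                                 "modality", "reg")]) >= 0))
    # report identity: total equals the weighted recombination
    expect_equal(rep$total, total_loss(rep, loss_weights(m = 1))$total,
                 tolerance = 1e-6 * max(1, rep$total))
  }
})

test_that("one-step prediction of a linear model matches the DMD residual", {
  # identity encoders/decoders, so predict_loss with m = 1 is the one-step
  # forecasting MSE of A on the raw data; cross-check against the
  # least-squares DMD solution fitted on the same series.
  set.seed(4)
  M <- matrix(c(0.9, 0.1, -0.1, 0.8), 2)
  x <- matrix(0, 60, 2); x[1, ] <- c(2, -1)
  for (k in 2:60) x[k, ] <- M %*% x[k - 1, ] + stats::rnorm(2, sd = 0.01)
  fitdmd <- dmd(x)
  m <- identity_model()
  m$params$A <- fitdmd$A
  b <- kmmae_batch(list(a = x[-60, ]), targets = list(a = list(x[-1, ])))
  pl <- predict_loss(m, b, m = 1)
  # predict_loss is the mean per-sample squared norm; DMD residual is the
  # entrywise RMSE of the same residual matrix
  expect_equal(sqrt(pl / 2), fitdmd$residual_rmse, tolerance = 1e-9)
})
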