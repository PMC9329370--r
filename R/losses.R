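#' Loss weights and horizon for the combined training objective
#'
#' The training objective combines four terms:
#' `total = lambda_recon * (L_recon + lambda_predict * L_predict) +
#'  lambda_linear * L_linear + lambda_modality * L_modality +
#'  lambda_reg * ||W||^2`,
#' where `L_predict` and `L_linear` run over a horizon of `m` steps of the
#' linear propagator.  All lambdas default to 1 (with `lambda_reg = 1e-8`),
#' the published settings; `lambda_predict` is an extra multiplier on the
#' prediction term defaulting to 1 so the two equivalent readings of the
#' objective coincide.
#'
#' @param lambda_recon,lambda_predict,lambda_linear,lambda_modality,lambda_reg
#'   nonnegative weights.
#' @param m prediction/linearity horizon in steps (>= 1).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_recon = 1, lambda_predict = 1, lambda_linear = 1,
                         lambda_modality = 1, lambda_reg = 1e-8, m = 5L) {
  w <- list(lambda_recon = lambda_recon, lambda_predict = lambda_predict,
            lambda_linear = lambda_linear, lambda_modality = lambda_modality,
            lambda_reg = lambda_reg, m = as.integer(m))
  lam <- unlist(w[1:5])
  if (any(!is.finite(lam)) || any(lam < 0)) stop("loss weights must be nonnegative")
  if (w$m < 1L) stop("'m' must be >= 1")
  structure(w, class = "loss_weights")
}

#' Assemble a training batch by hand
#'
#' Mostly useful for testing and inspection; the training loop builds batches
#' internally from [make_training_windows()].  Inputs are row-major (samples
#' in rows, width `d * C` per modality).
#'
#' @param inputs named list, one K x width matrix (or width-vector) per
#'   modality: the (possibly noisy/masked) network inputs at time `k`.
#' @param targets optional named list of lists: `targets[[id]][[j]]` holds the
#'   values at `k + j`, `j = 1..m`.
#' @param clean optional named list like `inputs` holding the clean values at
#'   `k` (reconstruction targets); defaults to `inputs`.
#' @return object of class `kmmae_batch`.
#' @export
kmmae_batch <- function(inputs, targets = NULL, clean = NULL) {
  tocol <- function(x) if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1) else t(as.matrix(x))
  x0 <- lapply(inputs, tocol)
  B <- unique(vapply(x0, ncol, integer(1)))
  if (length(B) != 1L) stop("all modalities must supply the same number of samples")
  xc <- if (is.null(clean)) x0 else lapply(clean, tocol)
  xj <- if (is.null(targets)) NULL else lapply(targets, function(tl) lapply(tl, tocol))
  m <- if (is.null(xj)) 0L else length(xj[[1L]])
  structure(list(x0 = x0, x0_clean = xc, xj = xj, m = m,
                 ids = names(x0), n = B),
            class = "kmmae_batch")
}

# Sum of squared entries of all weight matrices (biases excluded), incl. A.
.weight_norm2 <- function(params) {
  nm <- names(params)
  keep <- nm == "A" | grepl("_W[0-9]$", nm)
  sum(vapply(params[keep], function(w) sum(w * w), numeric(1)))
}

# Core forward (+ optional backward) pass over a batch.
#
# Components (B = batch size, nobs = number of observed modalities, mt = horizon):
#   recon    = 1/(B*nobs) sum_{l obs}      ||dec_l(enc_l(x_l)) - clean_l||^2
#   predict  = 1/(mt*B)   sum_{l all} sum_j ||dec_l(A^j ybar) - x_l(k+j)||^2
#   linear   = 1/(mt*B)   sum_{l obs} sum_j ||enc_l(x_l(k+j)) - A^j enc_l(x_l(k))||^2
#   modality = 1/(B*nobs) sum_{l obs}      ||ybar - enc_l(x_l)||^2
#   reg      = ||W||^2 (weights incl. A, biases excluded)
# Masked modalities never enter an encoder; their decoders are trained only
# through the prediction term from the fused state (restoration training).
.kmmae_grad <- function(model, batch, weights, missing = character(),
                        want_grad = TRUE, divisor = c("observed", "total")) {
  divisor <- match.arg(divisor)
  arch <- model$arch; params <- model$params
  act <- arch$activation
  ids <- arch$ids
  obs <- setdiff(ids, missing)
  if (!length(obs)) stop("all modalities are missing; cannot evaluate the loss")
  nobs <- length(obs)
  B <- batch$n
  if (B < 1L) stop("empty batch")
  mt <- min(weights$m, batch$m)
  A <- params$A
  lam_r <- weights$lambda_recon; lam_p <- weights$lambda_predict
  lam_l <- weights$lambda_linear; lam_m <- weights$lambda_modality
  lam_g <- weights$lambda_reg

  grads <- if (want_grad) lapply(params, .zeros_like) else NULL
  add_g <- function(g) {
    for (nm in names(g)) grads[[nm]] <<- grads[[nm]] + g[[nm]]
  }

  # --- encoders at time k (observed only)
  enc0 <- lapply(obs, function(id)
    .mlp_forward(params, paste0("enc_", id), batch$x0[[id]], act, keep = want_grad))
  names(enc0) <- obs
  Y0 <- lapply(enc0, function(cc) if (want_grad) cc$out else cc)
  ybar <- Reduce(`+`, Y0) / if (divisor == "observed") nobs else length(ids)

  per_mod <- matrix(0, length(ids), 3,
                    dimnames = list(ids, c("recon", "predict", "linear")))

  # --- reconstruction
  recon <- 0
  dec0 <- list()
  for (id in obs) {
    cc <- .mlp_forward(params, paste0("dec_", id), Y0[[id]], act, keep = want_grad)
    out <- if (want_grad) cc$out else cc
    R <- out - batch$x0_clean[[id]]
    per_mod[id, "recon"] <- sum(R * R) / B
    recon <- recon + sum(R * R)
    dec0[[id]] <- list(cache = cc, R = R)
  }
  recon <- recon / (B * nobs)

  # --- fused rollout z_j = A^j ybar and prediction term
  predict <- 0
  zs <- vector("list", mt + 1L); zs[[1L]] <- ybar
  decP <- list()
  if (mt >= 1L && !is.null(batch$xj)) {
    for (j in seq_len(mt)) zs[[j + 1L]] <- A %*% zs[[j]]
    for (id in ids) {
      decP[[id]] <- vector("list", mt)
      for (j in seq_len(mt)) {
        cc <- .mlp_forward(params, paste0("dec_", id), zs[[j + 1L]], act, keep = want_grad)
        out <- if (want_grad) cc$out else cc
        E <- out - batch$xj[[id]][[j]]
        per_mod[id, "predict"] <- per_mod[id, "predict"] + sum(E * E) / (mt * B)
        predict <- predict + sum(E * E)
        decP[[id]][[j]] <- list(cache = cc, E = E)
      }
    }
    predict <- predict / (mt * B)
  }

  # --- per-modality latent rollout and linearity term
  linear <- 0
  encJ <- list(); wchain <- list()
  if (mt >= 1L && !is.null(batch$xj)) {
    for (id in obs) {
      encJ[[id]] <- vector("list", mt)
      w <- vector("list", mt + 1L); w[[1L]] <- Y0[[id]]
      S <- vector("list", mt)
      for (j in seq_len(mt)) {
        w[[j + 1L]] <- A %*% w[[j]]
        cc <- .mlp_forward(params, paste0("enc_", id), batch$xj[[id]][[j]], act,
                           keep = want_grad)
        out <- if (want_grad) cc$out else cc
        S[[j]] <- out - w[[j + 1L]]
        per_mod[id, "linear"] <- per_mod[id, "linear"] + sum(S[[j]]^2) / (mt * B)
        linear <- linear + sum(S[[j]]^2)
        encJ[[id]][[j]] <- cc
      }
      wchain[[id]] <- list(w = w, S = S)
    }
    linear <- linear / (mt * B)
  }

  # --- modality (center) term
  modality <- 0
  Cres <- list()
  for (id in obs) {
    Cl <- ybar - Y0[[id]]
    modality <- modality + sum(Cl * Cl)
    Cres[[id]] <- Cl
  }
  modality <- modality / (B * nobs)

  reg <- .weight_norm2(params)
  total <- lam_r * (recon + lam_p * predict) + lam_l * linear +
    lam_m * modality + lam_g * reg

  report <- list(recon = recon, predict = predict, linear = linear,
                 modality = modality, reg = reg, total = total,
                 per_modality = per_mod, n = B, m = mt)

  if (!want_grad) return(list(report = report))

  fr <- 2 * lam_r / (B * nobs)
  fp <- 2 * lam_r * lam_p / (max(1L, mt) * B)
  fl <- 2 * lam_l / (max(1L, mt) * B)
  fm <- 2 * lam_m / (B * nobs)

  dY0 <- lapply(Y0, function(y) array(0, dim(y)))
  dz <- lapply(zs, function(z) array(0, dim(z)))

  # reconstruction path
  for (id in obs) {
    bk <- .mlp_backward(params, paste0("dec_", id), dec0[[id]]$cache,
                        fr * dec0[[id]]$R, act)
    add_g(bk$grads)
    dY0[[id]] <- dY0[[id]] + bk$dX
  }

  # prediction path: decoders -> dz_j, then back down the A-chain
  if (mt >= 1L && length(decP)) {
    for (id in ids) {
      for (j in seq_len(mt)) {
        bk <- .mlp_backward(params, paste0("dec_", id), decP[[id]][[j]]$cache,
                            fp * decP[[id]][[j]]$E, act)
        add_g(bk$grads)
        dz[[j + 1L]] <- dz[[j + 1L]] + bk$dX
      }
    }
    for (j in rev(seq_len(mt))) {
      grads$A <- grads$A + dz[[j + 1L]] %*% t(zs[[j]])
      dz[[j]] <- dz[[j]] + t(A) %*% dz[[j + 1L]]
    }
    dfuse <- dz[[1L]] / if (divisor == "observed") nobs else length(ids)
    for (id in obs) dY0[[id]] <- dY0[[id]] + dfuse
  }

  # linearity path
  if (mt >= 1L && length(wchain)) {
    for (id in obs) {
      w <- wchain[[id]]$w; S <- wchain[[id]]$S
      dw <- lapply(w, function(x) array(0, dim(x)))
      for (j in seq_len(mt)) {
        bk <- .mlp_backward(params, paste0("enc_", id), encJ[[id]][[j]],
                            fl * S[[j]], act)
        add_g(bk$grads)
        dw[[j + 1L]] <- dw[[j + 1L]] - fl * S[[j]]
      }
      for (j in rev(seq_len(mt))) {
        grads$A <- grads$A + dw[[j + 1L]] %*% t(w[[j]])
        dw[[j]] <- dw[[j]] + t(A) %*% dw[[j + 1L]]
      }
      dY0[[id]] <- dY0[[id]] + dw[[1L]]
    }
  }

  # modality (center) path — the fused-state part cancels exactly because the
  # residuals sum to zero over observed modalities.
  for (id in obs) dY0[[id]] <- dY0[[id]] - fm * Cres[[id]]

  # encoders at time k
  for (id in obs) {
    bk <- .mlp_backward(params, paste0("enc_", id), enc0[[id]], dY0[[id]], act)
    add_g(bk$grads)
  }

  # l2 regularization on weights (biases excluded)
  if (lam_g > 0) {
    nm <- names(params)
    keep <- nm == "A" | grepl("_W[0-9]$", nm)
    for (w in nm[keep]) grads[[w]] <- grads[[w]] + 2 * lam_g * params[[w]]
  }

  list(report = report, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# zero object with the same shape as x (vectors stay plain vectors so that
# matrix-plus-bias recycling keeps working after optimizer updates)
.zeros_like <- function(x) if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))

#' Reconstruction loss
#'
#' Mean, over batch samples and non-missing modalities, of the squared L2
#' distance between each input and its `decode(encode(.))` reconstruction.
#' Masked modalities contribute no terms.
#'
#' @param object a `kmmae_model` or fitted `kmmae`.
#' @param batch a [kmmae_batch()] or the output of [make_training_windows()].
#' @param missing character vector of masked modality ids.
#' @return a nonnegative scalar.
#' @export
recon_loss <- function(object, batch, missing = character()) {
  model <- .model_of(object)
  .kmmae_grad(model, .as_batch(batch), loss_weights(m = max(1L, batch$m)),
              missing, want_grad = FALSE)$report$recon
}

#' Multi-step prediction loss
#'
#' `(1/m) * mean over batch of sum_l sum_{j=1..m}
#'  || x_l(k+j) - decode_l(A^j ybar(k)) ||^2`, where `ybar(k)` is the fused
#' latent state of the non-missing modalities.  Propagating the fused state —
#' rather than each modality's own encoding — is what trains the decoders of
#' masked modalities and makes cross-modal restoration possible.
#'
#' @inheritParams recon_loss
#' @param m horizon; defaults to the batch's target depth.
#' @return a nonnegative scalar.
#' @export
predict_loss <- function(object, batch, m = batch$m, missing = character()) {
  if (batch$m < 1L) stop("batch carries no multi-step targets")
  if (m > batch$m) stop("window supplies only ", batch$m, " target steps, need ", m)
  model <- .model_of(object)
  .kmmae_grad(model, .as_batch(batch), loss_weights(m = m), missing,
              want_grad = FALSE)$report$predict
}

#' Linear-dynamics (Koopman consistency) loss
#'
#' `(1/m) * mean over batch of sum_l sum_{j=1..m}
#'  || encode_l(x_l(k+j)) - A^j encode_l(x_l(k)) ||^2`, computed per modality
#' in latent space.  Driving this to zero makes the latent trajectory evolve
#' linearly under `A`.
#'
#' @inheritParams predict_loss
#' @return a nonnegative scalar.
#' @export
linear_loss <- function(object, batch, m = batch$m, missing = character()) {
  if (batch$m < 1L) stop("batch carries no multi-step targets")
  if (m > batch$m) stop("window supplies only ", batch$m, " target steps, need ", m)
  model <- .model_of(object)
  .kmmae_grad(model, .as_batch(batch), loss_weights(m = m), missing,
              want_grad = FALSE)$report$linear
}

#' Modality (center) loss
#'
#' Mean over non-missing modalities (and samples) of the squared distance
#' between each modality's encoding and the fused center — the penalty that
#' pulls all encoders towards one shared latent trajectory.
#'
#' @param encodings named list of latent `p`-vectors or K x p matrices.
#' @param missing character vector of modality ids to exclude.
#' @return a nonnegative scalar.
#' @export
modality_loss <- function(encodings, missing = character()) {
  keep <- setdiff(names(encodings), missing)
  if (!length(keep)) stop("all modalities are missing")
  enc <- lapply(encodings[keep], function(y)
    if (is.null(dim(y))) matrix(as.numeric(y), ncol = 1) else t(as.matrix(y)))
  B <- ncol(enc[[1L]])
  center <- Reduce(`+`, enc) / length(enc)
  sum(vapply(enc, function(y) sum((center - y)^2), numeric(1))) / (B * length(enc))
}

#' Combine loss components into the weighted objective
#'
#' @param components named list (or `LossReport`) with elements `recon`,
#'   `predict`, `linear`, `modality` and optionally `reg`.
#' @param weights a [loss_weights()].
#' @param params optional parameter list; when supplied, `reg` is recomputed
#'   as the sum of squared weight entries (biases excluded).
#' @return a `loss_report`: the components plus `total`.
#' @export
total_loss <- function(components, weights, params = NULL) {
  if (!inherits(weights, "loss_weights")) stop("'weights' must be a loss_weights object")
  reg <- if (!is.null(params)) .weight_norm2(params) else components$reg %||% 0
  total <- weights$lambda_recon * (components$recon + weights$lambda_predict * components$predict) +
    weights$lambda_linear * components$linear +
    weights$lambda_modality * components$modality +
    weights$lambda_reg * reg
  structure(list(recon = components$recon, predict = components$predict,
                 linear = components$linear, modality = components$modality,
                 reg = reg, total = total,
                 per_modality = components$per_modality),
            class = "loss_report")
}

#' Evaluate the full loss report on a batch
#'
#' @inheritParams recon_loss
#' @param weights a [loss_weights()].
#' @return a `loss_report` with all components, the weighted total and a
#'   per-modality breakdown.
#' @export
kmmae_loss <- function(object, batch, weights = loss_weights(),
                       missing = character()) {
  model <- .model_of(object)
  rep <- .kmmae_grad(model, .as_batch(batch), weights, missing,
                     want_grad = FALSE)$report
  structure(rep, class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("loss: total %.6g  (recon %.4g, predict %.4g, linear %.4g, modality %.4g, reg %.4g)\n",
              x$total, x$recon, x$predict, x$linear, x$modality, x$reg))
  invisible(x)
}

.as_batch <- function(batch) {
  if (inherits(batch, "kmmae_batch")) return(batch)
  if (inherits(batch, "kmmae_windows")) return(.windows_to_batch(batch))
  stop("expected a 'kmmae_batch' or 'kmmae_windows' object")
}
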