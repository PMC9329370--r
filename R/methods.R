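#' @export
print.kmmae <- function(x, ...) {
  cat("Koopman multi-modal auto-encoder fit\n")
  cat(sprintf("  modalities: %s\n", paste(names(x$standardizers), collapse = ", ")))
  cat(sprintf("  joint width p = %d, hidden %s, %s hidden activation\n",
              x$config$p, paste(x$config$hidden, collapse = "/"),
              x$config$activation))
  cat(sprintf("  embedding: d = {%s}, tau = {%s}\n",
              paste(x$embedding$d, collapse = ", "),
              paste(x$embedding$tau, collapse = ", ")))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs; best validation total %.5g at epoch %d\n",
                nrow(x$history), x$best_val, x$best_epoch))
  } else cat("  untrained (0 epochs)\n")
  cat(sprintf("  spectral radius of A: %.4f\n",
              koopman_spectrum(x)$spectral_radius))
  invisible(x)
}

#' Summarize a fitted Koopman multi-modal auto-encoder
#'
#' Reports the validation loss components at the best epoch, the per-modality
#' reconstruction RMSE on the held-out test range (original units) and the
#' leading eigenvalues of the learned propagator.
#'
#' @param object a fitted [kmmae()] model.
#' @param ... unused.
#' @return an object of class `summary.kmmae`.
#' @export
summary.kmmae <- function(object, ...) {
  ids <- names(object$standardizers)
  dat <- .default_eval_data(object)
  rec <- predict(object, type = "reconstruct")
  test_rmse <- vapply(ids, function(id) {
    ks <- attr(rec[[id]], "k")
    keep <- if (isTRUE(object$session_mode)) rep(TRUE, length(ks))
    else ks %in% object$split$test
    if (!any(keep)) return(NA_real_)
    rmse(dat[[id]]$values[ks[keep], , drop = FALSE],
         rec[[id]]$values[keep, , drop = FALSE])
  }, numeric(1))
  best <- if (nrow(object$history))
    object$history[object$history$epoch == object$best_epoch, ] else NULL
  structure(list(fit = object, test_rmse = test_rmse, best = best,
                 spectrum = koopman_spectrum(object)),
            class = "summary.kmmae")
}

#' @export
print.summary.kmmae <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$best)) {
    cat("\nValidation loss components at best epoch:\n")
    print(signif(unlist(x$best[c("val_recon", "val_predict", "val_linear",
                                 "val_modality", "val_reg", "val_total")]), 4))
  }
  cat("\nTest reconstruction RMSE (original units):\n")
  print(signif(x$test_rmse, 4))
  cat("\nLeading eigenvalues of A:\n")
  print(signif(utils::head(x$spectrum$eigenvalues, 5), 5))
  invisible(x)
}

#' @export
coef.kmmae <- function(object, ...) object$model$params$A

#' Predict from a fitted Koopman multi-modal auto-encoder
#'
#' * `type = "reconstruct"` — encode, fuse and decode every modality over the
#'   aligned range of `newdata` (default: the training data), returning
#'   reconstructions in original units.
#' * `type = "rollout"` — open-loop multi-step prediction through the linear
#'   propagator; see [rollout_predict()].
#' * `type = "restore"` — restore the modalities named in `missing` from the
#'   others; see [restore_missing()].
#'
#' @param object a fitted [kmmae()] model.
#' @param newdata named list of [modal_series()] (default: the fitting data).
#' @param type prediction mode.
#' @param horizon rollout horizon (`type = "rollout"`).
#' @param missing modalities to restore (`type = "restore"`).
#' @param from source index to roll out from (`type = "rollout"`).
#' @param ... unused.
#' @return reconstructions/restorations as named lists of [modal_series()]
#'   (with attribute `"k"` giving source indices), or per-modality prediction
#'   matrices for rollouts.
#' @export
predict.kmmae <- function(object, newdata = NULL,
                          type = c("reconstruct", "rollout", "restore"),
                          horizon = 1L, missing = NULL, from = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- .default_eval_data(object)
  if (type == "rollout")
    return(rollout_predict(object, newdata, horizon = horizon, from = from))
  if (type == "restore") {
    if (is.null(missing)) stop("type = 'restore' needs 'missing'")
    return(restore_missing(object, newdata, missing))
  }
  ids <- intersect(names(object$standardizers), names(newdata))
  emb <- .prepare_embedded(object, newdata, ids)
  fs <- .fused_states(object, emb, ids)
  out <- lapply(ids, function(id) {
    dec <- decode(object, id, t(fs$ybar))
    C <- length(object$standardizers[[id]]$mean)
    v <- unstandardize(.current_block(dec, C), object$standardizers[[id]])
    structure(modal_series(v, id, sample_rate = newdata[[id]]$sample_rate %||% 1),
              k = fs$ks)
  })
  names(out) <- ids
  out
}

#' @export
fitted.kmmae <- function(object, ...) predict(object, type = "reconstruct")

#' @export
residuals.kmmae <- function(object, ...) {
  dat <- .default_eval_data(object)
  rec <- predict(object, type = "reconstruct")
  out <- lapply(names(rec), function(id) {
    ks <- attr(rec[[id]], "k")
    dat[[id]]$values[ks, , drop = FALSE] - rec[[id]]$values
  })
  names(out) <- names(rec)
  out
}

# Default data for methods: the recording itself, or (session mode) the first
# held-out test session.
.default_eval_data <- function(object) {
  if (isTRUE(object$session_mode)) object$data[[object$split$test[1L]]]
  else object$data
}

#' Simulate modality trajectories from the learned linear dynamics
#'
#' Fuses the latent state at `from` (default: the last embedded index of the
#' fitting data), rolls it forward under `A` and decodes every modality —
#' i.e. draws what the learned shared dynamics predicts the system will do
#' next.  With `nsim > 1`, independent white observation noise at the fit's
#' training SNR is added to each replicate (no noise when the fit was trained
#' without augmentation).
#'
#' @param object a fitted [kmmae()] model.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param horizon steps to simulate.
#' @param from source index to start from.
#' @param ... unused.
#' @return list of `nsim` simulations; each is a named list of per-modality
#'   `horizon` x C matrices in original units.
#' @export
simulate.kmmae <- function(object, nsim = 1, seed = NULL, horizon = 20L,
                           from = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- rollout_predict(object, .default_eval_data(object), horizon = horizon,
                          from = from)
  snr <- object$config$snr_db
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    out[[i]] <- if (is.finite(snr) && i > 1L)
      lapply(base, function(v) tryCatch(add_noise_snr(v, snr), error = function(e) v))
    else base
  }
  out
}

#' Plot training history and Koopman spectrum
#'
#' Two panels: training/validation total loss per epoch (log scale) and the
#' eigenvalues of the learned propagator in the complex plane with the unit
#' circle (eigenvalues inside the circle are decaying latent modes, on it
#' oscillatory, outside unstable).
#'
#' @param x a fitted [kmmae()] model.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kmmae <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (nrow(x$history)) {
    graphics::plot(x$history$epoch, x$history$train_total, type = "l",
                   log = "y", xlab = "epoch", ylab = "total loss",
                   main = "training history", ...)
    graphics::lines(x$history$epoch, x$history$val_total, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  } else {
    graphics::plot.new(); graphics::title("untrained model")
  }
  ev <- koopman_spectrum(x)$eigenvalues
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::plot(cos(th), sin(th), type = "l", col = "grey", asp = 1,
                 xlab = "Re", ylab = "Im", main = "spectrum of A")
  graphics::points(Re(ev), Im(ev), pch = 19)
  invisible(x)
}
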