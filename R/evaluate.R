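#' Root mean square error
#'
#' `sqrt(mean((truth - estimate)^2))` over all channels and time steps.
#'
#' @param truth,estimate [modal_series()] objects or numeric arrays of equal
#'   shape.
#' @return a nonnegative scalar.
#' @export
rmse <- function(truth, estimate) {
  a <- .series_values(truth); b <- .series_values(estimate)
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  sqrt(mean((a - b)^2))
}

# Standardize + embed new series with a fit's parameters; returns the
# embedded list restricted to the given modalities.
.prepare_embedded <- function(fit, data, ids = names(fit$standardizers)) {
  stopifnot(inherits(fit, "kmmae"))
  missing_ids <- setdiff(ids, names(data))
  if (length(missing_ids))
    stop("data lacks modalities: ", paste(missing_ids, collapse = ", "))
  out <- lapply(ids, function(id) {
    s <- data[[id]]
    v <- standardize(.series_values(s), fit$standardizers[[id]])
    delay_embed(modal_series(v, id), fit$embedding$d[[id]], fit$embedding$tau[[id]])
  })
  names(out) <- ids
  out
}

# Align embedded series on the shared source index; returns list(ks, rows)
# where rows[[id]] maps each k to the modality's embedded row.
.align_embedded <- function(embedded) {
  Ts <- vapply(embedded, function(e) e$origin_index + nrow(e$vectors) - 1L, integer(1))
  if (length(unique(Ts)) != 1L) stop("modalities have different source lengths")
  origin <- max(vapply(embedded, `[[`, integer(1), "origin_index"))
  ks <- seq.int(origin, Ts[[1L]])
  rows <- lapply(embedded, function(e) ks - e$origin_index + 1L)
  list(ks = ks, rows = rows)
}

# Fused latent states (p x K) from the observed modalities of embedded data.
.fused_states <- function(fit, embedded, observed = names(embedded)) {
  al <- .align_embedded(embedded[observed])
  enc <- lapply(observed, function(id)
    t(encode(fit, id, embedded[[id]]$vectors[al$rows[[id]], , drop = FALSE])))
  names(enc) <- observed
  list(ks = al$ks, ybar = Reduce(`+`, enc) / length(enc), enc = enc)
}

# First lag block (current sample) of an embedded row matrix -> T x C values.
.current_block <- function(x, channels) x[, seq_len(channels), drop = FALSE]

#' Restore missing modalities from the observed ones
#'
#' Encodes the observed modalities, fuses them into the shared latent state
#' and decodes each missing modality from it, then inverts the
#' standardization.  The restored values depend only on the observed
#' modalities — whatever is stored in the masked series never enters the
#' network.  Any number of modalities can be restored at once as long as at
#' least one is observed.
#'
#' @param fit a fitted [kmmae()] model.
#' @param data named list of [modal_series()] (original units) holding at
#'   least the observed modalities.
#' @param missing character vector of modality ids to restore.
#' @return named list of restored [modal_series()], one per missing modality,
#'   aligned to the shared embedded time range (attribute `"k"` carries the
#'   source indices).
#' @export
restore_missing <- function(fit, data, missing) {
  stopifnot(inherits(fit, "kmmae"))
  all_ids <- names(fit$standardizers)
  missing <- intersect(all_ids, missing)
  observed <- setdiff(intersect(all_ids, names(data)), missing)
  if (!length(observed)) stop("all modalities are missing; cannot restore")
  emb <- .prepare_embedded(fit, data[observed], observed)
  fs <- .fused_states(fit, emb, observed)
  out <- lapply(missing, function(id) {
    dec <- decode(fit, id, t(fs$ybar))
    C <- length(fit$standardizers[[id]]$mean)
    v <- unstandardize(.current_block(dec, C), fit$standardizers[[id]])
    structure(modal_series(v, id,
                           sample_rate = fit$data[[id]]$sample_rate %||% 1),
              k = fs$ks)
  })
  names(out) <- missing
  out
}

#' Open-loop multi-step prediction through the linear propagator
#'
#' Fuses the latent state at source index `from`, advances it with `A^j` for
#' `j = 1..horizon` and decodes every modality at each step — no re-encoding
#' of predictions (fully open-loop, all dynamics carried by `A`).
#'
#' @param fit a fitted [kmmae()] model.
#' @param data named list of [modal_series()] in original units.
#' @param horizon number of steps ahead (>= 1).
#' @param from source index at which to fuse (default: last available).
#' @param observed modalities used for fusion (default all present).
#' @return named list: per modality a `horizon` x C matrix of predicted
#'   values in original units (row `j` is the prediction for `from + j`).
#' @export
rollout_predict <- function(fit, data, horizon, from = NULL, observed = NULL) {
  stopifnot(inherits(fit, "kmmae"))
  if (horizon < 1L) stop("'horizon' must be >= 1")
  all_ids <- names(fit$standardizers)
  if (is.null(observed)) observed <- intersect(all_ids, names(data))
  emb <- .prepare_embedded(fit, data, observed)
  fs <- .fused_states(fit, emb, observed)
  if (is.null(from)) from <- fs$ks[length(fs$ks)]
  i <- match(from, fs$ks)
  if (is.na(i)) stop("'from' must be an embedded source index in [",
                     fs$ks[1], ", ", fs$ks[length(fs$ks)], "]")
  y <- fs$ybar[, i]
  A <- fit$model$params$A
  out <- lapply(all_ids, function(id)
    matrix(NA_real_, horizon, length(fit$standardizers[[id]]$mean)))
  names(out) <- all_ids
  for (j in seq_len(as.integer(horizon))) {
    y <- as.numeric(A %*% y)
    for (id in all_ids) {
      dec <- decode(fit, id, y)
      C <- length(fit$standardizers[[id]]$mean)
      out[[id]][j, ] <- unstandardize(matrix(dec[seq_len(C)], 1), fit$standardizers[[id]])
    }
  }
  out
}

#' Per-time-step reconstruction and prediction loss traces
#'
#' For every aligned source index `k` of a segment, computes `loss1(k)` — the
#' reconstruction loss at `k` — and `loss2(k)` — the `horizon`-step-ahead
#' prediction loss landing at `k` (decoded from the fused state at
#' `k - horizon`), per modality on the standardized scale.  A spike in these
#' traces marks a departure from the dynamics the model was trained on, which
#' is how stimulus reaction times are detected.
#'
#' @param fit a fitted [kmmae()] model.
#' @param data named list of [modal_series()] covering the segment (original
#'   units).
#' @param horizon prediction horizon for `loss2` (default 1 step).
#' @return object of class `kmmae_trace`: list with `k` (source indices),
#'   `loss1`, `loss2` (K x L matrices, one column per modality).  The first
#'   `horizon` entries of `loss2` are `NA` (no prediction lands there).
#' @export
loss_trace <- function(fit, data, horizon = 1L) {
  stopifnot(inherits(fit, "kmmae"))
  horizon <- as.integer(horizon)
  ids <- intersect(names(fit$standardizers), names(data))
  emb <- .prepare_embedded(fit, data, ids)
  fs <- .fused_states(fit, emb, ids)
  K <- length(fs$ks)
  if (K <= horizon)
    stop("segment too short: ", K, " embedded steps for horizon ", horizon)
  al <- .align_embedded(emb)
  loss1 <- loss2 <- matrix(NA_real_, K, length(ids), dimnames = list(NULL, ids))
  A <- fit$model$params$A
  Aj <- diag(nrow(A))
  for (j in seq_len(horizon)) Aj <- A %*% Aj
  for (id in ids) {
    X <- emb[[id]]$vectors[al$rows[[id]], , drop = FALSE]
    rec <- decode(fit, id, t(fs$ybar))
    loss1[, id] <- rowSums((rec - X)^2)
    pred_states <- Aj %*% fs$ybar[, seq_len(K - horizon), drop = FALSE]
    prd <- decode(fit, id, t(pred_states))
    loss2[seq.int(horizon + 1L, K), id] <-
      rowSums((prd - X[seq.int(horizon + 1L, K), , drop = FALSE])^2)
  }
  structure(list(k = fs$ks, loss1 = loss1, loss2 = loss2, horizon = horizon,
                 ids = ids),
            class = "kmmae_trace")
}

#' @export
print.kmmae_trace <- function(x, ...) {
  cat(sprintf("<kmmae_trace>  %d steps (k = %d..%d), horizon %d, modalities: %s\n",
              length(x$k), x$k[1], x$k[length(x$k)], x$horizon,
              paste(x$ids, collapse = ", ")))
  invisible(x)
}

#' Assemble an event trace around a stimulus
#'
#' Pairs aligned reconstruction (`loss1`) and prediction (`loss2`) loss series
#' with a stimulus index and computes the per-series pre-stimulus baselines
#' (the two losses have different scales, so each gets its own baseline).
#'
#' @param loss1,loss2 numeric loss series aligned on the same time base
#'   (leading `NA`s in `loss2` are tolerated).
#' @param stimulus_index index (into the series) of the stimulus; the
#'   baseline is the mean over steps strictly before it.
#' @param time optional vector of source indices (defaults to `1:length`).
#' @return object of class `event_trace`.
#' @seealso [detect_reaction_time()]
#' @export
event_trace <- function(loss1, loss2, stimulus_index, time = seq_along(loss1)) {
  if (length(loss1) != length(loss2)) stop("loss series must be aligned")
  stimulus_index <- as.integer(stimulus_index)
  if (stimulus_index <= 1L) stop("'stimulus_index' must leave a pre-stimulus window")
  pre <- seq_len(stimulus_index - 1L)
  b1 <- mean(loss1[pre], na.rm = TRUE)
  b2 <- mean(loss2[pre], na.rm = TRUE)
  if (!is.finite(b1) || !is.finite(b2))
    stop("empty pre-stimulus window: cannot compute baselines")
  structure(list(loss1 = loss1, loss2 = loss2, time = time,
                 stimulus_index = stimulus_index,
                 baseline1 = b1, baseline2 = b2),
            class = "event_trace")
}

#' Detect the reaction time from loss spikes
#'
#' The reaction index is the first time at (or after) the stimulus at which
#' both the reconstruction and the prediction loss stay above `ratio` times
#' their respective pre-stimulus baselines for `consec_len` consecutive
#' steps; the start of that qualifying window is reported.  Returns `NA` when
#' no such window exists.  Pre-stimulus exceedances are reported as a
#' data-quality warning rather than detections.  Raising `ratio` can never
#' yield an earlier reaction index.
#'
#' @param trace an [event_trace()].
#' @param ratio threshold ratio applied to both baselines (published settings:
#'   1.5 for EEG, 4 for EMG).
#' @param consec_len required consecutive exceedance length (published: 3).
#' @return the reaction index (position in the trace), or `NA_integer_`;
#'   attribute `"time"` carries the corresponding source index.
#' @export
detect_reaction_time <- function(trace, ratio, consec_len = 3L) {
  stopifnot(inherits(trace, "event_trace"))
  consec_len <- as.integer(consec_len)
  if (consec_len < 1L) stop("'consec_len' must be >= 1")
  if (ratio <= 0) stop("'ratio' must be positive")
  hit <- trace$loss1 > ratio * trace$baseline1 &
    trace$loss2 > ratio * trace$baseline2
  hit[is.na(hit)] <- FALSE
  n <- length(hit)
  pre <- seq_len(trace$stimulus_index - 1L)
  if (any(hit[pre]))
    warning("loss exceedances before the stimulus: baselines may be unreliable")
  for (t in seq.int(trace$stimulus_index, n)) {
    if (t + consec_len - 1L > n) break
    if (all(hit[seq.int(t, t + consec_len - 1L)]))
      return(structure(t, time = trace$time[t]))
  }
  NA_integer_
}

#' Least-squares linear propagator (DMD / EDMD)
#'
#' Fits `A` minimizing `|| Psi(x(k+1)) - A Psi(x(k)) ||^2` over a trajectory,
#' by QR least squares — dynamic mode decomposition when `dictionary` is the
#' identity, extended DMD otherwise.  This closed-form estimator shares no
#' code with the trained network and serves as the independent oracle for the
#' linear and exactly-embeddable regimes.
#'
#' @param x T x n trajectory matrix (rows = time).
#' @param dictionary optional function mapping a T x n matrix to a T x q
#'   feature matrix (default identity).
#' @return list with `A` (q x q), `eigenvalues` (sorted by modulus,
#'   descending) and `residual_rmse` (one-step, in dictionary space).
#' @export
edmd <- function(x, dictionary = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two time steps")
  Psi <- if (is.null(dictionary)) x else as.matrix(dictionary(x))
  G0 <- Psi[-nrow(Psi), , drop = FALSE]
  G1 <- Psi[-1L, , drop = FALSE]
  At <- qr.solve(G0, G1)        # G1 ~ G0 %*% At, so A = t(At)
  A <- t(At)
  res <- G1 - G0 %*% At
  ev <- eigen(A, only.values = TRUE)$values
  list(A = A, eigenvalues = ev[order(Mod(ev), decreasing = TRUE)],
       residual_rmse = sqrt(mean(res^2)))
}

#' @rdname edmd
#' @export
dmd <- function(x) edmd(x)
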