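#' Split sessions or a time range into train/validation/test
#'
#' `mode = "random"` shuffles whole sessions into the three sets with the
#' given fractions (default 0.8/0.1/0.1), guaranteeing at least one session in
#' validation and test; when condition `labels` are supplied the split is
#' stratified so that every set contains at least one session of every
#' condition.  `mode = "temporal"` cuts a single recording of length
#' `sessions` (an integer) at the stated fractions in time order (default
#' 0.7/0.1/0.2): the first block is training, then validation, then test.
#'
#' @param sessions either a count/list of sessions (`mode = "random"`) or the
#'   number of time steps (`mode = "temporal"`).
#' @param mode `"random"` or `"temporal"`.
#' @param fractions length-3 numeric summing to 1; defaults depend on mode.
#' @param labels optional condition label per session (random mode).
#' @param seed integer seed (random mode).
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(sessions, mode = c("random", "temporal"),
                          fractions = NULL, labels = NULL, seed = NULL) {
  mode <- match.arg(mode)
  n <- if (length(sessions) == 1L && is.numeric(sessions)) as.integer(sessions) else length(sessions)
  if (is.null(fractions))
    fractions <- if (mode == "random") c(0.8, 0.1, 0.1) else c(0.7, 0.1, 0.2)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must be three numbers summing to 1")
  if (mode == "temporal") {
    n_train <- floor(n * fractions[1L])
    n_val <- floor(n * (fractions[1L] + fractions[2L])) - n_train
    if (n_train < 1L || n_val < 1L || n_train + n_val >= n)
      stop("series too short for temporal fractions ", paste(fractions, collapse = "/"))
    return(list(train = seq_len(n_train),
                val = n_train + seq_len(n_val),
                test = seq.int(n_train + n_val + 1L, n)))
  }
  if (n < 3L) stop("random splitting needs at least 3 sessions")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("'labels' must have one entry per session")
    bad <- names(which(table(labels) < 3L))
    if (length(bad))
      stop("stratification infeasible: condition(s) with fewer than 3 sessions: ",
           paste(bad, collapse = ", "))
    out <- list(train = integer(), val = integer(), test = integer())
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      k <- length(idx)
      n_test <- max(1L, round(k * fractions[3L]))
      n_val <- max(1L, round(k * fractions[2L]))
      out$test <- c(out$test, idx[seq_len(n_test)])
      out$val <- c(out$val, idx[n_test + seq_len(n_val)])
      out$train <- c(out$train, idx[-seq_len(n_test + n_val)])
    }
    return(lapply(out, sort))
  }
  idx <- sample(n)
  n_test <- max(1L, round(n * fractions[3L]))
  n_val <- max(1L, round(n * fractions[2L]))
  list(train = sort(idx[-seq_len(n_test + n_val)]),
       val = sort(idx[n_test + seq_len(n_val)]),
       test = sort(idx[seq_len(n_test)]))
}

#' Build aligned multi-step training windows
#'
#' Emits, for every shared source index `k` with complete history and complete
#' `m`-step targets across all modalities, the embedded input `x_l(k)` and the
#' targets `x_l(k+1) .. x_l(k+m)`.  All modalities are aligned on the shared
#' source time index even when their `(d, tau)` differ.
#'
#' @param embedded named list of [delay_embed()] results built from aligned,
#'   equal-length source series.
#' @param m target horizon (>= 1).
#' @param k_range optional `c(lo, hi)`: keep only windows whose full span —
#'   embedding history through `k + m` — lies inside this source-index range
#'   (used to keep train/validation windows disjoint).
#' @return object of class `kmmae_windows` with `n` windows.
#' @export
make_training_windows <- function(embedded, m, k_range = NULL) {
  if (!length(embedded) || is.null(names(embedded)))
    stop("'embedded' must be a named list of delay-embedded series")
  ok <- vapply(embedded, inherits, logical(1), "delay_embedded")
  if (!all(ok)) stop("all entries must be delay_embedded objects")
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  Ts <- vapply(embedded, function(e) e$origin_index + nrow(e$vectors) - 1L, integer(1))
  if (length(unique(Ts)) != 1L)
    stop("embedded series come from sources of different lengths: ",
         paste(Ts, collapse = ", "))
  Tn <- Ts[[1L]]
  origin <- max(vapply(embedded, `[[`, integer(1), "origin_index"))
  k_lo <- origin; k_hi <- Tn - m
  if (!is.null(k_range)) {
    k_lo <- max(k_lo, k_range[1L] + origin - 1L)
    k_hi <- min(k_hi, k_range[2L] - m)
  }
  if (k_hi < k_lo)
    stop("no complete windows: series of length ", Tn, " with embedding origin ",
         origin, " cannot supply m = ", m, " target steps",
         if (!is.null(k_range)) " inside the requested range" else "")
  ks <- seq.int(k_lo, k_hi)
  x0 <- list(); xj <- list()
  for (id in names(embedded)) {
    e <- embedded[[id]]
    row <- function(k) k - e$origin_index + 1L
    x0[[id]] <- t(e$vectors[row(ks), , drop = FALSE])
    xj[[id]] <- lapply(seq_len(m), function(j) t(e$vectors[row(ks + j), , drop = FALSE]))
  }
  structure(list(x0 = x0, xj = xj, m = m, ids = names(embedded),
                 n = length(ks), k = ks),
            class = "kmmae_windows")
}

#' @export
print.kmmae_windows <- function(x, ...) {
  cat(sprintf("<kmmae_windows>  %d windows, m = %d, modalities: %s\n",
              x$n, x$m, paste(x$ids, collapse = ", ")))
  invisible(x)
}

# Column-bind windows from several sessions into one pool.
.concat_windows <- function(ws) {
  ws <- ws[lengths(ws) > 0]
  if (!length(ws)) stop("no windows to pool")
  if (length(ws) == 1L) return(ws[[1L]])
  ids <- ws[[1L]]$ids; m <- ws[[1L]]$m
  x0 <- lapply(ids, function(id) do.call(cbind, lapply(ws, function(w) w$x0[[id]])))
  names(x0) <- ids
  xj <- lapply(ids, function(id) lapply(seq_len(m), function(j)
    do.call(cbind, lapply(ws, function(w) w$xj[[id]][[j]]))))
  names(xj) <- ids
  structure(list(x0 = x0, xj = xj, m = m, ids = ids,
                 n = sum(vapply(ws, `[[`, integer(1), "n")),
                 k = unlist(lapply(ws, `[[`, "k"), use.names = FALSE)),
            class = "kmmae_windows")
}

.windows_to_batch <- function(w, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(w$n)
  x0 <- lapply(w$x0, function(m) m[, idx, drop = FALSE])
  xj <- lapply(w$xj, function(tl) lapply(tl, function(m) m[, idx, drop = FALSE]))
  structure(list(x0 = x0, x0_clean = x0, xj = xj, m = w$m,
                 ids = w$ids, n = length(idx)),
            class = "kmmae_batch")
}

# One Adam update with global-norm gradient clipping.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(clip) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    if (is.null(dim(params[[nm]]))) upd <- as.numeric(upd)
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}

.resolve_embed_par <- function(x, ids, what) {
  if (identical(x, "auto")) return(NULL)
  if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(as.integer(x), length(ids)), ids)
  if (is.null(names(x)) || !all(ids %in% names(x)))
    stop("'", what, "' must be \"auto\", a single value, or named per modality")
  vapply(ids, function(id) as.integer(x[[id]]), integer(1))
}

#' Fit a Koopman multi-modal auto-encoder
#'
#' The main fitting function.  Given aligned modality time series it:
#' standardizes each modality on the training portion of a temporal split
#' (default 0.7/0.1/0.2); selects the time-delay embedding per modality
#' (mutual-information delay and false-nearest-neighbour dimension, or fixed
#' values); builds aligned multi-step windows; and trains the multi-modal
#' auto-encoder of [kmmae_model()] with Adam under the combined objective of
#' [loss_weights()].  Each training batch is augmented with fresh white
#' Gaussian noise at `snr_db` and, with probability `mask_probability`, one
#' uniformly chosen modality is masked with the sentinel: the masked modality
#' is excluded from encoding, fusion and the reconstruction/linearity/center
#' terms, while its decoder keeps learning from the fused latent state — this
#' is what makes missing-modality restoration possible at inference.  The
#' returned fit carries the parameters of the best validation epoch.
#'
#' Everything is a deterministic function of the arguments and `seed`.
#'
#' @param data either one recording — a named list of aligned, equal-length
#'   [modal_series()] — or a list of such sessions.  A single recording is
#'   split temporally (first block train, then validation, then test);
#'   multiple sessions are split randomly whole-session.
#' @param d,tau embedding dimension and delay: `"auto"` (estimated per
#'   modality on the training split), one value for all modalities, or a
#'   named vector.
#' @param p joint (latent) layer width.
#' @param hidden the two hidden-layer widths.
#' @param activation hidden activation, `"relu"` or `"identity"`.
#' @param m prediction/linearity horizon (steps).
#' @param weights a [loss_weights()]; its `m` is taken from the `m` argument.
#' @param epochs maximum training epochs (0 returns the initialized model).
#' @param batch_size windows per Adam step.
#' @param learning_rate Adam learning rate.
#' @param snr_db SNR of the per-batch noise augmentation in dB; `Inf` disables
#'   it.
#' @param mask_probability probability that a batch has one modality masked.
#' @param sentinel sentinel value recorded for masking (the masked modality
#'   never enters an encoder, so the value itself is metadata).
#' @param split train/validation/test fractions: temporal (default
#'   0.7/0.1/0.2) for a single recording, whole-session random (default
#'   0.8/0.1/0.1) in session mode.
#' @param patience early-stopping patience in epochs (validation total).
#' @param grad_clip global-norm gradient clip.
#' @param max_lag,max_d search limits for the automatic embedding selection.
#' @param seed integer seed controlling initialization, batching, noise and
#'   masking.
#' @param verbose print a progress line every 50 epochs.
#' @return an object of class `kmmae`; see [predict.kmmae()],
#'   [restore_missing()], [koopman_spectrum()], [loss_trace()].
#' @examples
#' sys <- latent_system("linear_discrete",
#'                      parameters = list(M = matrix(c(0.98, -0.1, 0.1, 0.98), 2)),
#'                      x0 = c(1, 0))
#' obs <- observation_spec(
#'   modality_spec("a", "identity", channels = 2),
#'   modality_spec("b", list(type = "sinusoidal", frequency = 2), channels = 2))
#' series <- observe_modalities(simulate_latent(sys, 400), obs, seed = 1)
#' fit <- kmmae(series, d = 2, tau = 1, p = 6, m = 2, epochs = 30,
#'              snr_db = Inf, seed = 1)
#' fit
#' @export
kmmae <- function(data, d = "auto", tau = "auto", p = 20L, hidden = c(20L, 15L),
                  activation = c("relu", "identity"), m = 5L,
                  weights = loss_weights(m = m), epochs = 300L, batch_size = 64L,
                  learning_rate = 1e-3, snr_db = 10, mask_probability = 0.5,
                  sentinel = -1, split = c(0.7, 0.1, 0.2), patience = 50L,
                  grad_clip = 10, max_lag = 25L, max_d = 8L, seed = 1L,
                  verbose = FALSE) {
  activation <- match.arg(activation)
  cl <- match.call()
  if (!length(data)) stop("'data' must be a (list of) named list(s) of modal_series")
  session_mode <- is.list(data[[1L]]) && !inherits(data[[1L]], "modal_series")
  norm_session <- function(sess) {
    if (is.null(names(sess))) stop("each session must be a named list of modal_series")
    mapply(function(s, nm) if (inherits(s, "modal_series")) s else modal_series(s, nm),
           sess, names(sess), SIMPLIFY = FALSE)
  }
  sessions <- if (session_mode) lapply(data, norm_session) else list(norm_session(data))
  ids <- names(sessions[[1L]])
  for (sess in sessions) {
    if (!identical(names(sess), ids)) stop("all sessions must share the same modalities")
    if (length(unique(vapply(sess, function(s) nrow(s$values), integer(1)))) != 1L)
      stop("all modalities must have the same length within a session")
  }
  data <- if (session_mode) sessions else sessions[[1L]]
  weights$m <- as.integer(m)

  if (session_mode) {
    sp <- split_dataset(length(sessions), "random",
                        fractions = if (missing(split)) c(0.8, 0.1, 0.1) else split,
                        seed = seed)
  } else {
    sp <- split_dataset(nrow(sessions[[1L]][[1L]]$values), "temporal",
                        fractions = split)
  }

  train_values <- function(id) {
    if (session_mode)
      do.call(rbind, lapply(sessions[sp$train], function(sess) sess[[id]]$values))
    else sessions[[1L]][[id]]$values[sp$train, , drop = FALSE]
  }
  standardizers <- lapply(ids, function(id) fit_standardizer(train_values(id)))
  names(standardizers) <- ids

  d_fix <- .resolve_embed_par(d, ids, "d")
  tau_fix <- .resolve_embed_par(tau, ids, "tau")
  d_use <- integer(length(ids)); names(d_use) <- ids
  tau_use <- integer(length(ids)); names(tau_use) <- ids
  for (id in ids) {
    x_tr <- standardize(train_values(id), standardizers[[id]])[, 1L]
    tau_use[[id]] <- if (is.null(tau_fix))
      as.integer(estimate_delay_ami(x_tr, max_lag = max_lag)) else tau_fix[[id]]
    if (tau_use[[id]] < 1L) tau_use[[id]] <- 1L
    d_use[[id]] <- if (is.null(d_fix))
      as.integer(estimate_dim_fnn(x_tr, tau = tau_use[[id]], max_d = max_d)) else d_fix[[id]]
  }

  embed_session <- function(sess) {
    emb <- lapply(ids, function(id)
      delay_embed(standardize(sess[[id]], standardizers[[id]]),
                  d_use[[id]], tau_use[[id]]))
    names(emb) <- ids
    emb
  }
  if (session_mode) {
    w_train <- .concat_windows(lapply(sessions[sp$train], function(sess)
      make_training_windows(embed_session(sess), m)))
    w_val <- .concat_windows(lapply(sessions[sp$val], function(sess)
      make_training_windows(embed_session(sess), m)))
  } else {
    embedded <- embed_session(sessions[[1L]])
    w_train <- make_training_windows(embedded, m, k_range = range(sp$train))
    w_val <- make_training_windows(embedded, m, k_range = range(sp$val))
  }

  input_width <- vapply(w_train$x0, nrow, integer(1))
  model <- kmmae_model(input_width, p = p, hidden = hidden,
                       activation = activation, seed = seed)

  history <- data.frame()
  best <- list(params = model$params, epoch = 0L, val = Inf)
  epochs <- as.integer(epochs)
  if (epochs > 0L) {
    set.seed(as.integer(seed) + 1L)
    state <- list(m = lapply(model$params, .zeros_like),
                  v = lapply(model$params, .zeros_like),
                  t = 0L)
    # per-coordinate signal power of the training inputs (standardized scale)
    noise_sd <- if (is.finite(snr_db)) {
      lapply(w_train$x0, function(X) {
        pw <- rowMeans(sweep(X, 1, rowMeans(X))^2)
        sqrt(pmax(pw, 1e-12) / 10^(snr_db / 10))
      })
    } else NULL
    bs <- max(1L, min(as.integer(batch_size), w_train$n))
    since_best <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(w_train$n)
      starts <- seq.int(1L, w_train$n, by = bs)
      tr_tot <- 0; tr_n <- 0L
      for (s0 in starts) {
        idx <- ord[seq.int(s0, min(s0 + bs - 1L, w_train$n))]
        batch <- .windows_to_batch(w_train, idx)
        if (!is.null(noise_sd)) {
          for (id in ids) {
            X <- batch$x0[[id]]
            batch$x0[[id]] <- X + matrix(stats::rnorm(length(X)), nrow(X)) * noise_sd[[id]]
          }
        }
        masked <- character()
        if (mask_probability > 0 && stats::runif(1) < mask_probability) {
          masked <- sample(ids, 1L)
          batch$x0[[masked]][] <- sentinel
        }
        gr <- .kmmae_grad(model, batch, weights, missing = masked)
        if (!is.finite(gr$report$total))
          stop("non-finite loss at epoch ", ep,
               " (recon ", signif(gr$report$recon, 3),
               ", predict ", signif(gr$report$predict, 3),
               ", linear ", signif(gr$report$linear, 3), ")")
        upd <- .adam_step(model$params, gr$grads, state, learning_rate,
                          clip = grad_clip)
        model$params <- upd$params
        state <- upd$state
        tr_tot <- tr_tot + gr$report$total * batch$n
        tr_n <- tr_n + batch$n
      }
      vrep <- .kmmae_grad(model, .windows_to_batch(w_val), weights,
                          want_grad = FALSE)$report
      history <- rbind(history, data.frame(
        epoch = ep, train_total = tr_tot / tr_n,
        val_total = vrep$total, val_recon = vrep$recon,
        val_predict = vrep$predict, val_linear = vrep$linear,
        val_modality = vrep$modality, val_reg = vrep$reg))
      if (vrep$total < best$val - 1e-12) {
        best <- list(params = model$params, epoch = ep, val = vrep$total)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
      if (verbose && ep %% 50L == 0L)
        message(sprintf("epoch %d: train %.5g, val %.5g", ep,
                        tr_tot / tr_n, vrep$total))
    }
    model$params <- best$params
  }

  structure(list(
    model = model, weights = weights, standardizers = standardizers,
    embedding = list(d = d_use, tau = tau_use),
    split = sp, session_mode = session_mode, history = history,
    best_epoch = best$epoch, best_val = best$val, data = data,
    config = list(p = model$arch$p, hidden = model$arch$hidden,
                  activation = activation, m = as.integer(m),
                  epochs = epochs, batch_size = as.integer(batch_size),
                  learning_rate = learning_rate, snr_db = snr_db,
                  mask_probability = mask_probability, sentinel = sentinel,
                  split = split, patience = as.integer(patience),
                  grad_clip = grad_clip, seed = as.integer(seed)),
    call = cl), class = "kmmae")
}
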