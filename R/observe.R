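#' Describe one observed modality
#'
#' A modality is one observation stream of the shared latent system: a
#' pointwise observation map applied to the leading latent coordinates, an
#' optional lag behind the latent state, and optional additive white Gaussian
#' noise at a stated SNR.
#'
#' @param modality_id unique string identifier.
#' @param map observation map descriptor: `"identity"`, or a list with a
#'   `type` field among `"identity"`, `"polynomial"` (field `coefficients`,
#'   ascending powers), `"sinusoidal"` (fields `amplitude`, `frequency`,
#'   `phase`), `"affine"` (fields `scale`, `shift`) or `"tabulated"` (fields
#'   `x`, `y`, linearly interpolated).  Applied elementwise to the first
#'   `channels` latent coordinates.
#' @param channels number of output channels (>= 1).
#' @param delay_steps this modality lags the latent state by this many samples
#'   (>= 0).
#' @param noise_snr_db signal-to-noise ratio of added white Gaussian noise in
#'   dB; `Inf` (default) means no noise.
#' @return a list of class `modality_spec`.
#' @seealso [observation_spec()], [observe_modalities()]
#' @export
modality_spec <- function(modality_id, map = "identity", channels = 1L,
                          delay_steps = 0L, noise_snr_db = Inf) {
  if (is.character(map)) map <- list(type = map)
  if (is.null(map$type)) stop("observation map needs a 'type' field")
  map$type <- match.arg(map$type,
                        c("identity", "polynomial", "sinusoidal", "affine", "tabulated"))
  if (map$type == "polynomial" && is.null(map$coefficients))
    stop("polynomial map needs 'coefficients'")
  if (map$type == "tabulated" && (is.null(map$x) || is.null(map$y)))
    stop("tabulated map needs 'x' and 'y'")
  if (channels < 1L) stop("'channels' must be >= 1")
  if (delay_steps < 0L) stop("'delay_steps' must be >= 0")
  structure(list(modality_id = as.character(modality_id), map = map,
                 channels = as.integer(channels),
                 delay_steps = as.integer(delay_steps),
                 noise_snr_db = as.numeric(noise_snr_db)),
            class = "modality_spec")
}

#' Bundle modality descriptions into an observation specification
#'
#' @param ... [modality_spec()] objects (or one list of them).
#' @return a list of class `observation_spec` with unique modality ids.
#' @export
observation_spec <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && !inherits(mods[[1L]], "modality_spec")) mods <- mods[[1L]]
  if (!length(mods)) stop("at least one modality is required")
  ok <- vapply(mods, inherits, logical(1), "modality_spec")
  if (!all(ok)) stop("all entries must be modality_spec objects")
  ids <- vapply(mods, `[[`, character(1), "modality_id")
  if (anyDuplicated(ids)) stop("modality ids must be unique")
  names(mods) <- ids
  structure(mods, class = "observation_spec")
}

.apply_map <- function(map, z) {
  switch(map$type,
    identity = z,
    affine = {
      sc <- if (is.null(map$scale)) 1 else map$scale
      sh <- if (is.null(map$shift)) 0 else map$shift
      sc * z + sh
    },
    polynomial = {
      cf <- as.numeric(map$coefficients)
      out <- matrix(0, nrow(z), ncol(z))
      for (i in seq_along(cf)) out <- out + cf[i] * z^(i - 1L)
      out
    },
    sinusoidal = {
      a <- if (is.null(map$amplitude)) 1 else map$amplitude
      w <- if (is.null(map$frequency)) 1 else map$frequency
      ph <- if (is.null(map$phase)) 0 else map$phase
      a * sin(w * z + ph)
    },
    tabulated = {
      out <- stats::approx(map$x, map$y, xout = as.numeric(z), rule = 2)$y
      matrix(out, nrow(z), ncol(z))
    })
}

#' Observe a latent trajectory through modality maps
#'
#' Produces one [modal_series()] per modality.  Modality `l` at aligned step
#' `i` equals `map_l(latent[i + D - delay_l, ])` where `D` is the largest delay
#' across modalities, so all returned series are aligned, equal-length
#' (`T - D` steps) and modality `l` lags the latent state by `delay_l`
#' samples.  Noise, when configured, is added per channel at the requested SNR.
#'
#' @param latent T x p latent trajectory (rows = time).
#' @param obs an [observation_spec()].
#' @param seed integer seed controlling the noise draws.
#' @param sample_rate sampling rate recorded on the returned series.
#' @return named list of [modal_series()].
#' @export
observe_modalities <- function(latent, obs, seed = NULL, sample_rate = 1) {
  stopifnot(inherits(obs, "observation_spec"))
  latent <- as.matrix(latent)
  Tn <- nrow(latent); p <- ncol(latent)
  delays <- vapply(obs, `[[`, integer(1), "delay_steps")
  if (any(delays >= Tn))
    stop("delay_steps (", max(delays), ") must be smaller than the trajectory length ", Tn)
  D <- max(delays)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(obs, function(mod) {
    if (mod$channels > p)
      stop("modality '", mod$modality_id, "' requests ", mod$channels,
           " channels but the latent state has dimension ", p)
    idx <- seq_len(Tn - D) + D - mod$delay_steps
    z <- latent[idx, seq_len(mod$channels), drop = FALSE]
    v <- .apply_map(mod$map, z)
    s <- modal_series(v, mod$modality_id, sample_rate = sample_rate)
    if (is.finite(mod$noise_snr_db)) s <- add_noise_snr(s, mod$noise_snr_db)
    s
  })
  names(out) <- names(obs)
  out
}

#' Add white Gaussian noise at a given SNR
#'
#' Per channel, the noise variance is `signal_power / 10^(snr_db/10)` with the
#' signal power taken as the mean squared mean-removed sample (the conventional
#' AWGN definition).  `snr_db = Inf` returns the input unchanged.
#'
#' @param series a [modal_series()] or numeric matrix/vector.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed optional integer seed.
#' @return object of the same type as `series`, with noise added.
#' @export
add_noise_snr <- function(series, snr_db, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.finite(snr_db)) return(series)
  v <- .series_values(series)
  pw <- colMeans(sweep(v, 2, colMeans(v))^2)
  if (any(pw <= 0))
    stop("channel(s) ", paste(which(pw <= 0), collapse = ", "),
         " have zero variance; SNR is undefined")
  sd_n <- sqrt(pw / 10^(snr_db / 10))
  noise <- sweep(matrix(stats::rnorm(length(v)), nrow(v), ncol(v)), 2, sd_n, `*`)
  if (inherits(series, "modal_series")) {
    series$values <- v + noise
    series
  } else v + noise
}

#' Mask one modality with a sentinel value
#'
#' Replaces every value of the named modality with the sentinel and sets its
#' missing flag; all other modalities are untouched.  Masking an already
#' masked modality is a no-op.
#'
#' @param batch named list of [modal_series()].
#' @param modality_id modality to mask.
#' @param sentinel fill value (default `-1`).
#' @return the batch with the named modality masked.
#' @export
mask_modality <- function(batch, modality_id, sentinel = -1) {
  ids <- vapply(batch, `[[`, character(1), "modality_id")
  i <- match(modality_id, ids)
  if (is.na(i)) stop("unknown modality '", modality_id, "'")
  s <- batch[[i]]
  s$values[] <- sentinel
  s$missing <- rep(TRUE, nrow(s$values))
  s$sentinel <- as.numeric(sentinel)
  batch[[i]] <- s
  batch
}

#' Generate a stimulus (dynamics-change) dataset
#'
#' The latent state follows `pre_spec` up to `stimulus_step` and then evolves
#' under `post_spec` from the state reached at the stimulus (continuous
#' handoff).  Observation, delays and noise are as in [observe_modalities()].
#' The returned metadata records, per modality, the first aligned time index
#' at which the post-stimulus dynamics is visible — modality `l` lags the
#' stimulus by its `delay_steps`, which is the ground truth the loss-spike
#' reaction-time detector should recover.
#'
#' @param pre_spec,post_spec [latent_system()] objects with matching state
#'   dimension.
#' @param obs an [observation_spec()].
#' @param stimulus_step latent step at which the dynamics switches
#'   (`0 < stimulus_step < n_steps`).
#' @param n_steps total latent steps.
#' @param seed integer seed (noise draws).
#' @param sample_rate recorded on the returned series.
#' @return list with elements `series` (named list of [modal_series()]) and
#'   `event` (stimulus step, per-modality delays, aligned onset indices, seed).
#' @export
make_stimulus_dataset <- function(pre_spec, post_spec, obs, stimulus_step,
                                  n_steps, seed = NULL, sample_rate = 1) {
  stopifnot(inherits(pre_spec, "latent_system"), inherits(post_spec, "latent_system"))
  if (length(pre_spec$x0) != length(post_spec$x0))
    stop("pre and post systems have incompatible state dimensions (",
         length(pre_spec$x0), " vs ", length(post_spec$x0), ")")
  if (!(stimulus_step > 0 && stimulus_step < n_steps))
    stop("'stimulus_step' must lie strictly inside (0, n_steps)")
  stimulus_step <- as.integer(stimulus_step); n_steps <- as.integer(n_steps)
  pre <- simulate_latent(pre_spec, stimulus_step)
  post_spec$x0 <- pre[stimulus_step, ]
  post <- simulate_latent(post_spec, n_steps - stimulus_step + 1L)
  latent <- rbind(pre, post[-1L, , drop = FALSE])
  series <- observe_modalities(latent, obs, seed = seed, sample_rate = sample_rate)
  delays <- vapply(obs, `[[`, integer(1), "delay_steps")
  D <- max(delays)
  event <- list(stimulus_step = stimulus_step,
                delay_steps = delays,
                onset_latent = stimulus_step + delays,
                onset_index = stimulus_step + delays - D + 1L,
                seed = seed)
  list(series = series, event = event, latent = latent)
}
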