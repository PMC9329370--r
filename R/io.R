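#' Write modalities to a wide CSV with a JSON sidecar
#'
#' One header row, a `time` column and one `<modality>_<channel>` column per
#' channel (comma-separated, '.' decimal, UTF-8).  Missing steps are written
#' as the sentinel; a `<path>.json` sidecar records ids, channel counts,
#' sample rates, sentinels, missing masks and any extra metadata (seed,
#' generating spec), so a round trip is lossless.
#'
#' @param series named list of aligned [modal_series()].
#' @param path output CSV path.
#' @param meta optional list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_modalities <- function(series, path, meta = list()) {
  stopifnot(length(series) > 0)
  Ts <- vapply(series, function(s) nrow(s$values), integer(1))
  if (length(unique(Ts)) != 1L) stop("all modalities must have the same length")
  rates <- vapply(series, `[[`, numeric(1), "sample_rate")
  if (length(unique(rates)) != 1L)
    stop("all modalities must share one sample rate in a wide CSV")
  Tn <- Ts[[1L]]
  df <- data.frame(time = (seq_len(Tn) - 1L) / rates[[1L]])
  for (s in series) {
    v <- s$values
    v[s$missing, ] <- s$sentinel
    cn <- paste0(s$modality_id, "_", seq_len(ncol(v)))
    df[cn] <- as.data.frame(v)
  }
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    modalities = lapply(unname(series), function(s) list(
      modality_id = s$modality_id, channels = ncol(s$values),
      sample_rate = s$sample_rate, sentinel = s$sentinel,
      missing = which(s$missing))),
    meta = meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read modalities from a wide CSV
#'
#' Expects a `time` column plus `<modality>_<channel>` columns; checks that
#' the sampling is uniform (relative tolerance 1e-6) with no duplicate
#' timestamps.  Values equal to the sentinel across all of a modality's
#' channels are flagged as missing (the sidecar's recorded mask, when
#' present, takes precedence).
#'
#' @param path CSV path written by [write_modalities()] or of the same layout.
#' @param sentinel sentinel value (overridden by the sidecar if present).
#' @return named list of [modal_series()].
#' @export
read_modalities <- function(path, sentinel = -1) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column in ", path)
  tt <- df$time
  if (anyDuplicated(tt)) stop("duplicate timestamps in ", path)
  if (length(tt) > 1L) {
    dts <- diff(tt)
    if (any(abs(dts - dts[1L]) > 1e-6 * max(abs(dts[1L]), 1)))
      stop("non-uniform sampling in ", path)
    rate <- 1 / dts[1L]
  } else rate <- 1
  side <- NULL
  if (file.exists(paste0(path, ".json")))
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cols <- setdiff(names(df), "time")
  pref <- sub("_[0-9]+$", "", cols)
  if (any(pref == cols)) stop("channel columns must be named <modality>_<channel>")
  out <- list()
  for (id in unique(pref)) {
    v <- as.matrix(df[cols[pref == id]])
    sen <- sentinel
    miss <- rowSums(v != sen) == 0
    sr <- rate
    if (!is.null(side)) {
      mi <- which(side$modalities$modality_id == id)
      if (length(mi)) {
        sen <- side$modalities$sentinel[mi]
        sr <- side$modalities$sample_rate[mi]
        rec <- side$modalities$missing[[mi]]
        miss <- rowSums(v != sen) == 0
        if (length(rec)) miss[rec] <- TRUE
      }
    }
    out[[id]] <- modal_series(v, id, sample_rate = sr, missing = miss,
                              sentinel = sen)
  }
  out
}

#' Downsample by block means
#'
#' Decimates a series to `target_rate` by averaging each block of
#' `sample_rate / target_rate` consecutive samples (the source rate must be
#' an integer multiple of the target rate); a trailing partial block is
#' dropped.  Block averaging gives crude anti-aliasing without filter design.
#'
#' @param series a [modal_series()].
#' @param target_rate desired rate in Hz.
#' @return downsampled [modal_series()].
#' @export
downsample <- function(series, target_rate) {
  stopifnot(inherits(series, "modal_series"))
  f <- series$sample_rate / target_rate
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target rate ", target_rate, " Hz must divide the source rate ",
         series$sample_rate, " Hz")
  f <- as.integer(round(f))
  if (f == 1L) return(series)
  Tn <- nrow(series$values)
  nb <- Tn %/% f
  if (nb < 1L) stop("series shorter than one block")
  idx <- seq_len(nb * f)
  grp <- rep(seq_len(nb), each = f)
  v <- apply(series$values[idx, , drop = FALSE], 2,
             function(col) tapply(col, grp, mean))
  v <- matrix(v, nrow = nb)
  miss <- tapply(series$missing[idx], grp, any)
  modal_series(v, series$modality_id, sample_rate = target_rate,
               missing = as.logical(miss), sentinel = series$sentinel)
}

#' Save / load a fitted model
#'
#' Checkpoints carry all weight tensors, the architecture, standardization
#' parameters, per-modality embedding settings and the training
#' configuration; loading is a bit-exact round trip.
#'
#' @param fit a fitted [kmmae()] model (or a bare `kmmae_model`).
#' @param path checkpoint path.
#' @return `save_kmmae` returns `path` invisibly; `load_kmmae` returns the
#'   restored object.
#' @export
save_kmmae <- function(fit, path) {
  stopifnot(inherits(fit, c("kmmae", "kmmae_model")))
  obj <- list(format = "kmmae-checkpoint", version = 1L, fit = fit)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_kmmae
#' @export
load_kmmae <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "kmmae-checkpoint"))
    stop("not a kmmae checkpoint: ", path)
  obj$fit
}

#' Read latent-system and observation specifications from YAML/JSON
#'
#' The file mirrors the constructor fields: a `latent` block (`kind`,
#' `parameters`, `dt`, `x0`; for `linear_discrete`, `parameters$M` is given
#' row-major) and a `modalities` list (each with `modality_id`, `map`,
#' `channels`, `delay_steps`, `noise_snr_db`; `noise_snr_db: null` or `"Inf"`
#' means no noise).
#'
#' @param path YAML (or JSON) file path.
#' @return list with `latent` (a [latent_system()]) and `obs`
#'   (an [observation_spec()]).
#' @export
read_system_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$latent) || is.null(cfg$modalities))
    stop("spec needs 'latent' and 'modalities' blocks")
  lat <- cfg$latent
  pars <- lat$parameters %||% list()
  if (!is.null(pars$M)) {
    M <- pars$M
    if (is.list(M)) M <- do.call(rbind, lapply(M, unlist))
    if (is.null(dim(M))) M <- matrix(unlist(M), sqrt(length(unlist(M))), byrow = TRUE)
    pars$M <- M
  }
  latent <- latent_system(lat$kind, parameters = pars,
                          dt = lat$dt %||% 1, x0 = unlist(lat$x0))
  mods <- lapply(cfg$modalities, function(mo) {
    snr <- mo$noise_snr_db
    if (is.null(snr) || identical(snr, "Inf")) snr <- Inf
    modality_spec(mo$modality_id, map = mo$map %||% "identity",
                  channels = mo$channels %||% 1L,
                  delay_steps = mo$delay_steps %||% 0L,
                  noise_snr_db = snr)
  })
  list(latent = latent, obs = observation_spec(mods))
}
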