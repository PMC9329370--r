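#' Fit per-channel standardization parameters
#'
#' Computes per-channel mean and standard deviation (population convention,
#' i.e. divisor `T`) so that applying the parameters to the fitting data gives
#' mean 0 and standard deviation 1 per channel.  In the training pipeline the
#' standardizer is always fitted on the training split only.
#'
#' @param series a [modal_series()] or numeric matrix/vector.
#' @return object of class `standardizer` with fields `mean` and `sd`.
#' @seealso [standardize()], [unstandardize()]
#' @export
fit_standardizer <- function(series) {
  v <- .series_values(series)
  if (nrow(v) < 2L) stop("need at least 2 samples per channel")
  mu <- colMeans(v)
  sd <- sqrt(colMeans(sweep(v, 2, mu)^2))
  if (any(sd <= 0))
    stop("constant channel(s): ", paste(which(sd <= 0), collapse = ", "),
         "; cannot standardize")
  structure(list(mean = mu, sd = sd,
                 modality_id = if (inherits(series, "modal_series")) series$modality_id else NA_character_),
            class = "standardizer")
}

#' Apply / invert standardization
#'
#' `standardize()` maps values to `(x - mean) / sd`; `unstandardize()` is its
#' exact inverse.
#'
#' @param series a [modal_series()] or numeric matrix/vector.
#' @param params a `standardizer` from [fit_standardizer()].
#' @return same type as `series`.
#' @export
standardize <- function(series, params) {
  v <- .series_values(series)
  v <- sweep(sweep(v, 2, params$mean), 2, params$sd, `/`)
  if (inherits(series, "modal_series")) { series$values <- v; series } else v
}

#' @rdname standardize
#' @export
unstandardize <- function(series, params) {
  v <- .series_values(series)
  v <- sweep(sweep(v, 2, params$sd, `*`), 2, params$mean, `+`)
  if (inherits(series, "modal_series")) { series$values <- v; series } else v
}

#' Time-delay (Hankel) embedding
#'
#' Builds delay vectors `[x(k), x(k - tau), ..., x(k - (d-1) tau)]`
#' (most-recent-first) for every valid time index `k`, flattening channels
#' within each lag block.  The result has `K = T - (d-1) tau` rows; row `r`
#' represents source index `origin_index + r - 1`.
#'
#' `tau = 0` is accepted for compatibility with configurations that stack
#' consecutive samples: it is interpreted as `tau = 1` with a warning, the
#' only reading under which `d > 1` carries information.
#'
#' @param series a [modal_series()] or numeric matrix/vector (T x C).
#' @param d embedding dimension (number of stacked lags, >= 1).
#' @param tau lag spacing in samples.
#' @return object of class `delay_embedded` with fields `vectors`
#'   (K x (d*C)), `d`, `tau`, `channels`, `origin_index` and `modality_id`.
#' @export
delay_embed <- function(series, d, tau) {
  v <- .series_values(series)
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be >= 1")
  if (tau == 0L) {
    warning("tau = 0 interpreted as stacking consecutive samples (tau = 1)")
    tau <- 1L
  }
  tau <- as.integer(tau)
  if (tau < 0L) stop("'tau' must be >= 0")
  Tn <- nrow(v); C <- ncol(v)
  need <- (d - 1L) * tau + 1L
  if (Tn < need)
    stop("series too short for (d = ", d, ", tau = ", tau,
         "): need at least ", need, " samples, have ", Tn)
  K <- Tn - (d - 1L) * tau
  out <- matrix(NA_real_, K, d * C)
  ks <- seq.int(need, Tn)
  for (j in seq_len(d) - 1L) {
    out[, j * C + seq_len(C)] <- v[ks - j * tau, , drop = FALSE]
  }
  structure(list(modality_id = if (inherits(series, "modal_series")) series$modality_id else NA_character_,
                 d = d, tau = tau, channels = C,
                 vectors = out, origin_index = need),
            class = "delay_embedded")
}

#' @export
print.delay_embedded <- function(x, ...) {
  cat(sprintf("<delay_embedded '%s'>  d = %d, tau = %d, K = %d, width = %d (origin %d)\n",
              x$modality_id, x$d, x$tau, nrow(x$vectors), ncol(x$vectors),
              x$origin_index))
  invisible(x)
}

# Equal-width 2-D histogram mutual information between x and its lag-l copy.
.lagged_mi <- function(x, lag, n_bins) {
  n <- length(x)
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins) / length(a)
  px <- tabulate(ia, nbins = n_bins) / length(a)
  py <- tabulate(ib, nbins = n_bins) / length(a)
  pij <- matrix(joint, n_bins, n_bins)
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / (outer(px, py)[nz])))
}

#' Estimate the embedding delay from mutual information
#'
#' Returns the first local minimum of the lagged mutual information function
#' `MI(l)`, i.e. the smallest lag `l >= 1` with `MI(l) < MI(l-1)` and
#' `MI(l) <= MI(l+1)`.  MI is estimated with an equal-width 2-D histogram of
#' `n_bins` bins per axis.  If no local minimum exists below `max_lag`, the
#' function returns `max_lag` with a warning.
#'
#' @param series single-channel numeric vector (or single-channel series).
#' @param max_lag largest lag to examine.
#' @param n_bins histogram bins per axis (default 16).
#' @return integer lag estimate; the MI curve is attached as attribute `"mi"`.
#' @export
estimate_delay_ami <- function(series, max_lag, n_bins = 16L) {
  x <- as.numeric(.series_values(series)[, 1L])
  if (length(unique(x)) == 1L) stop("constant series: mutual information undefined")
  max_lag <- as.integer(max_lag)
  if (max_lag < 2L) stop("'max_lag' must be >= 2")
  if (length(x) < 4L * max_lag)
    stop("series too short: need at least 4 * max_lag = ", 4L * max_lag, " samples")
  mi <- vapply(0:max_lag, function(l) .lagged_mi(x, l, n_bins), numeric(1))
  tau <- NA_integer_
  for (l in 1:(max_lag - 1L)) {
    if (mi[l + 1L] < mi[l] && mi[l + 1L] <= mi[l + 2L]) { tau <- l; break }
  }
  if (is.na(tau)) {
    warning("no local minimum of mutual information below max_lag = ", max_lag,
            "; returning max_lag")
    tau <- max_lag
  }
  structure(tau, mi = mi)
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' For each candidate dimension `d`, the series is embedded at `(d, tau)`,
#' each point's (Euclidean) nearest neighbour is found, and the neighbour is
#' declared false when the distance added by the next coordinate exceeds
#' `rtol` times the current distance (the Kennel criterion).  The estimate is
#' the smallest `d` whose false-neighbour fraction falls below
#' `fnn_threshold`; if none qualifies, `max_d` is returned with a warning.
#' The criterion is ratio-based, so the estimate is invariant to affine
#' rescaling of the series.
#'
#' @param series single-channel numeric vector (or single-channel series).
#' @param tau embedding delay (>= 1).
#' @param max_d largest dimension to test.
#' @param rtol false-neighbour distance ratio threshold (conventional 10).
#' @param fnn_threshold acceptable false-neighbour fraction (conventional 0.01).
#' @return integer dimension estimate; the per-dimension false-neighbour
#'   fractions are attached as attribute `"fnn"`.
#' @export
estimate_dim_fnn <- function(series, tau, max_d, rtol = 10, fnn_threshold = 0.01) {
  x <- as.numeric(.series_values(series)[, 1L])
  tau <- as.integer(tau)
  if (tau < 1L) stop("'tau' must be >= 1")
  max_d <- as.integer(max_d)
  Tn <- length(x)
  fracs <- rep(NA_real_, max_d)
  for (d in seq_len(max_d)) {
    # points that exist in both the d and (d+1) embeddings
    need <- d * tau + 1L
    if (Tn < need + 1L) break
    ks <- seq.int(need, Tn)
    emb <- vapply(seq_len(d) - 1L, function(j) x[ks - j * tau], numeric(length(ks)))
    emb <- matrix(emb, nrow = length(ks))
    added <- x[ks - d * tau]
    dm <- as.matrix(stats::dist(emb))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, which.min)
    rd <- dm[cbind(seq_along(nn), nn)]
    extra <- abs(added - added[nn])
    # floor the neighbour distance at rounding scale so exact recurrences
    # (e.g. periodic orbits) do not produce 0/0 ratios counted as false
    floor_d <- sqrt(.Machine$double.eps) * max(diff(range(x)), 1e-12)
    false <- extra / pmax(rd, floor_d) > rtol
    fracs[d] <- mean(false)
    if (fracs[d] < fnn_threshold)
      return(structure(d, fnn = fracs))
  }
  warning("false-neighbour fraction never fell below ", fnn_threshold,
          " up to max_d = ", max_d, "; returning max_d")
  structure(max_d, fnn = fracs)
}
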