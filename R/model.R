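#' Construct and initialize a multi-modal Koopman auto-encoder
#'
#' Builds the network of the method: one encoder and one decoder per modality
#' plus a shared linear propagator.  Each encoder maps the (delay-embedded)
#' modality input through two hidden layers of widths `hidden` (default
#' 20 then 15) into the joint layer of width `p` (default 20); decoders mirror
#' the encoders.  Hidden layers use the chosen activation (ReLU by default);
#' the projection into the joint layer and the final decoder layer are linear,
#' so the latent state space and standardized targets can take negative
#' values.  The propagator `A` is a bias-free p x p matrix — the finite
#' approximation of the Koopman operator — initialized to the identity so
#' training starts from a stable, norm-preserving dynamics.
#'
#' All weight matrices are Xavier (Glorot uniform) initialized from `seed`;
#' all biases start at exactly zero.
#'
#' @param input_width named integer vector: input width (`d * channels`) per
#'   modality.
#' @param p joint (latent) layer width.
#' @param hidden widths of the two hidden layers.
#' @param activation `"relu"` (default) or `"identity"` for the hidden layers;
#'   `"identity"` makes the whole network linear, the regime in which the
#'   model can be compared against exact least-squares (DMD) solutions.
#' @param seed integer seed for the weight draws.
#' @return object of class `kmmae_model` with fields `arch` and `params`.
#' @seealso [encode()], [decode()], [fuse()], [step_linear()],
#'   [koopman_spectrum()]
#' @export
kmmae_model <- function(input_width, p = 20L, hidden = c(20L, 15L),
                        activation = c("relu", "identity"), seed = 1L) {
  activation <- match.arg(activation)
  if (is.null(names(input_width)) || any(!nzchar(names(input_width))))
    stop("'input_width' must be a named vector (one entry per modality)")
  if (anyDuplicated(names(input_width))) stop("modality ids must be unique")
  if (any(input_width < 1L)) stop("input widths must be >= 1")
  if (length(hidden) != 2L || any(hidden < 1L)) stop("'hidden' must give two positive widths")
  p <- as.integer(p)
  arch <- list(ids = names(input_width),
               input_width = vapply(input_width, as.integer, integer(1)),
               p = p, hidden = as.integer(hidden), activation = activation)
  set.seed(as.integer(seed))
  xavier <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  params <- list()
  for (id in arch$ids) {
    n <- arch$input_width[[id]]
    dims_e <- list(c(hidden[1L], n), c(hidden[2L], hidden[1L]), c(p, hidden[2L]))
    dims_d <- list(c(hidden[2L], p), c(hidden[1L], hidden[2L]), c(n, hidden[1L]))
    for (i in 1:3) {
      params[[sprintf("enc_%s_W%d", id, i)]] <- xavier(dims_e[[i]][1L], dims_e[[i]][2L])
      params[[sprintf("enc_%s_b%d", id, i)]] <- numeric(dims_e[[i]][1L])
      params[[sprintf("dec_%s_W%d", id, i)]] <- xavier(dims_d[[i]][1L], dims_d[[i]][2L])
      params[[sprintf("dec_%s_b%d", id, i)]] <- numeric(dims_d[[i]][1L])
    }
  }
  params$A <- diag(p)
  structure(list(arch = arch, params = params), class = "kmmae_model")
}

#' @export
print.kmmae_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<kmmae_model>  %d modalities (%s), joint width p = %d, hidden %s, %s hidden activation, %d parameters\n",
              length(x$arch$ids), paste(x$arch$ids, collapse = ", "),
              x$arch$p, paste(x$arch$hidden, collapse = "/"),
              x$arch$activation, n_par))
  invisible(x)
}

# Pull the raw model out of either a kmmae_model or a fitted kmmae object.
.model_of <- function(object) {
  if (inherits(object, "kmmae")) return(object$model)
  if (inherits(object, "kmmae_model")) return(object)
  stop("expected a 'kmmae_model' or fitted 'kmmae' object")
}

.act <- function(z, kind) if (kind == "relu") z * (z > 0) else z
.act_grad <- function(z, kind) if (kind == "relu") (z > 0) * 1 else array(1, dim(z))

# Forward pass through a 3-layer map.  X is width x B (columns = samples).
# prefix is "enc_<id>" or "dec_<id>"; hidden activation `act`, final linear.
.mlp_forward <- function(params, prefix, X, act, keep = FALSE) {
  W1 <- params[[paste0(prefix, "_W1")]]; b1 <- params[[paste0(prefix, "_b1")]]
  W2 <- params[[paste0(prefix, "_W2")]]; b2 <- params[[paste0(prefix, "_b2")]]
  W3 <- params[[paste0(prefix, "_W3")]]; b3 <- params[[paste0(prefix, "_b3")]]
  if (nrow(X) != ncol(W1))
    stop("input width ", nrow(X), " does not match expected ", ncol(W1),
         " for '", prefix, "'")
  Z1 <- W1 %*% X + b1
  H1 <- .act(Z1, act)
  Z2 <- W2 %*% H1 + b2
  H2 <- .act(Z2, act)
  out <- W3 %*% H2 + b3
  if (!keep) return(out)
  list(out = out, X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2)
}

# Backward pass; dout has the shape of the forward output.  Returns gradient
# contributions (named like the parameters) and the gradient wrt the input.
.mlp_backward <- function(params, prefix, cache, dout, act) {
  W2 <- params[[paste0(prefix, "_W2")]]
  W3 <- params[[paste0(prefix, "_W3")]]
  g <- list()
  g[[paste0(prefix, "_W3")]] <- dout %*% t(cache$H2)
  g[[paste0(prefix, "_b3")]] <- rowSums(dout)
  dH2 <- t(W3) %*% dout
  dZ2 <- dH2 * .act_grad(cache$Z2, act)
  g[[paste0(prefix, "_W2")]] <- dZ2 %*% t(cache$H1)
  g[[paste0(prefix, "_b2")]] <- rowSums(dZ2)
  dH1 <- t(W2) %*% dZ2
  dZ1 <- dH1 * .act_grad(cache$Z1, act)
  g[[paste0(prefix, "_W1")]] <- dZ1 %*% t(cache$X)
  g[[paste0(prefix, "_b1")]] <- rowSums(dZ1)
  W1 <- params[[paste0(prefix, "_W1")]]
  list(grads = g, dX = t(W1) %*% dZ1)
}

# Coerce user-facing row-major input (samples in rows) to width x B.
.as_cols <- function(x, width) {
  if (is.null(dim(x))) {
    if (length(x) != width)
      stop("input width ", length(x), " does not match expected ", width)
    return(matrix(as.numeric(x), ncol = 1))
  }
  x <- as.matrix(x)
  if (ncol(x) != width)
    stop("input width ", ncol(x), " does not match expected ", width)
  t(x)
}

#' Encode a modality into the joint latent space
#'
#' Deterministic forward pass through the modality's encoder: two hidden
#' layers with the model's activation, then a linear projection to the joint
#' width `p`.
#'
#' @param object a `kmmae_model` or fitted `kmmae`.
#' @param modality_id which encoder to use.
#' @param x a delay-embedded input row (length `d * C`) or a matrix of such
#'   rows.
#' @return a `p`-vector, or a K x p matrix when `x` has K rows.
#' @export
encode <- function(object, modality_id, x) {
  model <- .model_of(object)
  if (!modality_id %in% model$arch$ids) stop("unknown modality '", modality_id, "'")
  X <- .as_cols(x, model$arch$input_width[[modality_id]])
  out <- .mlp_forward(model$params, paste0("enc_", modality_id), X,
                      model$arch$activation)
  if (is.null(dim(x))) as.numeric(out) else t(out)
}

#' Decode a latent state back to a modality's embedded input
#'
#' Mirror of [encode()]: two hidden layers with the model's activation, then a
#' final linear layer of the modality's input width (so standardized negative
#' values are representable).
#'
#' @inheritParams encode
#' @param y a latent `p`-vector or K x p matrix.
#' @return reconstructed embedded input (vector or K x (d*C) matrix).
#' @export
decode <- function(object, modality_id, y) {
  model <- .model_of(object)
  if (!modality_id %in% model$arch$ids) stop("unknown modality '", modality_id, "'")
  Y <- .as_cols(y, model$arch$p)
  out <- .mlp_forward(model$params, paste0("dec_", modality_id), Y,
                      model$arch$activation)
  if (is.null(dim(y))) as.numeric(out) else t(out)
}

#' Fuse per-modality encodings into the shared latent state
#'
#' The shared state is the arithmetic mean of the encodings of the non-missing
#' modalities (permutation-invariant).  With `divisor = "total"` the sum is
#' divided by the total number of modalities instead — the literal reading of
#' the defining formula — which shrinks the state when modalities are missing
#' and is therefore not the default.
#'
#' @param encodings named list of latent `p`-vectors (or K x p matrices).
#' @param missing character vector of modality ids to exclude.
#' @param divisor `"observed"` (default) or `"total"`.
#' @return fused latent state, same shape as the entries of `encodings`.
#' @export
fuse <- function(encodings, missing = character(), divisor = c("observed", "total")) {
  divisor <- match.arg(divisor)
  keep <- setdiff(names(encodings), missing)
  if (!length(keep)) stop("all modalities are missing; cannot fuse")
  s <- Reduce(`+`, encodings[keep])
  s / if (divisor == "observed") length(keep) else length(encodings)
}

#' Advance the latent state with the linear propagator
#'
#' Returns `A^j y` (computed by repeated multiplication); `j = 0` is the
#' identity.  `A` carries no bias and no activation, so this map is exactly
#' linear.
#'
#' @inheritParams encode
#' @param y latent `p`-vector or K x p matrix of states (rows).
#' @param j number of steps (integer >= 0).
#' @return advanced state(s), same shape as `y`.
#' @export
step_linear <- function(object, y, j = 1L) {
  model <- .model_of(object)
  if (j < 0) stop("'j' must be >= 0")
  Y <- .as_cols(y, model$arch$p)
  A <- model$params$A
  for (i in seq_len(as.integer(j))) Y <- A %*% Y
  if (is.null(dim(y))) as.numeric(Y) else t(Y)
}

#' Eigenvalues of the learned Koopman approximation
#'
#' @inheritParams encode
#' @return object of class `koopman_spectrum`: list with `eigenvalues`
#'   (complex, sorted by modulus, descending) and `spectral_radius`.
#' @export
koopman_spectrum <- function(object) {
  model <- .model_of(object)
  ev <- eigen(model$params$A, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  structure(list(eigenvalues = ev, spectral_radius = max(Mod(ev))),
            class = "koopman_spectrum")
}

#' @export
print.koopman_spectrum <- function(x, ...) {
  cat(sprintf("Koopman spectrum (p = %d), spectral radius %.4f\n",
              length(x$eigenvalues), x$spectral_radius))
  print(signif(x$eigenvalues, 5))
  invisible(x)
}
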