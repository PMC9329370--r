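#' Specify a latent dynamical system
#'
#' Describes the hidden state dynamics that the synthetic generator simulates
#' and the multi-modal observations are derived from.  Three kinds are
#' supported:
#'
#' * `"linear_discrete"` — exact discrete map `x(k+1) = M x(k)`;
#'   `parameters$M` is the p x p matrix.
#' * `"slow_manifold"` — the canonical nonlinear pair
#'   `dx1/dt = mu * x1`, `dx2/dt = lambda * (x2 - x1^2)`, which admits an exact
#'   3-dimensional linear Koopman embedding with dictionary `{x1, x2, x1^2}`;
#'   `parameters$mu` and `parameters$lambda` are rates per unit time.
#' * `"custom_ode"` — `parameters$rhs` is a function `(t, x) -> dx/dt`.
#'
#' ODE kinds are integrated with a fixed-step 4th-order Runge-Kutta scheme at
#' step `dt` (optionally with finer substeps), so trajectories are exactly
#' reproducible.
#'
#' @param kind one of `"linear_discrete"`, `"slow_manifold"`, `"custom_ode"`.
#' @param parameters named list of parameters for the chosen kind.
#' @param dt seconds per output step (must be > 0).
#' @param x0 initial state vector.
#' @return an object of class `latent_system`.
#' @examples
#' sys <- latent_system("slow_manifold",
#'                      parameters = list(mu = -0.05, lambda = -1),
#'                      dt = 0.01, x0 = c(1, 1))
#' traj <- simulate_latent(sys, n_steps = 101)
#' @export
latent_system <- function(kind = c("linear_discrete", "slow_manifold", "custom_ode"),
                          parameters = list(), dt = 1, x0) {
  kind <- match.arg(kind)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("'dt' must be > 0")
  x0 <- as.numeric(x0)
  p <- length(x0)
  if (p < 1L) stop("'x0' must be a non-empty numeric vector")
  if (kind == "linear_discrete") {
    M <- parameters$M
    if (is.null(M)) stop("linear_discrete requires parameters$M")
    M <- as.matrix(M)
    if (nrow(M) != p || ncol(M) != p)
      stop("parameters$M must be ", p, " x ", p, " to match x0")
    parameters$M <- M
  } else if (kind == "slow_manifold") {
    if (is.null(parameters$mu) || is.null(parameters$lambda))
      stop("slow_manifold requires parameters$mu and parameters$lambda")
    if (p != 2L) stop("slow_manifold state is 2-dimensional; x0 has length ", p)
  } else {
    if (!is.function(parameters$rhs))
      stop("custom_ode requires a right-hand-side function parameters$rhs")
  }
  structure(list(kind = kind, parameters = parameters,
                 dt = as.numeric(dt), x0 = x0),
            class = "latent_system")
}

#' @export
print.latent_system <- function(x, ...) {
  cat(sprintf("<latent_system '%s'>  state dim = %d, dt = %g\n",
              x$kind, length(x$x0), x$dt))
  invisible(x)
}

.latent_rhs <- function(spec) {
  switch(spec$kind,
    slow_manifold = {
      mu <- spec$parameters$mu; lambda <- spec$parameters$lambda
      function(t, x) c(mu * x[1], lambda * (x[2] - x[1]^2))
    },
    custom_ode = spec$parameters$rhs,
    stop("no continuous right-hand side for kind '", spec$kind, "'"))
}

#' Simulate a latent trajectory
#'
#' Advances the system described by a [latent_system()] for `n_steps` output
#' steps.  The first row of the returned matrix is the initial state `x0`.
#' Discrete linear systems are advanced exactly; ODE systems use fixed-step
#' RK4 at step `dt / n_substeps`.
#'
#' @param spec a [latent_system()].
#' @param n_steps number of rows to produce (>= 1), including the initial state.
#' @param seed optional integer; the built-in kinds are deterministic, the seed
#'   is set (when supplied) so that stochastic `custom_ode` right-hand sides
#'   are reproducible.
#' @param n_substeps RK4 substeps per output step (>= 1).
#' @return `n_steps` x p numeric matrix, one state per row.
#' @export
simulate_latent <- function(spec, n_steps, seed = NULL, n_substeps = 1L) {
  stopifnot(inherits(spec, "latent_system"))
  if (!is.numeric(n_steps) || n_steps < 1) stop("'n_steps' must be >= 1")
  n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- length(spec$x0)
  out <- matrix(NA_real_, n_steps, p)
  out[1L, ] <- spec$x0
  if (n_steps == 1L) return(out)
  if (spec$kind == "linear_discrete") {
    M <- spec$parameters$M
    for (k in 2:n_steps) {
      out[k, ] <- as.numeric(M %*% out[k - 1L, ])
      if (any(!is.finite(out[k, ])))
        stop("latent state diverged (non-finite) at step ", k)
    }
    return(out)
  }
  rhs <- .latent_rhs(spec)
  h <- spec$dt / max(1L, as.integer(n_substeps))
  x <- spec$x0
  for (k in 2:n_steps) {
    for (s in seq_len(max(1L, as.integer(n_substeps)))) {
      k1 <- rhs(0, x)
      k2 <- rhs(0, x + h / 2 * k1)
      k3 <- rhs(0, x + h / 2 * k2)
      k4 <- rhs(0, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(x)))
      stop("latent state diverged (non-finite) at step ", k)
    out[k, ] <- x
  }
  out
}
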