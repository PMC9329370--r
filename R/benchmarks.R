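#' Reference synthetic benchmarks
#'
#' Fixed study conditions used throughout the package's verification suite.
#' Each builder returns data (and, where relevant, ground truth) generated
#' from a known latent dynamics, so that every headline property —
#' equivalence with least-squares propagators in the linear regime, Koopman
#' spectrum recovery, missing-modality restoration, reaction-time recovery —
#' can be recomputed from scratch.
#'
#' @name benchmarks
NULL

#' Damped-free planar rotation latent system
#'
#' A convenience [latent_system()]: discrete rotation by `2 pi / period` per
#' step — a persistent 2-D oscillation, the simplest latent dynamics whose
#' observations keep exciting the whole state space.
#'
#' @param period rotation period in samples.
#' @param x0 initial state.
#' @param dt seconds per step.
#' @return a [latent_system()].
#' @export
rotation_system <- function(period = 40, x0 = c(1.5, 0), dt = 1) {
  th <- 2 * pi / period
  latent_system("linear_discrete",
                parameters = list(M = matrix(c(cos(th), sin(th),
                                               -sin(th), cos(th)), 2)),
                dt = dt, x0 = x0)
}

#' @describeIn benchmarks Noiseless 2-D linear system `M = diag(0.9, 0.5)`
#'   observed through one identity modality — the regime in which the trained
#'   model is comparable against the exact least-squares (DMD) propagator.
#' @param n_steps trajectory length.
#' @export
benchmark_linear <- function(n_steps = 500) {
  sys <- latent_system("linear_discrete",
                       parameters = list(M = diag(c(0.9, 0.5))), x0 = c(4, 4))
  list(system = sys,
       series = observe_modalities(
         simulate_latent(sys, n_steps),
         observation_spec(modality_spec("x", "identity", channels = 2))),
       eigenvalues = c(0.9, 0.5))
}

#' @describeIn benchmarks Slow-manifold system (`mu = -0.05`, `lambda = -1`,
#'   `dt = 0.01`) observed through an identity modality and a squared scalar
#'   observable, as several short sessions from a grid of initial conditions
#'   (a single trajectory leaves the fast latent direction unconstrained
#'   after its transient).  Ground-truth discrete-time eigenvalues:
#'   `{e^(mu dt), e^(lambda dt), e^(2 mu dt)}`.
#' @param session_steps steps per session.
#' @export
benchmark_slow_manifold <- function(session_steps = 300) {
  mu <- -0.05; lambda <- -1; dt <- 0.01
  obs <- observation_spec(
    modality_spec("state", "identity", channels = 2),
    modality_spec("sq", list(type = "polynomial", coefficients = c(0, 0, 1)),
                  channels = 1))
  x0s <- expand.grid(x1 = c(0.5, 1, 1.5), x2 = c(0.2, 1, 2.5))
  sessions <- lapply(seq_len(nrow(x0s)), function(i) {
    sys <- latent_system("slow_manifold",
                         parameters = list(mu = mu, lambda = lambda),
                         dt = dt, x0 = as.numeric(x0s[i, ]))
    observe_modalities(simulate_latent(sys, session_steps), obs)
  })
  list(sessions = sessions,
       eigenvalues = exp(c(mu, lambda, 2 * mu) * dt),
       dictionary = function(z) cbind(z, z[, 1]^2))
}

#' @describeIn benchmarks Four modalities (identity / square / sine / affine
#'   maps) of one shared 2-D rotation at a stated SNR — the restoration
#'   benchmark.
#' @param n_sessions number of sessions (varied initial phase).
#' @param snr_db observation noise level in dB.
#' @param seed noise seed.
#' @export
benchmark_multimodal <- function(n_sessions = 8, n_steps = 220, snr_db = 10,
                                 seed = 1) {
  obs <- observation_spec(
    modality_spec("ident", "identity", channels = 2, noise_snr_db = snr_db),
    modality_spec("square", list(type = "polynomial", coefficients = c(0, 0, 1)),
                  channels = 1, noise_snr_db = snr_db),
    modality_spec("sine", list(type = "sinusoidal", amplitude = 1, frequency = 2),
                  channels = 2, noise_snr_db = snr_db),
    modality_spec("affine", list(type = "affine", scale = -0.8, shift = 2),
                  channels = 2, noise_snr_db = snr_db))
  lapply(seq_len(n_sessions), function(i) {
    phase <- 2 * pi * (i - 1) / n_sessions
    sys <- rotation_system(x0 = 1.5 * c(cos(phase), sin(phase)))
    observe_modalities(simulate_latent(sys, n_steps), obs, seed = seed + i)
  })
}

#' @describeIn benchmarks Two lagged modalities (`A` immediate, `B` delayed 5
#'   samples) of a rotation whose period switches at a stimulus — the
#'   reaction-time benchmark.  Returns pre-stimulus training sessions and a
#'   replicate generator `stimulus(seed)`.
#' @export
benchmark_stimulus <- function(seed = 1) {
  obs <- observation_spec(
    modality_spec("A", "identity", channels = 2, noise_snr_db = 20),
    modality_spec("B", list(type = "affine", scale = 0.7, shift = 0.5),
                  channels = 2, delay_steps = 5, noise_snr_db = 20))
  pre <- rotation_system(40)
  post <- rotation_system(10)
  train_sessions <- lapply(1:6, function(i) {
    phase <- 2 * pi * (i - 1) / 6
    observe_modalities(
      simulate_latent(rotation_system(40, 1.5 * c(cos(phase), sin(phase))), 150),
      obs, seed = seed + 100 + i)
  })
  list(obs = obs, train_sessions = train_sessions, true_lag = 5L,
       stimulus = function(rep_seed)
         make_stimulus_dataset(pre, post, obs, stimulus_step = 80,
                               n_steps = 140, seed = rep_seed))
}
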