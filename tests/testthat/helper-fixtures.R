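# Shared fixture builders: everything is generated in code at test time.
# The heavyweight study conditions live in the package itself
# (rotation_system(), benchmark_*()); this helper only adds small utilities.

benchmark_obs <- function(snr_db = Inf) {
  observation_spec(
    modality_spec("ident", "identity", channels = 2, noise_snr_db = snr_db),
    modality_spec("square", list(type = "polynomial", coefficients = c(0, 0, 1)),
                  channels = 1, noise_snr_db = snr_db),
    modality_spec("sine", list(type = "sinusoidal", amplitude = 1, frequency = 2),
                  channels = 2, noise_snr_db = snr_db),
    modality_spec("affine", list(type = "affine", scale = -0.8, shift = 2),
                  channels = 2, noise_snr_db = snr_db))
}

# Closed form of the slow-manifold system for oracle checks:
# x1(t) = x1(0) e^(mu t);  x2(t) = (x2(0) - c x1(0)^2) e^(lambda t)
#                                 + c x1(0)^2 e^(2 mu t),  c = lambda/(lambda - 2 mu)
slow_manifold_exact <- function(t, x0, mu, lambda) {
  cc <- lambda / (lambda - 2 * mu)
  cbind(x0[1] * exp(mu * t),
        (x0[2] - cc * x0[1]^2) * exp(lambda * t) + cc * x0[1]^2 * exp(2 * mu * t))
}

# Small trained fit on a clean two-modality rotation, shared by several tests
# (built once per test run).
cached_small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      obs <- observation_spec(
        modality_spec("a", "identity", channels = 2),
        modality_spec("b", list(type = "affine", scale = 0.5, shift = 1),
                      channels = 2))
      series <- observe_modalities(simulate_latent(rotation_system(), 400), obs)
      fit <<- kmmae(series, d = 2, tau = 1, p = 4, m = 2, epochs = 120,
                    snr_db = Inf, mask_probability = 0.3, seed = 11,
                    learning_rate = 3e-3, patience = 120)
    }
    fit
  }
})
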