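# kmmae — Koopman multi-modal auto-encoders for shared linear dynamics

Physiological monitoring rarely observes a system through one channel.  A
driver under stress is measured through heart rate, electrodermal activity,
perspiration and breathing rate; an emergency braking response shows up in
both an EEG channel and a leg-muscle EMG.  Each of these *modalities* is a
nonlinear, noisy, possibly lagged observation `x_l(t) = g_l(y(t))` of one
underlying state `y(t)` evolving under a shared dynamics `dy/dt = h(y)`.

`kmmae` learns that shared dynamics as a *linear* map on a learned latent
space.  By Koopman operator theory, a nonlinear dynamics becomes linear when
expressed through suitable measurement functions of the state; the package
approximates those functions with one encoder per modality feeding a joint
latent layer `y(k)` of width `p`, on which a bias-free linear layer — the
finite Koopman approximation `A` — advances time:

    y_l(k) = encoder_l( x_l(k), x_l(k-tau), ..., x_l(k-(d-1)tau) )   (delay embedding)
    y(k)   = mean over non-missing modalities of y_l(k)              (fusion)
    y(k+1) = A y(k)                                                  (linear dynamics)
    x_l(k) = decoder_l( y(k) )                                       (reconstruction)

Training minimizes

    lambda_recon (L_recon + L_predict) + lambda_linear L_linear
      + lambda_modality L_modality + lambda_reg ||W||^2

where `L_recon` is the auto-encoder error, `L_predict` decodes `A^j y(k)`
against `x_l(k+j)` for `j = 1..m`, `L_linear` forces
`encoder_l(x_l(k+j)) = A^j encoder_l(x_l(k))` (latent linearity), and
`L_modality` is a center loss pulling every modality's encoding onto one
shared latent trajectory.  Batches are augmented with white Gaussian noise at
a stated SNR and with random sentinel masking of whole modalities, so the
trained model denoises, and can *restore a masked modality from the others*
and predict all modalities forward through `A`.  Spikes of the
reconstruction/prediction losses against their pre-stimulus baselines give a
reaction-time detector for dynamics-change events.

Because no autodiff framework is assumed, the network, backpropagation and
the Adam optimizer are implemented in vectorized base R; the architecture is
small (hidden widths 20/15, joint width 20 by default) and trains in seconds
to minutes at desk scale.

## A worked example

Two modalities observe one latent planar rotation — one directly, one through
an affine map.  We fit the model, inspect the learned spectrum and restore a
masked modality:

```r
library(kmmae)

obs <- observation_spec(
  modality_spec("a", "identity", channels = 2),
  modality_spec("b", list(type = "affine", scale = 0.5, shift = 1), channels = 2))
series <- observe_modalities(simulate_latent(rotation_system(period = 40), 400), obs)

fit <- kmmae(series, d = 2, tau = 1, p = 4, m = 2, epochs = 120,
             snr_db = Inf, mask_probability = 0.3, seed = 11,
             learning_rate = 3e-3, patience = 120)
fit
#> Koopman multi-modal auto-encoder fit
#>   modalities: a, b
#>   joint width p = 4, hidden 20/15, relu hidden activation
#>   embedding: d = {2, 2}, tau = {1, 1}
#>   trained 120 epochs; best validation total 0.0048112 at epoch 87
#>   spectral radius of A: 1.0004

koopman_spectrum(fit)
#> Koopman spectrum (p = 4), spectral radius 1.0004
#> [1] 1.00040+0.00000i 0.98759+0.15651i 0.98759-0.15651i 0.92415+0.00000i
```

The complex pair sits essentially on the unit circle at phase
`0.1565 ≈ 2*pi/40` — the model has identified the 40-sample rotation as an
undamped oscillatory latent mode (the remaining real eigenvalues carry the
constant offset and a decaying correction).  Restoration of a masked
modality uses only the other one:

```r
restored <- restore_missing(fit, series, "b")
ks <- attr(restored$b, "k")
rmse(series$b$values[ks, ], restored$b$values)
#> [1] 0.009282782
```

i.e. modality `b` is rebuilt from modality `a` alone to within ~1% of its
amplitude.  `predict(fit, type = "rollout", horizon = 10)` continues all
modalities forward through `A`, and `loss_trace()` +
`detect_reaction_time()` implement the loss-spike event detector.

A thin command-line tool wrapping these functions is installed as
`exec/kmmae` with subcommands `simulate`, `embed`, `train`, `evaluate`,
`detect` and `spectrum`.

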