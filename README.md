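# cartrec

Noninvasive measurement of the **characteristic recovery time** of
articular cartilage from serial MRI.

Articular cartilage deforms under load and slowly recovers its thickness
afterwards; how fast it recovers is a mechanical property of the tissue,
governed by interstitial fluid flow through the solid matrix. Changes in
mechanical function appear early in osteoarthritis, before radiographic
findings, so an in vivo handle on recovery dynamics is of direct clinical
interest. `cartrec` implements the full measurement chain for researchers
working with knee MRI: segment-derived surface meshes in, a fitted
recovery time constant out — together with synthetic phantoms so every
stage can be verified without patient data.

## What it computes

**Morphometry.** Post-activity bone models are aligned to the
pre-activity bone model by iterative closest point (ICP) registration.
Cartilage thickness is the distance from each cartilage mesh node to the
nearest bone mesh node, averaged within a 2.5 mm radius of 18 fixed
sampling sites (a 3 × 3 grid on each tibial plateau). Strain at time *t*
after activity is

    ε(t) = (h_post(t) − h_pre) / h_pre · 100%

(negative = compression).

**Recovery fit.** The mean strain trajectory is fit with the two-parameter
Kelvin–Voigt exponential

    ε(t) = A · exp(−B t)

and the characteristic recovery time is 1/B (minutes).

**Biphasic model.** The exponential is the first-order truncation of the
confined-compression biphasic creep series

    ε(t) = −(σ₀/H_A) · [1 − 2 Σₙ (1/Mₙ) exp(−(Mₙ/τ) t)],
    Mₙ = π²(n + ½)²,  τ = h²/(H_A k),  τ₀ = (4/π²) τ

linking the characteristic time τ₀ to tissue thickness *h*, aggregate
modulus *H_A* and permeability *k*.

**Relaxometry.** Per-pixel mono-exponential fits S(t) = S₀·exp(−t/T) over
spin-lock (T1rho) or echo (T2) times under a cartilage mask, summarised
as the mean relaxation time over valid masked pixels.

## Worked example

Characteristic time from published ex vivo creep parameters of tibial
plateau cartilage:

```r
library(cartrec)
p <- biphasic_parameters(h = 2.27, H_A = 0.65, k = 2.00e-15, units = "mm_MPa")
p
#> <biphasic_parameters> h = 2.270 mm, H_A = 0.650 MPa, k = 2e-15 m^4/Ns, sigma0 = 0 MPa
#>   time constant 3963.8 s, characteristic time 26.8 min
```

Fitting a measured strain trajectory (minutes post-activity vs percent
strain):

```r
traj <- strain_trajectory(c(10, 20, 30, 40, 50),
                          c(-3.9, -2.7, -1.8, -1.3, -0.8))
fit_kelvin_voigt(traj)
#> <kelvin_voigt_fit>
#>   A = -5.7270 %, B = 0.038108 /min
#>   characteristic recovery time 1/B = 26.24 min
#>   RMSE = 0.0376 (% strain), n = 5, converged = TRUE
```

The strain magnitude was about 3.9% ten minutes after activity and the
fitted exponential decays with a 26-minute time constant: the tissue has
recovered to roughly 1/e of its initial compression after that long.

A full pipeline run on a synthetic recovery sequence (meshes written to
disk, registered, measured, fitted) recovers the phantom's ground truth:

```r
seq <- make_recovery_sequence(
  phantom_spec("recovery_sequence",
               list(extent = c(20, 10), gap = 3, spacing = 0.5), seed = 4),
  A = -5, B = 0.04)           # true 1/B = 25 min
# ... write meshes, assemble run_config(), then:
rep <- run_pipeline(cfg)
rep$fit
#> <kelvin_voigt_fit>
#>   A = -5.0000 %, B = 0.040000 /min
#>   characteristic recovery time 1/B = 25.00 min
#>   RMSE = 0.0000 (% strain), n = 5, converged = TRUE
```

See `?run_pipeline` and the vignette source in `vignettes/` for the
modelling details. A command-line wrapper with subcommands (`register`,
`thickness`, `strain`, `fit-recovery`, `biphasic`, `relax-map`,
`phantom`, `run`) is provided in `inst/cli/cartrec.R`.

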