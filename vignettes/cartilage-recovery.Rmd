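---
title: "Measuring the in vivo characteristic recovery time of cartilage"
author: "cartrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the in vivo characteristic recovery time of cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartrec)
```

## The measurement

Articular cartilage is a biphasic material: a porous solid matrix
saturated with interstitial fluid. Under load the fluid is slowly pressed
out and the tissue creeps; after unloading it is drawn back in and the
thickness recovers. The time scale of that recovery is set by the
tissue's aggregate modulus $H_A$, permeability $k$ and thickness $h$, and
is therefore a mechanical property one would like to read out in vivo,
where mechanical testing is impossible.

`cartrec` implements a noninvasive protocol for doing so with MRI. A
subject is scanned before a walking bout (speed normalised across
subjects by the Froude number, $v = \sqrt{Fr \, L \, g}$, `froude_walk_speed()`),
then serially afterwards. Each scan is segmented into bone and cartilage
surface meshes (segmentation itself is outside this package; the phantom
generators stand in for it). The pipeline is then:

1. **Registration** (`icp_register`): each post-activity bone model is
   rigidly aligned to the pre-activity bone model, and the cartilage of
   that scan is carried along, so thickness is always sampled at the same
   anatomical locations.
2. **Thickness** (`nodewise_thickness`): the distance from each cartilage
   mesh node to the nearest bone mesh node. The node-to-node definition
   is deliberate — it matches how thickness is measured on segmented
   surface models — rather than a point-to-triangle distance.
3. **Site averaging** (`build_sampling_grid`, `site_thickness`): 18 fixed
   sampling sites, nine per tibial plateau in a 3 × 3 axial grid; all
   cartilage nodes within 2.5 mm (Euclidean) of a site are averaged.
4. **Strain** (`compute_strain`):
   $\varepsilon(t) = (h_{post}(t) - h_{pre})/h_{pre} \cdot 100\%$,
   averaged over the 18 sites per scan; negative = compression.
5. **Recovery fit** (`fit_kelvin_voigt`): the Kelvin–Voigt exponential
   $\varepsilon(t) = A e^{-Bt}$; the characteristic recovery time is
   $1/B$ minutes.

## The biphasic model and its first-order approximation

Confined-compression creep of a biphasic layer under constant stress
$\sigma_0$ follows the series

$$\varepsilon(t) = -\frac{\sigma_0}{H_A}\Big[1 - 2\sum_{n=0}^{\infty}
\frac{1}{M_n} e^{-(M_n/\tau)\,t}\Big], \qquad
M_n = \pi^2\big(n+\tfrac12\big)^2, \qquad \tau = \frac{h^2}{H_A k},$$

implemented in `biphasic_strain()`. The slowest mode ($n = 0$) decays
with the *characteristic time* $\tau_0 = (4/\pi^2)\,\tau$
(`characteristic_time()`, reported in minutes; `time_constant()` returns
$\tau$ in seconds). With only a handful of post-activity time points the
full series is not estimable, which is why the two-parameter exponential
is the fitted model: truncating the series at one term gives exactly
$A e^{-Bt} + \text{const}$ with $B = M_0/\tau$, so $1/B$ estimates
$\tau_0$ up to the neglected fast modes. The test suite verifies this
truncation identity numerically.

Plugging published ex vivo creep parameters for human cartilage into
$\tau_0$ gives reference values to compare in vivo fits against:

```{r biphasic}
characteristic_time(biphasic_parameters(2.27, 0.65, 2.00e-15,
                                        units = "mm_MPa"))
characteristic_time(biphasic_parameters(3.12, 0.79, 4.70e-15,
                                        units = "mm_MPa"))
```

## Relaxometry

T1rho and T2 relaxation times are computed per pixel from multi-spin-lock
/ multi-echo stacks by nonlinear least squares of
$S(t) = S_0 e^{-t/T}$ (`fit_pixel_decay`, `compute_map`). The
log-linear closed form only initialises the solver: log-linearisation
weights residuals by $1/S$ and is biased under additive noise. One binary
mask per stack (drawn on the first-acquired frame) is applied to all
frames. A subject is summarised by the arithmetic mean of T over valid
masked pixels from all slices.

## Tunable parameters

| parameter | default | unit | notes |
|---|---|---|---|
| grid radius | 2.5 | mm | averaging neighbourhood around each site |
| grid fractions | 25/50/75% | — | of each plateau's axial bounding box |
| ICP `tol` | 1e-6 | mm | stop when RMS improvement falls below this |
| ICP `max_iter` | 100 | — | non-convergence sets a flag, never errors |
| post-activity time labels | 10, 20, 30, 40, 50 | min | nominal scan-end times; configurable |
| Kelvin–Voigt bounds on B | (1e-6, 10] | 1/min | a rate pinned at a bound flags the fit |
| relaxometry validity cap | 10 × max(t) | ms | T above the cap is excluded from means |
| phantom mesh spacing | 0.5 | mm | see below |

## Design decisions

**Grid placement.** Only the 3 × 3-per-plateau layout of the sampling
system is prescribed by the protocol; exact coordinates are an
implementation choice. We split the cartilage footprint at the midpoint
of a configurable mediolateral axis and place sites at the 25/50/75%
fractions of each half's axial bounding box: deterministic,
mesh-resolution independent, and equivariant under reflection (tested).
Each site's height is taken from the axially nearest cartilage vertex so
the 2.5 mm ball sits on the surface. The grid is built once on the
pre-activity model and reused verbatim for all aligned post-activity
scans. The 2.5 mm neighbourhood uses Euclidean (not geodesic) distance —
the simplest reading of a radius criterion — and is evaluated per scan on
the aligned models.

**ICP.** Point-to-point metric over all vertices (optional deterministic
uniform subsampling), rigid motion re-estimated each iteration by the
SVD/Kabsch solution, convergence when the RMS improvement drops below
1e-6 mm. The iteration is seeded with a coarse principal-axes alignment
(centroids matched, covariance eigenvectors aligned, the best
proper-rotation sign choice by residual): plain ICP only converges from
within roughly one mesh spacing of the optimum, while the seeded version
recovers the motions of interest (up to ~10° and several mm) to
numerical precision. No outlier rejection of correspondences is applied.
The returned transform is guaranteed to leave the residual no worse than
the identity. Registration failures are reported through a convergence
flag, not exceptions.

**Missing sites.** A site whose neighbourhood captures no cartilage
vertex is flagged missing and excluded from per-scan means — never
imputed and never reported as zero thickness, which would bias strain.

**Kelvin–Voigt initialisation.** $A_0$ = first observed strain,
$B_0 = 1/\mathrm{median}(t)$; $A$ unbounded in sign so pathological
positive (swelling) trajectories fit rather than fail. There is no
offset term by default — strain is assumed to return to zero at full
recovery, exactly as the two-parameter model states; a three-parameter
variant with offset exists behind `offset = TRUE` as a diagnostic only.
Per-subject fits that drive $B$ into a bound are flagged not-converged
and a cohort analysis should treat them as failures rather than truncate
them silently.

**Series evaluation.** `biphasic_strain()` truncates adaptively when the
next term falls below 1e-12 (hard cap 10,000 terms). At $t = 0$ the
series converges only like $1/N$, so the value is returned through the
closed-form normalisation $2\sum 1/M_n = 1$, making $\varepsilon(0) = 0$
exact. The applied stress appearing in the series and the $\sigma_0$ of
the parameter set are the same quantity.

**Relaxometry validity.** Pixels with any non-positive intensity, a
diverged fit, or $T$ beyond 10× the last acquisition time are excluded
from subject means (and the count of exclusions is reported in the map
summary). Unbounded fits in flat-signal pixels otherwise destabilise the
mean. Mono-exponential only: no noise floor or stretched exponential.

## Phantoms: what they emulate and what they do not

The generators (`make_cartilage_phantom`, `make_recovery_sequence`,
`make_relaxation_stack`) produce inputs whose ground truth is known in
closed form; all module tests read truth from the stored sidecar record,
never by re-deriving it from generator internals, and noise is always
applied after the truth is recorded.

Mesh phantoms place bone and cartilage vertices on shared x/y columns
over a flat bone plate, so the node-to-node thickness equals the
analytic field exactly. Interior columns are jittered deterministically
(default 20% of spacing): a perfectly regular lattice is symmetric under
a 180° flip and aliases ICP correspondences — degeneracies real anatomy
does not have. Boundary nodes stay on the exact footprint so grid
placement is reproducible across resolutions. Default vertex spacing is
0.5 mm, keeping discretisation error well below a tenth of the ~0.1 mm
thickness changes being measured. Recovery sequences scale cartilage
height by $1 + \varepsilon(t)/100$ with $\varepsilon(t) = A e^{-Bt}$ and
optionally apply a rigid perturbation to each scan to exercise
registration. Relaxation phantoms use Gaussian or Rician noise (Rician
being the natural model for MR magnitude data).

What passing on phantoms does **not** show: robustness to segmentation
error, to non-rigid deformation between scans, to realistic knee
curvature and osteophytes, or to partial-volume effects at the cartilage
surface — phantom geometry is idealised and its noise models are simple.

## Problem sizes and runtime

The shipped tests run meshes of roughly 200–900 vertices per surface
(10 × 10 to 20 × 10 mm footprints at 0.5–1 mm spacing), five-scan
recovery sequences, 1000-replicate Monte-Carlo noise studies of the
Kelvin–Voigt fit, and 8 × 8 to 25 × 40 pixel relaxation stacks — sizes at
which the full suite completes in well under a minute while still
exercising every pipeline stage end to end. The same code handles
clinical-resolution meshes (tens of thousands of vertices); the
brute-force nearest-neighbour kernel is exact and O(N·M), which remains
comfortable at those sizes.

## Known limitations

- Node-to-node thickness slightly overestimates true surface distance on
  coarse meshes; that is the accepted definition here, and a
  point-to-triangle variant was deliberately not made the default.
- Tibial plateau grids only; femoral or patellar cartilage would need a
  user-supplied grid (`sampling_grid()` accepts one).
- Rigid registration only: activity-induced bone motion between scans is
  assumed rigid, and qMRI stacks are assumed already in the mask's frame.
- The five-point in vivo design cannot constrain more than two recovery
  parameters; fitting the full biphasic series to such data is out of
  scope by design.
- ASCII PLY/OBJ/STL only; binary meshes should be converted on export.
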