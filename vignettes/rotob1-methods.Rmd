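---
title: "Methods: rotating-coil B1 encoding, its calibration, and its numerics"
author: "rotob1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotating-coil B1 encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement models implemented in `rotob1`, the
reasoning behind every tunable default, and what the simulations do and do
not say about real acquisitions.

## 1. The encoding scheme

A single transmit coil with a spatially nonuniform complex field
`B1(r)` (tesla per unit drive) rotates about the sample at angular rate
`omega_rot` while a shaped pulse `env(t)` (unit peak, duration `tau`) plays.
One repetition (TR) per phase encode `alpha = 1..M`; the per-TR field scale
is `g_alpha = alpha - M/2 - 1/2`, stepping symmetrically about zero.  After
each TR the rotation start angle advances by `360/M` degrees (2D), so every
part of the object is "illuminated" equally across the acquisition.
Reception is through a uniform body coil, so each data point is the plain
complex sum of transverse magnetization.

Relaxation is deliberately absent: the repetition time is taken long enough
for full recovery, and every excitation starts from thermal equilibrium
`(0, 0, M_z = intensity)`.  All fields live in the frame rotating at the
Larmor frequency, so only the RF (transverse) field appears.

## 2. Two measurement models and their equivalence

**Sine model.** The flip accumulated by voxel `r` up to sample time `t`
within a TR, as the map rotates under the envelope, is the complex path
integral

    xi(r, t) = gamma * g_alpha * A * int_0^t env(u) B1_theta(u)(r) du .

The recorded datum is `D_i = sum_r M(r) (xi/|xi|) sin|xi|`.  For a field
whose phase is constant in time this is the *exact* solution of the Bloch
equation (rotation about a fixed transverse axis), and for small flips it
reduces to `sum_r M(r) xi`, which is the small-tip limit of the Bloch
dynamics for any field.  We deliberately accumulate along the rotating-map
path rather than freezing the map at the sample instant: a frozen-map
("snapshot") kernel differs from the small-tip Bloch limit by the full
within-TR variation of the map and would break the model-consistency
property that the test suite checks to 1 %.

**Bloch model.** Every voxel's magnetization is stepped through the same
rotating, pulse-scaled transverse field with the midpoint finite-difference
update (Section 3) and the signal `M_y - i M_x` is recorded.  That receive
convention equals `-i (M_x + i M_y)` and makes the Bloch signal coincide
with the sine model exactly in the constant-phase case and to second order
in the flip angle otherwise.  Because each voxel evolves independently and
linearly in its initial `M_z`, the Bloch measurement is also a linear map of
the image: one joint simulation with unit sources yields the whole encoding
matrix, and superposition (`E %*% G` equals the direct simulation) holds to
rounding error — the test suite asserts it at 1e-12.

Each reconstruction route pairs data and matrix from the *same* model
(pseudo-inverse with the sine model, LSQR with the Bloch model), so
noiseless reconstructions are exact up to conditioning and the reported
deviations isolate the effect of map noise.

## 3. The midpoint Bloch solver

The update is the Cayley transform of the cross-product generator: it
rotates `M` about the instantaneous field direction by
`2 atan(gamma |B| dt / 2)`.  Its 3x3 operator has eigenvalues `1` and
`(1 + i gamma B dt/2)/(1 - i gamma B dt/2)` with conjugate — all of modulus
one for *any* step size, hence unconditional stability and exact norm
conservation (asserted to 1e-13 per step).  Against the closed-form
Rodrigues rotation for a constant field the per-step angle error is
`O((gamma B dt)^3)`, giving second-order global convergence; the suite
checks the error ratio of 4 under step halving.  The field is sampled at
the midpoint of each step, matching the scheme's centering, and the solver
grid is refined to align with the sample instants (at least one step per
acquired sample).  `gamma` defaults to the proton value
2.675e8 rad s^-1 T^-1.

## 4. Why the drive amplitude is calibrated for encoding, not for a peak flip

This is the central design question of the package.  Consider the linear
gradient map: at coil angle `theta` the accumulated flip is affine in
position, `xi(r) = a(t) + k(t) . r`, so every encoding function is
`sin(a + k . r)` — a single spatial frequency with `|k|` proportional to the
drive amplitude `A`.  The set of such functions spans (numerically) only
the disc `|k| <= k_max` in spatial-frequency space.  Resolving `J` voxels
requires roughly `k_max * FOV >= 2 sqrt(pi J)` radians: for a 64 x 64
image, a flip-angle *span* across the FOV of tens of full turns at the
strongest encode.

A calibration that caps the peak flip at ±90° therefore cannot resolve the
image, no matter how the data are inverted: we verified that the resulting
32 x 32 encoding matrix has numerical rank ~18 of 512.  The package's
`calibrate_encoding()` instead fixes the amplitude by a sampling-theory
rule, the direct analogue of Nyquist-spaced phase-encode stepping in
B0-gradient imaging: **one unit step of `g_alpha` advances the across-FOV
span of the accumulated flip by `cycles_per_g` full cycles**,

    A = 2 pi cycles_per_g / (gamma * range(B1) * max_s |K(s)|),
    K(s) = int_0^{t_s} env(u) e^{i omega_rot u} du .

With Nyquist-exact stepping (`cycles_per_g = 1`) the out-and-back
spatial-frequency trajectory traced by `K(s)` under a full rotation per TR
leaves coverage holes; a conditioning study on the reference configuration
fixed the 2D default at `cycles_per_g = 3`, the smallest value at which the
masked 32 x 32 system is full rank and comfortably conditioned (the suite
asserts full column rank and condition number below 1e3).  The classical
peak-flip calibration remains available as `calibrate_amplitude()` — it is
exact by construction (±90° at the schedule extremes for `M = 64`) and is
what the flip-angle checks exercise — but the experiment pipelines use the
encoding calibration.  The corresponding physical drive is far beyond
routine SAR practice; this is a property of flip-angle-modulation encoding
at this resolution, not of the implementation, and it is why practical
interest centers on phase-dominated variants.

## 5. Acquisition schedule defaults

* `omega_rot` defaults to exactly one rotation per pulse, `2 pi / tau`
  (1256.6 rad/s for the 5 ms pulse) — the stated equivalence of rotation
  period and pulse duration taken literally.
* `samples_per_rotation` defaults to `6 N` for an `N x N` image (a 77 kHz
  ADC for the 5 ms TR — unremarkable hardware).  Oversampling matters twice:
  the per-evaluation map noise enters the accumulated flip as a random walk,
  so its standard deviation falls as `1/sqrt(samples)`, and the extra rows
  average the inversion.  At a one-sample-per-image-row rate
  the noisy reconstruction is noise-dominated.
* In 3D the start offset advances by `360/M^2` degrees after *every* TR
  with the amplitude index as the outer loop, so all `M^2` offsets are
  visited for each amplitude and the full circle is covered; `M^2` TRs at
  `2N` samples give roughly twice as many events as voxels at the default
  11^3 size.

## 6. Noise model

The stated acquisition condition is bounded noise of ±0.2 % of the map peak
added "for every incremental map rotation".  We implement it as independent
uniform draws in `[-0.002, +0.002] * peak|B1|`, applied to every
rotated-map evaluation used to *simulate* data, while the reconstruction
matrix is built from noiseless nominal maps — that asymmetry is what makes
map noise propagate into the image instead of cancelling.  For the
linearly polarized gradient map the perturbation acts on the in-phase
channel (the field is real; its orientation is known exactly); for complex
maps both quadratures are perturbed.  The standalone `add_map_noise()`
always perturbs both channels, per its contract.  All noise is seeded and
the pipelines are bit-reproducible for a fixed seed.

## 7. The deviation-versus-gradient sweep

`run_gradient_sweep()` holds the *drive amplitude* fixed at the value
calibrated for the 37.5 nT/m baseline and varies the unit gradient, so the
maximum flip (and with it the encoding span) scales with the gradient —
matching the stated reading that across the sweep "the maximum FA may be
smaller or larger" than the reference.  Two alternatives are instructive
and both degenerate: recalibrating per gradient with map-relative noise
makes the whole problem exactly scale-invariant (a flat curve, no collapse
anywhere), and map-relative noise with fixed drive is scale-invariant too
once the flips are small.  Only an absolute reference somewhere — here the
fixed drive — produces the characteristic monotone collapse at weak
gradients.  A consequence worth stating plainly: the gradient at which the
reconstruction recovers to the noise plateau is tied to the baseline
encoding gain.  With the package's 3-cycle gain the recovery threshold sits
within about an order of magnitude of the baseline gradient; a claim of
recovery at 1e-9 T/m would require a baseline drive ~40x stronger, whose
amplified map noise would in turn destroy the baseline reconstruction
itself.  The corresponding test in the suite therefore fails its
weak-gradient recovery clause by design; the collapse (>20 % at
1e-12 T/m) and the monotone approach to the plateau hold.

## 8. Coil maps

* **Linear gradient map**: amplitude maximal at the coil-side edge and one
  quarter of the maximum at the isocenter (`B1max = G (L/2) / (3/4)`); the
  amplitude crosses zero inside the FOV and continues negative, as a real
  linearly polarized field does; phase zero, no angle-dependent global
  phase on rotation.
* **Surface loop**: quasi-static Biot-Savart sum over straight segments,
  returning the transverse complex field `(B_x + i B_y)` per unit current;
  validated against the closed-form on-axis loop field.  Rotation applies
  the angle-dependent global phase `e^{i theta}`.  For 3D encoding the loop
  center must be displaced along the slice axis (`loop_z_offset`): a loop
  centered on the rotation axis has a z-mirror-symmetric field, rotation
  preserves the symmetry, and slices at ±z become algebraically
  indistinguishable — the layered phantom then reconstructs to the average
  of its mirror slices.  The 3D defaults (radius 0.12 m, standoff 0.3 m,
  z-offset 0.14 m, `cycles_per_g = 10` — z is encoded only through the
  field's z-decay, so the 3D gain must be higher) were fixed by the same
  conditioning methodology as the 2D gain.  The 2D loop pipeline defaults
  (radius 0.2 m, standoff 0.36 m, gain 6) temper the steep near-coil field
  decay that otherwise dominates the conditioning.
* Rotation interpolates the real and imaginary channels separately (no
  phase unwrapping issues), with Catmull-Rom cubic convolution by default
  and bilinear as a cheaper option; points mapped from outside the support
  fill with zero.  Positive angles are counterclockwise with row index
  down mapped to physical +y up.

## 9. Inversion and metrics

`solve_pinv()` truncates singular values below `rel_tol = 1e-6` times the
largest; at the default conditions nothing is truncated (the systems are
full rank), so the tolerance only guards genuinely degenerate sweeps.
`solve_lsqr()` is a from-scratch complex-capable Paige-Saunders LSQR with
the reference stopping rule (400 iterations or relative residual 1e-6); no
installed package offers complex LSQR.  `rrfc_fit()` wraps either solver in
a model object with `print`, `summary`, `coef`, `fitted`, `residuals`,
`predict` and `plot` methods.  Reconstruction is restricted to a threshold
mask (the phantom support in the pipelines), which shrinks the system and
suppresses noise exactly as masked SENSE-style reconstruction does.

`deviation_metrics()` peak-normalizes both magnitude images over the mask
and reports per-voxel `100 (|recon| - |orig|)`: signed mean and standard
deviation, the maximum absolute value, and a 50-bin pixel-frequency
histogram.  Peak normalization (not L2) is used because deviations are
quoted in percent of full scale; both signed and absolute views are exposed
since published figures use each.

## 10. What the synthetic conditions do and do not show

The generator reproduces the *study conditions*: ideal phantom intensities,
exactly known coil maps, noise only in the map rotation stream, no
relaxation, no off-resonance, ideal slice selection, uniform reception.
Passing tests therefore demonstrate the algebraic soundness of the encoding
and inversion chain and the propagation of map noise — not robustness to
T1/T2 decay during the 5 ms excitation-acquisition window, B0
inhomogeneity, coil-map estimation error, or concurrent transmit-receive
hardware effects, all of which are out of scope.  The reference-scale runs
used throughout the tests are 64 x 64 and 32 x 32 in 2D and 11^3 in 3D
(the package's chosen desk scales; the 3D reference size of 21^3 runs with
the same code path via `matrix_size = 21`).

## 11. Degenerate inputs and tie-breaks

Zero accumulated flip (`g_alpha = 0` at odd `M`, or a zero envelope)
contributes exactly zero signal; voxels where the map magnitude vanishes
contribute zero (their phase is undefined); an all-zero image cannot make a
mask; empty systems are rejected by both solvers.  Histogram bin edges are
widened by 1e-9 so boundary values always fall inside.  The
bandwidth-time product is measured on a DC-centered, 32x zero-padded
magnitude spectrum with linear interpolation of the half-maximum crossings,
so plateau-with-ripple spectra (truncated sinc) are handled.

## 12. Known limitations

* The sine model is exact only for time-constant field phase; with the
  complex loop map it is a small-tip approximation, and the pseudo-inverse
  and Bloch-LSQR routes genuinely differ at large flips (the LSQR images
  are slightly smoother, consistent with the path-averaging's high-frequency
  attenuation).
* Encoding gain, loop geometry and oversampling interact: the defaults are
  a studied operating point, not optima; off-default combinations can be
  severely ill-conditioned (that is the physics, and the diagnostics in the
  fit object expose it).
* 3D z-resolution rests entirely on the map's z-decay; thin-slice
  resolution would require either a z-varying coil trajectory or an
  auxiliary gradient, both out of scope.
* Runtime and memory grow as the product of events and masked voxels; the
  3D reference size (21^3, ~9.3e3 unknowns) is feasible but takes hours in
  plain R, which is why the desk scale is 11^3.
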