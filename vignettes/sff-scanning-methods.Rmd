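---
title: "Methods: scanned scattering-foil-free electron beams on curved phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanned scattering-foil-free electron beams on curved phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sffscan)
```

## The problem

Extensive superficial tumours on curved surfaces (the scalp is the
canonical case) are hard to treat well: photon arcs irradiate the whole
head, and a single broad electron field applied to a curved surface
delivers a heterogeneous dose because the effective depth changes with
off-axis position. One proposed alternative is to *scan* a small
scattering-foil-free (SFF) electron field over the surface, keeping every
beam perpendicular to the skin at a fixed source-to-surface distance
(SSD). Removing the scattering foil raises the per-MU output by an order
of magnitude and suppresses the bremsstrahlung photon tail, both of which
matter when thousands of small fields are delivered.

`sffscan` implements the computational side of that idea as a pipeline:

1. **beam curves** — read tabulated percent-depth-dose (PDD) curves and
   off-axis profiles, or synthesise them from a parametric model, and
   compute the standard beam-characteristic metrics (R50, practical range
   Rp, bremsstrahlung contamination, SFF/SF output ratio, 2%/1 mm curve
   agreement);
2. **kernel** — reconstruct a 3D single-beam dose kernel from a PDD plus
   lateral profiles as a separable product;
3. **phantom + scan** — build voxelized cylindrical/spherical water
   phantoms with a 1 cm bolus and a 5 mm target shell, enumerate
   surface-normal beam placements at a given angular (and, for cylinders,
   longitudinal) scanning resolution, and superpose the kernel;
4. **plan metrics** — normalize to the 95%/95% coverage rule and compute
   DVHs, conformity index (CI), homogeneity index (HI) and body mean dose;
5. **experiments** — resolution sweeps and finest-resolution plan
   summaries.

## The beam model

The synthetic generator exists so that every downstream stage is testable
without proprietary beam data; its closed form doubles as the oracle in
the test suite. The central-axis dose is

$$D(z) \propto (1 - e^{-\beta z})\,F(z) + t/100,\qquad
  F(z) = \operatorname{clamp}\!\Big(\tfrac12 - \frac{z - R_{50}}{2w},\,0,\,1\Big),$$

a saturating buildup times a quasi-linear distal falloff plus a flat
bremsstrahlung floor. The linear ramp is the textbook description of the
electron distal falloff — it crosses 50% at $R_{50}$, reaches the photon
floor at $R_{50} + w$, and makes the tangent construction of the
practical range exact. (An earlier logistic falloff was rejected: its
exponential tail is still ~2.5% of maximum one centimetre past Rp, which
is an order of magnitude above the photon floor of a real 6 MeV beam and
makes the contamination metric unable to recover the tail parameter.)

The lateral shape at depth $z$ is an axis-normalized error-function pair
with half-width $\tfrac{f}{2}\,\frac{\mathrm{SSD}+z}{\mathrm{SSD}}$ (the
geometric projection of the field) and edge spread
$\sigma(z) = \sigma_0 + g\,z^{1.5}$, a Fermi–Eyges-like growth law.

Defaults (6 MeV SFF, `beam_preset("6mev-sff")`):

| parameter | default | unit | rationale |
|---|---|---|---|
| `r50` (broad beam) | 2.3 (SFF) / 2.1 (SF) | cm | so the 2×2 cm curve lands on the published 2.2 / 2.0 cm |
| field-size R50 shift | 0.40 @ 1×1, 0.10 @ 2×2, 0.03 @ 4×4 | cm | loss of lateral scatter equilibrium in small fields |
| `buildup_rate` β | 3.5 | /cm | buildup limb ≈ 85% of max at 0.5 cm, a textbook 6 MeV value |
| `falloff_width` w | 0.75 | cm | distal gradient ≈ 67%/cm, floor at ≈ 2.95 cm |
| `tail_level` | 0.07 (SFF) / 0.49 (SF) | % of max | published contamination values |
| `sigma0` | 0.15 (SFF) / 0.20 (SF) | cm | source/collimator penumbra at the surface |
| `sigma_growth` | 0.3 | cm/cm^1.5 | σ ≈ 0.6 cm at 1.5 cm depth, plausible for 6 MeV in water |
| `output_scale` | 20.88 (SFF) / 1 (SF) | – | published output increase |
| `d_max` | 1.3 | cm | nominal dose-maximum depth (metadata) |

Two deliberate model properties to be aware of:

* The saturating-exponential buildup times the ramp produces a broad
  plateau rather than a sharp peak at `d_max`; matching the buildup limb
  was preferred over forcing the peak position, which would require an
  unphysically slow buildup (≈ 63% of max at 0.5 cm).
* The tail is added *after* normalizing the electron component, so a
  generated relative curve has maximum exactly 100 and tail exactly
  `tail_level` — the contamination metric recovers the parameter exactly.

What the generator does **not** emulate: Monte Carlo statistical noise
structure (available only as optional white noise via `noise_sd`),
profile horns and asymmetries, energy spectra, and any in-patient
heterogeneity. Passing tests therefore demonstrate the correctness of
the pipeline's geometry, superposition and metrics — not the fidelity of
any particular clinical beam.

## Kernel reconstruction

`build_kernel_separable()` forms $D(x,y,z) = \mathrm{PDD}(z)\,p(x;z)\,p(y;z)$
with the axis-normalized lateral shape $p$. This separability is the
principal fidelity limit: real kernels are not exactly separable, and the
axis-normalized form does not conserve slice energy for fields comparable
to the penumbra width (the z-slice energy monotonicity property is
asserted for the 4×4 cm field only).

Profiles tabulated at several depths are linearly interpolated in depth
after scaling off-axis coordinates by the divergence factor
$(\mathrm{SSD}+z)/(\mathrm{SSD}+z_{\mathrm{profile}})$; outside the
tabulated range the nearest profile is carried with the same scaling
("clamp"), or an error is raised. A single profile is extended by fitting
the erf-pair edge model to it: edge spread from the 80–20% penumbra
(1.683 σ for an erf edge), half-width by inverting the FWHM equation
under that spread, and σ(z) growth fitted through the reference depth.

The default kernel grid is 2.5 × 2.5 × 2 mm voxels (the plan calculation
grid), extent `field + 4 cm` laterally and 8 cm in depth, with the
lateral product truncated below 0.1% of the axis value. For the 2 cm
field the erf-pair shape at mid depths is still a few percent of the axis
value at the grid edge, so the extent — not the 0.1% cut — is the binding
truncation there; the superposition oracle in the test suite accounts for
the kernel's defined extent.

## Phantoms, scanning lattices, superposition

Phantoms are voxelized on a centred grid (default 2.5 × 2.5 × 2 mm; a
5 mm "coarse" preview grid is used for sweep trend studies). Masks follow
the voxel-center rule: target shell `(R−0.5, R]`, bolus `(R, R+1]`, body
`[0, R−0.5]`, cylinders restricted to `|z| < length/2`. The voxelized
target volume is within 3% of the analytic shell volume on the default
grid.

**Cylinders** are scanned on an angle × axial-station grid: angles step
by Δθ (a divisor of 360°), stations step by Δz symmetrically about the
midplane. `place_beams_cylinder()` keeps stations inside the phantom
length by default; *plans* built by the experiments module extend the
stations by `field/2 + 2 cm` past each end (`overscan`). Without
overscan the end slices of the target receive roughly half the plateau
dose, D95 collapses, and CI/HI lose all meaning (CI ≈ HI ≈ 1.9 on the
R10 cylinder); the margin of half a field plus ≈ 3σ of penumbra keeps the
axial coverage flat to well under 1%.

**Spheres** use a uniform-surface-density latitude-ring lattice: polar
rings every Δθ with $n = \lceil 360 \sin\theta / \Delta\theta\rceil$
evenly spaced beams per ring (single placements at the poles). Rings
close exactly, the surface separation never exceeds the polar separation,
and the beam density per unit area is as uniform as a single resolution
parameter allows. A divisor-of-360 azimuthal step was rejected: it makes
the ring density jump by up to 2× between colatitudes, which shows up
directly as dose sawtooth versus latitude.

`superpose()` maps the beam-frame kernel into the phantom frame per
placement (depth axis along the beam direction, origin at the entry
point) and samples it trilinearly at phantom voxel centers, without
dose-mass renormalization; the pointwise closed-form oracle in the test
suite bounds the resulting error at 3% of the maximum dose on a coarse
cylinder. Numerical details that matter:

* laterally the kernel is zero-padded (values fall linearly to zero over
  one voxel past the outermost sample) — clamping instead would smear a
  spurious dose halo around the truncation edge;
* along depth, coordinates within half a voxel outside the sampled range
  are clamped (the surface plane holds ≈ zero dose, the deep end the
  flat tail);
* the kernel's lateral axes are an arbitrary orthonormal completion of
  the beam direction, legitimate because kernels are x/y symmetric;
* SSD is constant by construction and the kernel already encodes the
  60 cm divergence; no per-beam inverse-square rescaling is applied,
  replicating flat-phantom-kernel superposition onto curved surfaces.

## Plan metrics

Plans are normalized so that at least 95% of the target volume receives
95% of the 30 Gy prescription: the scale is $0.95\,R_x / D_{95}$, with
$D_{95}$ the exact sort-based percentile (the smallest dose received by
at least 95% of the voxels). DVHs are used for plotting and export only.

* `conformity_index()` = (patient volume receiving ≥ 95% of prescription) /
  (target volume). The removable bolus is excluded from the numerator by
  default — it is not tissue, and including it would make the index
  incommensurate with its usual magnitude; the choice is a function
  argument.
* `homogeneity_index()` = D5% / D95% on the target.
* `body_mean_dose()` averages over the body mask (phantom minus target
  shell minus bolus).

## Resolution sweeps and the breakpoint rule

`run_resolution_sweep()` runs one normalized plan per combination of
phantom, field size and resolution (angular sweeps at the reference
longitudinal resolution and vice versa). `breakpoint_check()` converts an
angular resolution into a surface beam separation on the *bolus* surface,
`(R + 1)·Δθ·π/180`, finds the smallest swept resolution whose separation
exceeds the field size, and flags whether CI there exceeds the
finest-resolution CI by more than 10%.

A caveat the sweeps make visible: "quality degrades exactly when the
separation exceeds the field size" is an idealization for beams whose
penumbra is small compared to the field. For a 1×1 cm 6 MeV field the
penumbra σ at target depth is comparable to the field itself, so
neighbouring beams still overlap substantially when the separation
slightly exceeds 1 cm, the baseline CI is already penumbra-limited, and
the sharp collapse appears one or two resolution steps beyond the
geometric breakpoint — first in HI and body mean dose, then in CI.

## Problem sizes

The package's own studies use: full 2.5 × 2.5 × 2 mm grids for the
finest-resolution plan summaries (≈ 0.4–1.2 M phantom voxels, ≈ 22 000
beams per cylinder plan and ≈ 41 000 per sphere plan at 1°/3 mm), and the
5 mm preview grid for sweep trend studies and breakpoint checks. The
superposition core is C++; a full-resolution cylinder plan takes tens of
seconds on one core.

## Known limitations

* Separable kernels: no profile horns, no asymmetry, no obliquity
  correction inside the kernel; energy is not conserved per slice for
  penumbra-dominated (small) fields.
* Homogeneous water only; no densities, no couch/gantry kinematics, no
  delivery-time model.
* The synthetic beam parameters are calibrated to published summary
  characteristics of one 6 MeV beam pair, not fitted to full curves;
  plan-level indices computed from them should be read as
  order-of-magnitude faithful, with residual differences of a few
  hundredths in CI/HI expected versus plans built from measured kernels.
* The sphere scanning lattice is one defensible reading of a
  single-parameter scanning resolution; published sphere results may use
  a different lattice.
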