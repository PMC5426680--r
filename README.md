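# sffscan

Dose simulation for **scanned scattering-foil-free (SFF) electron beams**
on curved surfaces — the treatment concept of sweeping a small electron
field perpendicular to the patient surface at constant SSD, as an
alternative to photon arcs for extensive superficial tumours (e.g. skin
cancer of the scalp).

The package is aimed at medical-physics researchers who want to study the
plan quality attainable with surface-normal electron scanning without a
Monte Carlo treatment-head model: it reconstructs single-beam dose
kernels from tabulated (or synthetic) beam data, superposes them over
scanning lattices on cylindrical and spherical phantoms, and evaluates
the resulting plans with standard dose-volumetric indices.

## What it computes

**Beam characteristics** from percent-depth-dose (PDD) curves and
off-axis profiles:

* R50 — distal depth of the 50% dose, the beam-quality surrogate;
* practical range Rp — intersection of the steepest distal tangent with
  the bremsstrahlung tail;
* photon contamination — mean tail dose over `[Rp + 0.5, Rp + 1.5]` cm,
  in % of the dose maximum;
* SFF/SF output ratio, profile FWHM, and a 2%/1 mm composite
  (dose-difference / distance-to-agreement) curve comparison.

**Scanned plans.** A separable single-beam kernel
`D(x, y, z) = PDD(z) · p(x; z) · p(y; z)` is superposed over
surface-normal placements — an angle × axial-station grid on cylinders,
a uniform-density latitude-ring lattice on spheres — and the plan is
normalized so that 95% of the target shell (surface to 5 mm depth, under
a 1 cm bolus) receives 95% of the 30 Gy prescription. Reported per plan:

* CI = V(≥ 0.95 Rx) / V(target) (conformity; 1 is ideal),
* HI = D5% / D95% on the target (homogeneity; 1 is uniform),
* body mean dose (normal-tissue burden),

plus full DVHs and resolution sweeps of all three against the angular
(1–20°) and longitudinal (0.3–2 cm) scanning resolutions.

A parametric 6 MeV beam model (buildup × quasi-linear distal falloff +
flat bremsstrahlung tail; erf-pair lateral profiles with Fermi–Eyges-like
spread growth) generates beam tables and kernels calibrated to published
SFF/SF beam characteristics, so the whole pipeline runs without any
external data. See `vignette("sff-scanning-methods")` for the model, its
parameters and its limits.

## Worked example

```r
library(sffscan)

## beam characteristics of the synthetic 6 MeV SFF beam (2 x 2 cm field)
sff <- beam_preset("6mev-sff", field_size = 2)
pdd <- synth_pdd(sff)
sprintf("R50 %.2f cm, Rp %.2f cm, tail %.3f %%",
        r50(pdd), practical_range(pdd), photon_contamination(pdd))
#> "R50 2.20 cm, Rp 2.95 cm, tail 0.070 %"

## a scanned plan on a 10 cm cylinder (5 mm preview grid, 5 deg / 3 mm)
kernel  <- build_kernel_synthetic(beam_preset("6mev-sff", field_size = 4),
                                  grid = kernel_grid(4, spacing = c(0.5, 0.5, 0.5)))
phantom <- build_phantom("cylinder", radius = 10, spacing = c(0.5, 0.5, 0.5))
beams   <- place_beams_cylinder(phantom, dtheta = 5, dz = 0.3, overscan = 4)
plan    <- plan_scan(kernel, beams, phantom, rx = 30)
plan
#> <sff_plan> cylinder R10, 4392 beams, rx 30 Gy
#>   CI 1.108  HI 1.061  body mean 4.65 Gy  target D95 28.50 Gy
```

The plan is read as: the 95%-of-prescription isodose volume exceeds the
target shell by ~11% (CI 1.108), the hottest-to-coldest target ratio is
1.06, the target D95 sits exactly at 28.5 Gy by the coverage rule, and
normal tissue receives 4.65 Gy on average for a 30 Gy surface
prescription. `glance(plan)` returns the same as a one-row tibble,
`tidy(plan)` per-structure dose statistics, `autoplot(plan)` the DVHs.

Full-resolution studies go through the experiments layer:

```r
cfg <- experiment_config(phantoms = tibble::tibble(kind = "cylinder", radius = 10),
                         resolution = "full")
run_table2_sff(cfg)          # finest-resolution (1 deg / 3 mm) plan summary
run_resolution_sweep(cfg)    # CI / HI / body mean vs scanning resolution
```

A thin command-line wrapper over the same functions ships in
`inst/cli/sffscan.R` (`beam-metrics`, `beam-compare`, `synth-beams`,
`table2`, `sweep`).

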