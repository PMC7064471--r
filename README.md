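# scaffseed

Cell-seeding simulation on 3D-printed lattice scaffolds.

When a cell suspension is pipetted into a culture well holding an
open-cell scaffold, the first seconds decide where the cells attach —
and the attachment pattern drives everything the construct later
becomes.  `scaffseed` models that process end to end for two lattice
designs (a cubic cross-link lattice with 1000-um windows and a
truncated-octahedron lattice with 240-um windows, both 7.9 x 7.9 x 6 mm)
so the designs can be compared by predicted cell distribution and
seeding efficiency before any wet-lab work.

The model couples three stages:

* **Filling flow** — laminar incompressible flow on a 64^3 staggered
  grid over the 15 mm x 11 mm well, with a volume-of-fluid front
  tracking 0.5 ml of medium injected from the side wall over 5 s
  (continuity + Navier-Stokes, pressure projection to a relative
  residual of 1e-6).
* **Cell transport** — Lagrangian tracking of 15-um cells
  (mass flow 8.18e-10 kg/s for 5 s, about 2.3e3 cells) under drag with
  relaxation time `tau_r = 4 rho_c d^2 / (3 mu C_D Re)` (Morsi-Alexander
  drag bands; exact exponential integration of the drag term, stable at
  `dt >> tau_r`).
* **Wall impingement** — every cell-scaffold impact classified by the
  dimensionless impact energy
  `E^2 = (rho V_pn^2 d / sigma) / (min(h_o/d,1) + delta_bl/d)` with
  `delta_bl = d/sqrt(Re)`: stick below E = 16, spread to a wall film up
  to 57.7, splash into six drops above; rebound only above the critical
  transition temperature `T_c = Tc* T_s` (never at 37 C).  Well walls
  reflect; only the scaffold traps.

The headline summary is the seeding efficiency
`Phi = 100 * N_attached / N_injected` and the lateral attachment
profile in six 1.3-mm bins from the injection side.  A confocal-image
stage (channel split, threshold, erode/dilate, grid count) reproduces
the matching microscope analysis and is validated against a synthetic
two-channel image generator.

## Worked example

```r
library(scaffseed)

measure_geometry(build_scaffold("cubic", voxel = 0.05))
#> Scaffold geometry metrics (cubic)
#>   V = 75.11 mm^3 of 374.46 mm^3 overall
#>   S = 595.53 mm^2
#>   porosity = 79.94%   SA:V = 7.93 mm^-1
#>   max pore side 1000 um, diagonal 1414 um
```

`V` and `S` are the structure volume and surface of the parametric
cubic lattice; porosity and the surface-to-volume ratio follow as
`(1 - V/V_overall) * 100%` and `S/V`.

A full coupled run (about 8 minutes on one core):

```r
res <- run_seeding(seeding_config("cubic", seed = 1))
res
#> Cell seeding simulation: cubic
#>   t = 6.0 s, injected 2314 cells
#>   attached live 1197 (stick 1197, spread 0), dead 0, suspended 1117
#>   seeding efficiency 51.7%
```

About half the injected cells end attached to the cubic lattice; the
rest stay suspended in the pooled medium once the flow comes to rest.
`lateral_bin_counts(res$particles, origin = res$scaffold_origin[1])`
shows the attachment falling off with distance from the injection side,
and the same run on `"truncated_octahedron"` yields a higher efficiency
— the fine TO lattice intercepts nearly every streamline that enters
it.

Command-line wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/build-scaffold.R --design to --out to.stl --metrics to.csv
Rscript inst/cli/simulate.R --design cubic --seed 1 --out out/
```

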