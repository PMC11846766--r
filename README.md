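# ossiforge

A continuum-based particle simulation of endochondral ossification — the
process by which a cartilage template becomes bone — focused on how the
growth plate survives between the primary (diaphyseal) and secondary
(epiphyseal) ossification centers. It is intended for computational
biomechanics and developmental-biology researchers who want a cell-resolved,
mechanistically explicit sandbox for Ihh/PTHrP-mediated growth-plate
regulation.

## The model in brief

Each material point is one chondrocyte plus its matrix, carrying a position,
volume, and deformation gradient decomposed as **F** = **F**ᵉ**F**ᵍ (elastic ×
growth). Tissue mechanics follow a compressible neo-Hookean energy

ψ = Jᵍ ( λ/8 ln²I₃ + μ/2 (I₁ − 3 − ln I₃) ),   Jᵍ = det **F**ᵍ,

solved quasi-statically each 0.02-day increment on a background grid
(material point method, quadratic B-spline interpolation, 50 µm spacing)
with slip symmetry planes. Cells cycle (T_cycle = 1 d, exponential G0 with
rate 5/d), divide at mid-cycle along the local Ihh gradient, and grow —
columnar (unidirectional) when proliferative, isotropic when
(pre)hypertrophic. Ihh and PTHrP obey

∂C/∂t = D∇²C + P − kC,  D = 1 µm²/s, k = 0.005/s,

integrated with an exponential-integrator implicit scheme whose fixed point
is the exact screened steady state. Differentiation is threshold-driven:
quiescent → proliferative at C_Ihh > 1, proliferative → prehypertrophic at
C_Ihh > 30 **and** C_PTHrP < 0.5 (the PTHrP gate), timed transitions into
hypertrophy and a 50/50 apoptosis/calcified-matrix terminal fate,
perichondrium → bone collar at C_Ihh > 10. Periarticular cells always
produce PTHrP in proportion to total tissue Ihh; resting-zone cells start at
secondary-ossification onset and ramp up over a maturation time T_mat — the
parameter the package's experiments sweep.

## Worked example

```r
library(ossiforge)

# emergent zone structure of a steady 1-D growth plate
zones <- run_1d_growth_plate(preset_1d(seed = 1))
zones
#> <oss_zones> steady combined proliferative+hypertrophic length: 223 um
#>   (proliferative 51, prehypertrophic 45, hypertrophic 128)
```

The column self-organizes into the familiar layering — quiescent cartilage
ahead of the front, then proliferative (51 µm), prehypertrophic (45 µm) and
hypertrophic (128 µm) zones, trailing calcified tissue. The combined
proliferative + hypertrophic length of ~223 µm sits inside the 200–400 µm
range that the Ihh thresholds were chosen to produce, and is what
`scripts/acceptance.R` reports as the 1-D calibration.

```r
# secondary ossification, reduced scale: with vs without resting-zone PTHrP
a <- run_simulation(preset_coarse(seed = 1, T_mat = 0.5))
b <- run_simulation(preset_coarse(seed = 1, days = 5.8, resting_enabled = FALSE))
a$outcome$fused  # FALSE — resting-zone PTHrP keeps the plate intact
b$outcome$fused  # TRUE  — without it the two centers fuse
```

A thin command-line driver is installed with the package
(`inst/cli/ossiforge`): `ossiforge run --preset coarse --seed 1`,
`ossiforge sweep --tmat 0.5,2,8,12`, `ossiforge metrics checkpoint.rds`.
Runs can emit legacy-VTK point snapshots, CSV census/division logs and RDS
checkpoints (`out_dir` in the config, or `--out`).

See `vignettes/growth-plate-maintenance.Rmd` for the full model description,
parameter table, numerical choices and the limits of the reduced-scale
presets.

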