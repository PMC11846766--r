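---
title: "Modeling growth-plate maintenance during secondary ossification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling growth-plate maintenance during secondary ossification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ossiforge)
```

## The biological problem

Long bones form by endochondral ossification: a cartilage template is
progressively replaced by bone. A primary ossification center (POC) forms in
the mid-diaphysis; later a secondary center (SOC) forms in the epiphysis.
Between them survives the growth plate, a layered disc of cartilage --
resting, proliferative, prehypertrophic and hypertrophic zones -- that drives
longitudinal growth. Its survival is not obvious: both centers advance by
recruiting adjacent chondrocytes into hypertrophy, so something must stop
their fronts from consuming the plate.

`ossiforge` implements a cell-resolved continuum model of this process built
around the Ihh--PTHrP negative feedback loop. Prehypertrophic and early
hypertrophic cells secrete Indian hedgehog (Ihh), which (i) drives quiescent
chondrocytes into proliferation, and (ii) stimulates parathyroid
hormone-related protein (PTHrP) production. PTHrP in turn blocks the
proliferative-to-prehypertrophic transition. The model's central hypothesis
is about *where and when* PTHrP is made: periarticular producers are present
from the start, while resting-zone chondrocytes switch on PTHrP only at SOC
initiation, ramping up as the SOC matures over a time `T_mat`. The package's
experiments ask whether that ramp is fast enough to shield the plate.

## Model structure

### Mechanics: material points with multiplicative growth

Each material point represents one cell plus its matrix: position, volume,
and a deformation gradient decomposed multiplicatively as `F = F^e F^g`.
Growth is imposed on `F^g`; the elastic part responds through a compressible
neo-Hookean energy density

psi = J^g ( lambda/8 ln^2 I3 + mu/2 (I1 - 3 - ln I3) ),

with `J^g = det F^g` and `I1`, `I3` invariants of `C^e`. Lame parameters come
from the per-point Young's modulus and Poisson ratio (chondrocytes 1 kPa /
0.4; calcified matrix 1000 kPa / 0.3; bone collar 100 kPa / 0.3).

Every increment (`dt` = 0.02 days) the package solves quasi-static
equilibrium on a background grid (spacing 50 um) with quadratic B-spline
interpolation: total elastic energy is minimized over grid node
displacements by L-BFGS-B, subject to slip conditions on the three mirror
planes (ghost nodes are slaved to their images, so symmetry is exact).
Points are then advected, `F <- (I + grad u) F`, and volumes follow
`det F`. The quasi-static choice reflects the time scales: growth is many
orders of magnitude slower than elastic relaxation, so inertia is
irrelevant. The solver tolerance (projected gradient 2.5e-3 kPa um^2,
relative energy 1e-8) and the iteration cap are config keys; the
reduced-scale preset caps iterations at 25 per increment, which changes
zone-level outcomes by less than the run-to-run stochastic variation
(tightening the cap 5x leaves type censuses identical in spot checks).

The 1-D growth-plate column is special-cased: a laterally free column with a
basal slip plane admits the exact stress-free solution, in which each
segment's length is its reference length times the axial growth stretch and
`F = F^g` exactly. The driver therefore uses the closed-form stacking update
there; the grid solver is exercised by the 3-D drivers and by 3-D column
fixtures in the test suite, where stress-free uniform growth and
tip-displacement identities are asserted against the analytic values.

### Cell cycle, division and growth schedules

Proliferative chondrocytes cycle through S/G2/M/G1 with `T_cycle` = 1 day,
then rest in G0 for an exponentially distributed time with rate `R_prolif` =
5/day (inverse-CDF sampling). Division happens once per cycle, halfway
through, splitting a point into two children of half volume placed
symmetrically along the division axis; the axis follows the local Ihh
gradient (with a deterministic tie-break: previous axis, then a seeded
random unit vector). Columnar growth is unidirectional along the same axis,
ramping so that the growth determinant doubles across one cycle -- division
is volume-neutral per generation. Prehypertrophic and hypertrophic cells
enlarge isotropically; the stretch ramps linearly in `t_H` to a volume
multiple of 8 across `T_prehyp + T_hyp` (both phases enlarge; the multiple
and its window are config keys since the literature constrains the endpoint
better than the trajectory). Cells that differentiate while mid-cycle finish
that cycle (dividing at most once); cells caught in G0 never re-enter.

### Signaling

Ihh and PTHrP share diffusivity `D` = 1 um^2/s and degradation `k` =
0.005/s, giving a screening length `sqrt(D/k)` = 14.1 um. Ihh production per
cell ramps from 0 to 1 pM/um^3/s over prehypertrophy (`T_prehyp` = 0.5 d)
and back to zero over the first half of hypertrophy. Periarticular PTHrP
production is `P_max * Ihh_total / Ihh_max`, coupling production to the
current whole-tissue Ihh content; resting-zone production multiplies this by
`min(t_SOC / T_mat, 1)`.

Two implementation choices deserve emphasis.

**The reaction-diffusion scheme.** The solver advances
`dC/dt = D lap C + P - k C` with an exponential-integrator step:
`(I - g D L) C_new = e^{-k dt} C + g P`, `g = (1 - e^{-k dt})/k`. This is
unconditionally stable, preserves non-negativity, is exact for pure decay,
and -- unlike naive splitting or plain backward Euler -- its fixed point
satisfies the *exact* screened steady state `D lap C + P = k C` for any
substep size. That matters because the biology is quasi-steady: `1/k` = 200 s
versus 1728 s per mechanics increment, so the concentration field the
thresholds see is essentially the steady screened profile, and a scheme that
distorts it (naive splitting inflates the screening length by
`sqrt(k dt / (1 - e^{-k dt}))`, a factor 1.56 at our substep) systematically
accelerates differentiation fronts. Symmetry planes are zero-flux (mirror
stencils), the far field is held at zero concentration at least two cells
beyond the tissue, and an explicit forward scheme is available behind
`chem_scheme = "explicit"` for cross-checks.

**Chemistry grid resolution.** The background-grid spacing (50 um) is more
than three screening lengths, so a 50 um chemistry grid cannot resolve the
exponential profile (its discrete e-fold distance is ~19 um) and widens
every Ihh halo, roughly doubling front speeds. The chemistry grid spacing
is therefore its own key, `chem_h`. The 1-D calibration preset resolves the
profile (`chem_h` = 12.5 um); the reduced-scale 3-D preset uses 25 um; the
full-resolution preset keeps the shared 50 um grid. Resolution matters in
both directions: the maintenance mechanism is a standoff between the Ihh
halo of the advancing fronts and the PTHrP counter-halo of the resting
zone, both with e-fold distance 14.1 um. Under-resolving the morphogen
field (50 um chemistry at 25 um points) lets the smeared Ihh halo flood the
resting band before its production ramps up, while over-coarse material
points (25 um spacing with resolved chemistry) starve the wave -- the
threshold C = 30 becomes unreachable one cell layer ahead of the sources
and differentiation goes extinct. 20 um points with 25 um chemistry is the
coarsest combination we found that reproduces the dichotomy, which is why
`preset_coarse()` sits there.

**Total-Ihh bookkeeping.** `total_ihh()` integrates the Ihh concentration
over tissue-occupied nodes and multiplies by 8 (the octant models one-eighth
of the tissue). The feedback ratio uses this total expressed per initial
cell volume (10^3 um^3) against the normalization constant `ihh_max` =
1.5e6, and the production is capped at `P_pthrp_max` -- the constant is, by
its definition, the maximum total ever attained, so the ratio is clamped to
one. The per-cell unit convention is the one under which the stated
normalization constant is of the right order for this tissue; it is exposed
as `ihh_unit_volume` so other conventions can be explored.

### Differentiation

Transitions are strict-inequality threshold rules evaluated on B-spline
interpolated concentrations at each point: quiescent (and resting
producers) become proliferative above `C_Ihh` = 1; proliferative cells
become prehypertrophic above `C_Ihh` = 30 *only if* `C_PTHrP` < 0.5 (the
PTHrP gate); prehypertrophic cells become hypertrophic after `T_prehyp`;
hypertrophic cells terminate after `T_prehyp + T_hyp` into apoptotic or
calcified-matrix points with equal probability; perichondrium becomes bone
collar above `C_Ihh` = 10. Terminal states are absorbing (no remodeling).
During terminal transitions the Young's modulus ramps log-linearly over
`T_apop`/`T_calcif` -- a linear ramp across three decades would concentrate
the stiffness change in the last instants -- and the Poisson ratio ramps
linearly; apoptotic points share the calcified-matrix target since both
constitute the calcified zones. Resting producers are otherwise quiescent
cells and may themselves be recruited into proliferation
(`resting_can_proliferate` disables this).

## Geometry and initial conditions

The tissue is the distal portion of a mouse metatarsal: a cylinder (radius
300 um, height 300 um) capped by a dome rising 340 um, modeled as the
portion of an ellipsoid (semi-axes 330, 330, 250 um) whose center sits 90 um
above the cylinder top -- between cylinder top and equator the head
overhangs the shaft, as real metatarsal heads do. One-eighth of the tissue
(x, y, z >= 0) is discretized on a cell-centered 10 um lattice with
inclusive membership, which yields 42,861 material points, and the surface
is sampled by a deterministic equal-area golden-ratio scheme at a frozen
density of one point per (7.8308 um)^2, which yields 5,491 massless boundary
markers. Initial typing: a one-spacing shell on the lateral wall is
perichondrium, the shell over the articular dome is periarticular PTHrP
producers (periarticular wins where they overlap), the interior is
quiescent, and a 40 um-radius cluster at the epiphysis centroid is flagged
as the future SOC. At Day 0 the basal slab (one spacing) becomes
prehypertrophic (POC); at Day 2 the flagged cluster does (SOC, `t_SOC = 0`)
and the resting zone -- quiescent points between the top of the
proliferative zone and the bottom of the SOC seed, within the plate's radial
footprint -- is tagged as PTHrP producers.

## What the reduced-scale runs do and do not show

The reference resolution (10 um spacing, 42,861 points) is intended for long
batch runs. The test suite and the worked examples use two reduced
configurations chosen to fit continuous integration:

* `preset_1d()` -- the growth-plate column at full 10 um spacing, 8 days.
  Fast (seconds) and quantitative: the emergent steady combined
  proliferative + hypertrophic length is 223 um with the reference
  parameters, inside the 200-400 um range used to calibrate the Ihh
  thresholds, and is insensitive to the seed (the plateau oscillates by
  +/- 5 um).
* `preset_coarse()` -- the full 3-D capsule at 20 um spacing (5,355 points
  initially, roughly doubling by run end), 5.4-5.8 days, about 7-8 minutes
  per run. This reproduces the qualitative dichotomy -- growth-plate
  survival with early resting-zone PTHrP (the resting producers persist to
  run end) versus fusion of the ossification centers without it (day 4.9 at
  this scale; the full-resolution figure value is 5.8) -- but absolute
  front speeds and zone widths carry discretization error, so quantitative
  claims (the critical `T_mat` and its 0.168/day slope, penetration at
  `T_mat` >= 8, the ~30 um subarticular cartilage) are reserved for the
  full resolution. At this scale a shallow penetrated fringe (one or two
  converted layers at the band's lower edge) appears even at fast
  maturation, so the sweep's penetration ordering is not claimed here.

The synthetic fixtures used by the unit tests (`make_block()`,
`make_column()`) are regular lattices with uniform moduli; they exercise the
solvers' identities (partition of unity, linear-field reproduction,
stress-free growth, conservation at division) rather than biological
realism. Passing them shows the machinery is faithful to the model's
mathematics, not that the model captures any particular bone.

## Worked example

```{r example}
library(ossiforge)

# 1-D calibration: emergent zone structure of a steady growth plate
zones <- run_1d_growth_plate(preset_1d(seed = 1))
zones
#> <oss_zones> steady combined proliferative+hypertrophic length: 223 um
#>   (proliferative 51, prehypertrophic 45, hypertrophic 128)

# secondary ossification with and without resting-zone PTHrP
with_rz <- run_simulation(preset_coarse(seed = 1, T_mat = 0.5))
without <- run_simulation(preset_coarse(seed = 1, days = 5.8,
                                        resting_enabled = FALSE))
with_rz$outcome$fused    # FALSE: the plate survives to run end
without$outcome$fused    # TRUE: the centers fuse at day 4.9

# maturation-rate sweep (reduced scale)
sw <- run_tmat_sweep(preset_coarse(seed = 1), c(0.5, 8, 12))
sw$outcomes
```

## Numerical choices and limitations

* Tolerances: equilibrium projected-gradient 2.5e-3 kPa um^2; concentrations
  are clipped at -1e-9 (an error beyond that). Chemistry uses 4 substeps per
  increment by default; with the exponential-integrator scheme the steady
  profile is substep-independent, so this only controls transient accuracy.
* Degenerate inputs: empty POC slabs and double SOC initiation are errors;
  an empty resting zone is a warning and the run proceeds as the
  no-resting-PTHrP case; gradient ties in the division axis fall back
  deterministically.
* The model omits external loading, bone remodeling, vascularity, receptor
  kinetics, and any mechanosensitive feedback; the perichondrium is a
  passive shell; boundary points are massless markers for surface metrics
  and visualization only.
* Fusion is formalized as 6-connected flood-fill contact of the calcified
  (matrix + apoptotic) occupancies of POC and SOC on the background grid;
  penetration as any proliferative-to-hypertrophic point strictly inside
  the materially tracked resting band. Published figure-level day values
  depend on the visual criteria of their authors; ours are stated by these
  definitions.
* The spatial discretization of the morphogen field is the main source of
  quantitative error at reduced scale; see the chemistry-resolution note
  above.
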