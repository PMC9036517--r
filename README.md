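# curvsense

Curvature-sensing analysis for proteins on coarse-grained curved lipid
bilayers.

Peripheral membrane proteins with an amphipathic helix and a PIP2-binding
site feel two opposing pulls on a membrane of fixed curvature: hydrophobic
anchors are attracted to the convex shoulder, where lipid packing defects
expose tail groups, while the basic PIP2 site is attracted to the concave
band, where curvature-sorted PIP2 accumulates. `curvsense` is for
simulators and modellers who want to quantify that competition from bead
trajectories: it extracts the membrane shape, converts protein
centre-of-mass traces into normalized radial statistics, profiles
per-residue lipid contacts, and — because such trajectories are rarely
deposited — ships a synthetic generator that emulates the whole system so
every stage is testable.

## The model at the core

The radially averaged membrane height around a central pore is fitted by
a five-parameter sigmoid

    h(r) = a + d (1 + exp(-b (r - x0)))^(-c)

whose analytic derivatives (generated symbolically, never hand-copied)
give the signed curvature and radius of curvature

    K = h'' / (1 + h'^2)^(3/2),   RoC = 1 / |K|

with K > 0 on the concave (pore-side) band and K < 0 on the convex
shoulder. Protein and lipid localization is read from radial
distribution functions normalized by exact clipped annular area and by
each species' global area density, so uniform occupancy reads RDF = 1
and curvature preference appears as a peak inside a curvature-labelled
band. The synthetic protein moves by Metropolis Monte Carlo on the
two-term radial energy

    U(r) = -w_hydro * A_convex(r) - w_pip2 * rho_PIP2(r)   [kT]

which makes curvature sensing a tunable balance of hydrophobic and
electrostatic attraction.

## Worked example

```r
library(curvsense)

cfg    <- generator_config(seed = 42)                  # 97.5% PC + 2.5% PIP2
frames <- lapply(0:4, function(t) generate_membrane_frame(cfg, time = t))

prof <- radial_height_profile(frames, cfg$pore_center)
fit  <- fit_sigmoid(prof)
fit
#> sigmoid_fit: converged
#>        a        b        c        d       x0
#> 12.03152  0.51042  1.11500  2.97451  8.23926
#>   rss = 0.02378 nm^2 over 50 points

curv <- curvature_and_roc(fit, seq(0, 25, by = 0.1))
classify_regions(curv)[c("most_concave_r", "most_convex_r")]
#> $most_concave_r
#> [1] 5.7
#> $most_convex_r
#> [1] 11.2

run_pipeline(run_config(generator = cfg))
#> sensing_report:
#>   verdict: convex_sensing (peak 11.12 nm, region convex)
#>   PIP2 enriched in the concave region
#>   top tail-contact residues: 52, 10, 6, 17, 44
```

The fitted profile recovers the generator's geometry (transition midpoint
near 8.5 nm, ~3 nm deep), the curvature bands sit near 6 nm (concave) and
11 nm (convex), PIP2 is enriched on the concave side, and the default
(full-helix-like, `w_hydro = 5`) protein still peaks in the convex band
at ~11 nm despite the PIP2 pull — the curvature-sensing phenotype. The
five hydrophobic anchor residues (6, 10, 17, 44, 52) dominate the
tail-contact profile. Lowering `w_hydro` to 2 (the split/short-like
presets) flips the verdict to `concave_localized` on PIP2 membranes;
`run_condition_matrix()` tabulates all six preset × composition
conditions.

## Layout

- `R/` — generator, membrane profiling, localization statistics,
  contact/tilt analysis, pipeline orchestration
- `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code)
- `vignettes/curvature-sensing.Rmd` — the methods vignette: model,
  parameters, assumptions, numerical choices, limitations
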