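---
title: "Quantifying membrane curvature sensing with curvsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane curvature sensing with curvsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvsense)
```

## The scientific problem

Peripheral membrane proteins such as ANTH-domain endocytic adaptors carry
two competing membrane attachments: hydrophobic residues of an amphipathic
helix that insert into packing defects, and a cluster of basic residues
that binds the anionic lipid PIP2. On a membrane held at fixed curvature —
for example a coarse-grained bilayer draped over a nanoporous substrate,
so that a concave band (a bowl, as seen from the solvent) sits closer to
the pore centre than a convex shoulder — the two attachments pull in
opposite directions. Exposed hydrophobic defects are concentrated on the
convex shoulder, while curvature-sorted PIP2 accumulates in the concave
band. Whether a protein statistically enriches at convex curvature
("curvature sensing") therefore depends on the balance of the two
interactions.

`curvsense` implements the analysis stack used to read this balance off
particle trajectories — and, because such trajectories are rarely
deposited, a synthetic generator that emulates the full system so that
every analysis stage is testable end to end.

## The membrane model

The radially averaged height of the curved membrane is modelled by a
five-parameter generalized-logistic (Richards) curve

$$h(r) = a + d\,\bigl(1 + e^{-b (r - x_0)}\bigr)^{-c},$$

with $a$ the pore-side plateau (nm), $d$ the depth of the transition
(nm), $b$ the steepness (nm$^{-1}$), $c$ a dimensionless asymmetry
exponent, and $x_0$ the transition midpoint (nm). For $c = 1$ the curve
passes through the midpoint of its plateaus at $x_0$, and $d = 0$ is the
exact flat-membrane limit. Signed curvature and radius of curvature
follow from the plane-curve formula

$$K(r) = \frac{h''(r)}{\bigl(1 + h'(r)^2\bigr)^{3/2}}, \qquad
  \mathrm{RoC}(r) = \frac{1}{|K(r)|}.$$

Two design choices matter here:

* **Symbolic derivatives.** $h'$ and $h''$ are generated from the model
  expression by symbolic differentiation (`stats::D`) at package build.
  There is no hand-transcribed derivative to drift out of sync with the
  height model; tests verify the analytic forms against central finite
  differences to a relative sup-norm discrepancy below $10^{-4}$.
* **Sign convention.** $K > 0$ where the membrane curves toward the
  solvent-exposed side — the concave bowl as seen by a protein above the
  top leaflet; $K < 0$ on the convex shoulder. This is stated once and
  used by every module.

Points with $|K|$ below `flat_threshold` are labelled `flat`. The default
0.01 nm$^{-1}$ (RoC beyond 100 nm counts as flat) is a package choice;
"flat" has no canonical definition at finite resolution, so the
threshold is exposed in the configuration.

### Fitting

`fit_sigmoid()` estimates the five parameters by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`). The initial guess is deterministic:
plateau means give $a$ and $d$, the steepest point of the binned profile
gives $x_0$, the plateau gap over the maximal slope gives $b$ (a
logistic's maximal slope is $bd/4$), and $c$ starts at 1. A constant
profile short-circuits to the exact flat limit rather than asking the
optimizer to collapse a sigmoid. Because $(a, b, c, d, x_0)$ are not
always identifiable from a finite window, the contract is on *function
values*: the fitted curve, not the parameter vector, and the returned
fit never has a larger residual sum of squares than the deterministic
start. Fit failure after all fallback starts raises an error carrying
the optimizer diagnostics — never a silent constant.

A geometric caveat documented by the tests: a monotone sigmoid has
vanishing curvature at its plateaus, so it can only represent a
constant-curvature arc on its flank. The circular-arc oracle (radius
5 nm) is therefore fitted on a flank window; the recovered RoC is
accurate to ~3% there, and would not be at the arc's apex.

## Localization statistics

Protein centre-of-mass positions are reduced to radial distances
$r = \sqrt{(x - x_c)^2 + (y - y_c)^2}$ from the pore centre
(16, 20 nm in the default geometry). Three views are produced:

* **Probability histograms** (100 bins over 0–25 nm) and **50 × 50
  heatmaps** of $(|x - x_c|, |y - y_c|)$ over 0–16 × 0–20 nm. Both are
  normalized so all bins sum to exactly 1; out-of-range points are
  counted and reported, never silently dropped.
* **Radial distribution functions.** Each bin's count is divided by its
  annular area and by the species' global area density (total count /
  box area), so uniform occupancy reads RDF = 1 in every bin. Annuli
  that extend past the rectangular box are clipped by the *analytic*
  circle–rectangle intersection area — with sampled clipping the
  bulk = 1 property would only hold approximately. Bins beyond half the
  shortest box vector in xy (16 nm) are computed but flagged as not
  displayed.
* **Kernel density estimates** of the raw radii, Gaussian kernel with
  Scott's-rule bandwidth $\hat\sigma n^{-1/5}$ (overridable), evaluated
  on a grid wide and fine enough to integrate to 1 within $10^{-3}$.

A statistical point that shapes both the implementation and the tests:
the innermost annuli are tiny (the first 0.25 nm bin is ~0.2 nm²), so
their RDF values carry large Poisson shot noise at any realistic sample
size — with $10^5$ uniform points the first bin expects ~15 counts and
fluctuates by ~26%. Per-bin "RDF $\approx$ 1" assertions are therefore
only meaningful on bins with adequate expected counts, and peak calling
in the pipeline pools counts and areas over a short window (5 bins)
before taking the argmax. Pooling counts *and* areas together leaves a
uniform distribution unbiased. `peak_location()` itself defaults to the
bare argmax with ties broken toward smaller radius and reported.

## The synthetic generator

The generator emulates the study conditions: a 32 × 40 × 33 nm box, a
radially symmetric membrane over a central pore at (16, 20) nm, 4000
lipid sites split evenly between leaflets, composition 100% PC or
97.5% PC + 2.5% PIP2 with PIP2 confined to the solvent-exposed top
leaflet, and 8 replica protein traces per condition. Defaults place the
concave band near $r \approx 6$ nm and the convex band near
$r \approx 11$ nm by deriving the profile parameters from the taper
radii (6 and 11 nm) and a 3 nm pore depth; headgroup roughness is
isotropic Gaussian with $\sigma = 0.3$ nm, a typical coarse-grained
headgroup fluctuation scale. Each lipid contributes a headgroup, a
glycerol bead and two tail beads offset toward the midplane of a 4 nm
bilayer.

**PIP2 sorting.** A top-leaflet site becomes PIP2 with probability
proportional to $e^{w_K K(r)}$, normalized so the expected PIP2 count is
`pip2_fraction` × lipid sites. Positive $w_K$ enriches PIP2 in the
concave band and depletes it on the convex shoulder. The default
$w_K = 6$ nm yields a concave/convex density ratio of ~2.5 for the
default curvature amplitude, a moderate sorting contrast.

**Protein energy model.** The protein centre of mass moves on the
radial energy surface

$$U(r) = -\,w_\mathrm{hydro}\,A_\mathrm{convex}(r)
         \;-\; w_\mathrm{pip2}\,\rho_\mathrm{PIP2}(r) \quad [k_BT],$$

where $A_\mathrm{convex}(r) = \max(0, -K(r))/\max(-K)$ is a normalized
convexity score and $\rho_\mathrm{PIP2}(r)$ the relative local PIP2 area
density estimated from the generated frames (kernel-smoothed counts over
clipped annulus areas, normalized to a maximum of 1). The three protein
presets differ only in the hydrophobic term, scaled to the number of
anchoring residues: `full` ($w_\mathrm{hydro} = 5$, anchors L6, I10,
V17, Y44, M52), `split` (2; L6, I10) and `short` (2; Y44, M52), while
$w_\mathrm{pip2} = 6$ (four engaged lysines at 1.5 $k_BT$ each) is
identical across presets, reflecting an unmodified PIP2-binding site.
These weights were fixed from the residue counts when the model was
designed; they make curvature sensing a genuine competition — on a
PC-only membrane every preset seeks the convex shoulder, while with
PIP2 present only the full preset's hydrophobic pull
($5\,k_BT > w_\mathrm{pip2}\,\Delta\rho \approx 3.6\,k_BT$) overcomes
the concave-band attraction.

**Sampling.** Traces are Metropolis Monte Carlo walks over the periodic
box: an isotropic Gaussian step (σ = 1.5 nm) mixed with, at probability
0.05, a uniform independence jump across the whole box. Both proposal
components are symmetric, so the plain Metropolis acceptance
$\min(1, e^{-\Delta U})$ is exact; the jumps are what keep chains mixing
between the concave and convex wells, which are separated by a several-
$k_BT$ barrier at the preset weights. With both weights zero every
proposal is accepted and the walk is exactly uniform over the box — the
anchor for the RDF = 1 bulk convention. Reproducibility: one master
seed; frame and replica streams are derived from it by fixed integer
offsets, and identical configurations give bit-identical outputs without
touching the caller's RNG state.

What the generator does *not* emulate: molecular dynamics. There is no
force field, no solvent, no membrane elasticity or protein-induced
remodelling, no binding kinetics — occupancies are equilibrium samples
of a radial free-energy model. Passing tests demonstrate that the
*analysis machinery* is correct and that the qualitative phenotype logic
is internally consistent; they say nothing about force-field accuracy on
real systems.

## Contacts and orientation

`count_contacts()` counts (residue bead, target bead) pairs within a
cutoff under minimum-image periodic distance. The cutoff default of
0.6 nm is the conventional contact-tool default; contact conclusions on
synthetic data are stable over 0.5–0.7 nm, which the tests sweep.
Hydrophobic targets are tail-species beads and PIP2 targets are
PIP2-headgroup beads; glycerol belongs to neither group. Residue classes
follow the standard palette (hydrophobic L, I, A, V, M, Y; basic K, H,
R). `average_contact_profile()` reports per-residue means over all
frames of all replicas and retains per-replica means; the pooled mean
equals the frame-weighted replica average exactly. The bundled 55-residue
sequence is synthetic — a documented stand-in placing the canonical
anchors and lysines at their conventional indices, not a deposited
sequence.

The tilt measure is the angle between the protein's largest-variance
principal axis (orientation fixed by a named residue pair) and the
membrane normal. It is a declared stand-in for a full rotation-matrix
orientation analysis and is labelled as such.

## The pipeline and its verdict

`run_pipeline()` chains generate → profile → localize → contacts and
reports a per-condition verdict: `convex_sensing` if the protein RDF
peak falls in the convex band of the *fitted* curvature profile,
`concave_localized` if it falls in the concave band, `indeterminate`
when no peak rises more than `peak_min_excess` (default 0.25) above the
bulk level — the guard that keeps a zero-weight (freely diffusing)
protein from being assigned a random peak bin. Outputs are delimited
tables plus a JSON manifest with the configuration hash and seed;
rerunning the same configuration reproduces the outputs byte for byte.

```{r, eval = FALSE}
mat <- run_condition_matrix()
mat
#>   protein membrane peak_r peak_region           verdict
#> 1    full       PC 11.125      convex    convex_sensing
#> 2   split       PC 11.125      convex    convex_sensing
#> 3   short       PC 11.375      convex    convex_sensing
#> 4    full  PC/PIP2 11.125      convex    convex_sensing
#> 5   split  PC/PIP2  6.375     concave concave_localized
#> 6   short  PC/PIP2  5.125     concave concave_localized
```

## Problem sizes and numerical choices

The default study conditions are 20 membrane frames of 4000 lipids,
8 replicas × 10⁴ Metropolis steps per condition, 0.5 nm height-profile
bins, 100 radial histogram bins over 0–25 nm and a 0.1 nm curvature
grid. The Metropolis–Boltzmann equivalence checks use a single 10⁵-step
chain against direct summation of $e^{-U}$ over a 0.1 nm xy grid of the
box. Unit tests run reduced sizes (hundreds to thousands of lipids and
steps) chosen so that every assertion sits several standard deviations
inside its tolerance under the fixed test seeds.

Degenerate inputs are handled explicitly rather than numerically:
constant profiles short-circuit the fit, all-equal KDE samples raise a
bandwidth error with guidance, empty selections and empty histograms
raise named errors, flat RDFs raise the no-peak flag, and coincident
protein beads are a degenerate-geometry error for the tilt measure.

## Known limitations

* Radial symmetry is assumed throughout the analysis even though the
  box is rectangular; all statistics are radial, and annulus clipping
  handles the box boundary exactly.
* Radial distances apply no periodic minimum-image convention; the pore
  is centred and the displayed range (≤ 16 nm) stays inside the box.
  Off-centre pores would need that convention revisited.
* The energy model is radial: any angular structure (e.g. protein
  crowding, membrane defects at specific azimuths) is outside the
  model.
* PIP2 sorting is treated as substrate-geometry-driven and
  protein-independent; protein-induced PIP2 clustering is not modelled.
* The pooled height profile fits all frames together; a per-replica fit
  mode is available but dispersion across replica fits is not
  propagated into the curvature bands.
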