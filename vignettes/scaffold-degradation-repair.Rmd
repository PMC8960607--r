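---
title: "Modelling scaffold degradation in osteochondral defect repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scaffold degradation in osteochondral defect repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strutsim)
```

`strutsim` couples a poroelastic finite-element model of a loaded femoral
condyle with mechanoregulated cell dynamics and four phenomenological laws of
polymer scaffold degradation. This vignette documents the model, its
assumptions, the numerical choices, and the design decisions taken where the
problem statement left the design open. It states no result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Geometry and materials

The osteochondral defect is an axisymmetric cylinder of radius and depth
5 mm, discretised into a 40 × 40 lattice of 0.125 mm elements. The lattice's
z axis points from the defect base at the cancellous-bone interface (z = 0)
to the articular surface (z = 5 mm); all I/O uses this convention. The
scaffold consists of three vertical annular struts of 0.5 mm wall thickness
spanning the full depth. Their radial positions are not fixed by the
reference geometry, so the default centres them at 1.25, 2.5 and 3.75 mm —
evenly spaced, away from both the symmetry axis and the defect wall — and
they are configurable. Each strut occupies four lattice columns; the two
exterior-facing columns are labelled *surface*, the interior two *bulk*.

Tissue constants come from a fixed table (`load_tissue_table()`): poroelastic
subchondral bone, cancellous bone, cartilage, fibrous and granulation tissue;
a transversely isotropic meniscus; hyperelastic healthy cartilage; and the
scaffold material (50% porosity, 1,000 MPa, permeability 3.63·10⁻⁸ mm/s,
cell diffusivity 0.01 mm²/day). Permeabilities are hydraulic conductivities
in mm/s and are converted to Darcy mobilities with the fluid specific weight
9.74·10⁻⁶ N/mm³.

Two table entries need interpretation:

* **Neo-Hookean D1.** The healthy-cartilage strain-energy constants are
  C10 = 2.14 MPa and D1 = 0.399. Although the table labels D1 in MPa, a
  neo-Hookean D1 is conventionally an inverse modulus; we adopt the Abaqus
  convention K = 2/D1. The package linearises the healthy cartilage about
  zero strain (μ = 2·C10 = 4.28 MPa, K = 5.01 MPa), giving E ≈ 10.0 MPa and
  ν ≈ 0.168 — numerically identical to the poroelastic-cartilage row used
  for newly formed cartilage, which corroborates the interpretation. A
  large-strain neo-Hookean option is deliberately not implemented: the
  healthy cartilage lies outside the defect and its linearisation does not
  touch any reported quantity, while a Newton loop would complicate the
  solver substantially.
* **Grain bulk modulus 0.** A zero grain bulk modulus (granulation tissue,
  scaffold) is read as "incompressible grains", the usual meaning of an
  unspecified grain stiffness. The Biot coefficient is fixed at α = 1
  throughout: deriving α from 1 − K_drained/K_grain would give a negative
  value for subchondral bone (whose drained bulk modulus, 14,167 MPa,
  exceeds its tabulated grain modulus of 13,920 MPa), which is unphysical.
  Grain and fluid compressibility (fluid bulk modulus 2,300 MPa) enter the
  storage term only.

## Degradation laws and the day convention

All four modalities act on two per-element quantities, the material modulus
`E_t` and the volume fraction `N_t` (initially 1,000 MPa and 0.5). Molecular
weight is assumed proportional to the modulus and is never stored
separately.

* **Surface erosion**: N_t decreases by k_N per day in exposed columns only;
  each strut has two erosion fronts, one per face. The part of a day's
  decrement exceeding a column's remaining fraction carries over to the
  column it exposes, so a strut of width w columns finishes in exactly
  (w/2)·N₀/k_N days. E_t of an element is untouched until the element is
  fully eroded, at which point it is set to zero.
* **Linear bulk**: E_t decreases by k_E per day homogeneously; once
  E_t ≤ 10% of E₀, N_t additionally decreases by k_N in all elements.
* **Autocatalytic bulk**: interior (bulk) columns degrade at twice the
  surface rates, for both k_E and k_N, with per-element erosion onset.
* **Exponential bulk**: E_t = E₀·e^(−k_e·t) homogeneously, stepped as an
  exact multiplicative update; erosion as for linear bulk.

The rate presets pair three speeds (complete degradation in 25, 50 or 100
days) for the linear modalities with two experimentally derived exponential
rates: k_e = 0.003/day for porous PCL/PDLLA-like scaffolds and
k_e = 0.022/day with k_N = 5%/day for porous PLGA-like scaffolds.

A milestone "day X" is the first integer day at or after the continuous-time
crossing (ceiling). On the day a modulus trajectory crosses the erosion-onset
threshold, only the fraction of that day past the crossing erodes volume.
This makes daily stepping agree exactly with the closed-form calendar
(`milestones()`), which the test suite asserts for every preset; it also
makes the linear presets internally consistent, with modulus and volume
fraction reaching zero on the same day. Zero rates yield an infinite
("never") sentinel. Volume fractions are clipped to zero below 10⁻¹², which
absorbs the accumulation error of decimal rates in binary floating point.

Volume-fraction accounting uses element counts (area fractions in the
axisymmetric section), not annular ring volumes: the defect-wide bookkeeping
of the 40 × 40 matrix is area-based, and the initial scaffold share of the
defect is then 30% of elements × 50% porosity = 15% by construction.

## Scaffold stiffness

The standalone scaffold stiffness uses a ring-stack uniaxial model: each
strut column is a parallel spring of annular cross-section 2πr·Δr with
height-averaged effective modulus E_t·N_t, calibrated once so the undegraded
scaffold returns K₀ = 2,445 N/mm exactly. K₀ is an input rather than a
derived quantity because the strut radii are a design choice; the implied
total cross-section K₀·L/E_scaffold,0 ≈ 24.45 mm² is consistent with three
0.5 mm struts at the default radii (23.6 mm²). Homogeneous degradation
reduces the model to K = K₀·(E_t·N_t)/(E₀·N₀); under non-homogeneous
degradation the columns differ and the stack is summed explicitly. A
finite-element cross-check of a homogeneous annular column under axial load
(at ν = 0) is part of the test suite. Surface-erosion and bulk trajectories
coincide to round-off before erosion onset and differ by at most
(0.02τ − 0.004τ²)·K₀ during the erosion window — a closed-form bound peaking
at 2.5% of K₀ — because half of each strut's width is surface and half bulk.
Geometric nonlinearity and post-buckling are not modelled here; slenderness
failure is handled by the driver's failure surrogate.

## Poroelastic stage

All tissues are isotropic poroelastic except the transversely isotropic
meniscus and the linearised healthy cartilage. The condyle is meshed with
structured quadrilaterals: the defect at `fe_factor` lattice elements per FE
element edge (default 4, i.e. a 10 × 10 defect sub-mesh of 0.5 mm), the
surroundings at ≤ 0.625 mm, within a 10 mm radius and 10 mm height plus a
1.5 mm meniscus layer. Elements are Taylor–Hood: biquadratic displacements
with bilinear pore pressure, an inf–sup stable pairing that emulates the
behaviour of 8-node continuum pore-pressure quadrilaterals without claiming
bit equality. Time integration is backward Euler with 5 steps per load
phase.

Boundary conditions replace the reference model's hard frictionless contacts
with bonded interfaces and a rigid support: the tibial plateau fixes the
vertical displacement under the meniscus layer, the symmetry axis fixes the
radial displacement, the 0.637 MPa pressure acts on the top cut of the
cancellous bone, and during the consolidation step the pore pressure is zero
at the free cartilage edge of the outer boundary. The meniscus layer is
retained (rather than condensed away) because the axial compliance of the
support controls how much of the applied load actually deforms the defect
fill; with a rigid support directly at the articular surface the defect is
almost completely shielded and the strain field loses the base-to-surface
gradient that drives the tissue pattern.

Per day, the octahedral shear strain γ (from element-centre strains via the
principal-strain formula) is sampled at the end of the compression ramp, and
the fluid speed v is the per-element maximum of the Darcy flux magnitude
over the consolidation window, where drainage makes the flow peak. The
sampling instants are a documented choice; the reference does not state its
own. The stimulus S = γ/a + v/b (γ in %, a = 3.75%, b = 3·10⁻³ mm/s) is
classified by the half-open threshold partition, so every finite S ≥ 0 maps
to exactly one class.

Solver verification gates in the test suite: a confined-compression patch
test exact to 10⁻⁸ relative, a single-element oedometer solution to 10⁻⁶,
and the Terzaghi single-drainage consolidation series matched within 1% at
three time factors.

## Cells and homogenisation

MSCs fill the base row to its effective capacity at day 0 and re-enter
continuously: the cancellous edge is held at capacity throughout the run
(the bone supplies progenitors for as long as the defect heals). Migration
is one implicit (backward Euler) finite-volume diffusion step per day with
harmonic-mean face diffusivities and zero-flux boundaries elsewhere; the
scheme conserves mass exactly with closed boundaries and respects the
maximum principle, and the homogenised diffusivity field makes the scaffold
slow down invading cells (0.01 mm²/day) relative to granulation tissue
(0.8 mm²/day).

The daily population update applies all multipliers to the counts at the
start of the day: in an element whose stimulus favours a tissue, the
matching phenotype becomes `old·1.05 + 0.05·MSC_old`, the two other
phenotypes shrink by 15%, and MSCs become `0.95·MSC_old·1.15`; resorption
elements lose 10% of osteoblasts; counts are continuous. Capacity is
`100·(1 − N_t)` cells — an undegraded strut element hosts 50 cells, growing
back as the scaffold erodes. Clipping resolves the one ordering ambiguity:
MSC growth cannot push an element past its capacity (MSCs are capped at
capacity minus the differentiated phenotypes), and if the phenotypes alone
exceed a shrunken capacity they are scaled down proportionally.

Composite element properties follow the capacity-weighted average over
{bone, cartilage, fibrous, scaffold}, with granulation tissue (including
MSCs) as the remainder, applied to the elastic modulus, Poisson ratio,
permeability, grain bulk modulus and cell diffusivity. Permeability is
averaged arithmetically — the weighted-average rule is followed literally
even though harmonic averaging is physically more common for series flow.
The void ratio is not part of the rule and is taken from the dominant
species. Formed tissues map to the subchondral-bone, poroelastic-cartilage
and fibrous-tissue rows of the table. Resorbed bone reverts to granulation
behaviour implicitly, through the declining osteoblast load. The rule is
linear and convex by construction, which the property tests assert.

## Failure surrogate

In the reference model, mechanical failure manifests as non-convergence of
the FE analysis under excessive scaffold deformation — behaviour that is
specific to a solver. `strutsim` uses an explicit surrogate with
configurable thresholds: (i) solver divergence; (ii) octahedral shear strain
above `gamma_cap` (default 100%) in any element still holding scaffold;
(iii) Euler buckling of a freed thin strut wall. The third criterion is the
discriminating one: autocatalysis hollows each strut into two disconnected
single-column (0.125 mm) walls once the bulk completes, whereas surface
erosion consumes the struts from the faces inward and plain bulk degrades
all columns in lockstep, so neither ever produces a width-1 load-bearing
wall. A freed wall is checked against the critical strain
π²t²/(12(kL)²) with effective length factor k = 2 (a sway column:
restrained at the defect base, braced above only by compliant granulation
tissue). Exact failure days depend on the original solver's convergence
behaviour and are not a target; the modality-level pattern — autocatalysis
fails shortly after its bulk completes at every speed, slow surface erosion
and slow bulk never fail — is asserted by the regression suite, and the
surrogate's thresholds are configuration, not constants.

## Reduced problem sizes and what the tests show

The full configuration is the 40 × 40 lattice with `fe_factor = 4` (a
10 × 10 defect FE sub-mesh); one 125-day run takes on the order of a minute
on one CPU, and the regression suite runs the five modality/speed scenarios
at this size. `make_fixture("small")` provides an 8 × 8 lattice with a
single two-column strut and rates chosen so modulus and volume fraction
vanish together within its 5-day horizon, exercising every pipeline stage
in seconds. The coarser FE resolution smears the strain field within each
4 × 4 block of lattice cells; milestone, stiffness and homogenisation
results are independent of it, but the tissue maps are only
resolution-converged qualitatively. Passing tests therefore demonstrate the
internal consistency of the model and its agreement with the analytic
calendar, the calibrated stiffness values and the classical poroelastic
benchmarks — not a validated prediction of in vivo repair: the model
inherits the reference simplifications (no pH or degradation by-product
biology, no extracellular-matrix stabilisation, clear-cut degradation
modalities, one iteration per day, continuous cell counts).

## Known limitations

* Contacts are bonded and the tibial plateau is rigid; day-5 scaffold
  stiffness values differ from a 3D contact FE by a fraction of a percent,
  and exact failure days are not reproduced.
* The S-class area map is razor-thin at the resorption/bone boundary
  (S = 0.01), so small mechanical changes can swap a few percent of the
  defect between those classes late in a run; the equilibrium regression is
  therefore formulated on the amounts of formed tissue (cells per
  phenotype), the quantity the equilibrium statement describes.
* Strut radial positions, the meniscus thickness and the γ/v sampling
  instants are documented defaults, not published values.
* No haptotaxis or chemotaxis, no matrix-production kinetics, no
  remodelling outside the defect, and no 3D (non-axisymmetric) scaffold
  architectures.
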