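---
title: "Anoxic microenvironments on sand grains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anoxic microenvironments on sand grains: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Permeable (sandy) shelf sediments are flushed by pore-water flow, so their
upper layers are well oxygenated — yet they sustain substantial
denitrification, an anaerobic process. The resolution of this paradox lives
at the scale of a single sand grain: grain surfaces carry a patchy mosaic of
net O2-consuming microbial colonies and net O2-producing phototrophs. Where
respiration outpaces diffusion of O2 through the diffusive boundary layer
(DBL) around the grain, micrometre-scale anoxic niches form on the grain
surface even while the surrounding pore water stays oxic, and denitrifiers
in those niches remove fixed nitrogen.

`grainDBL` implements the full computational chain behind that argument:

1. **grain geometry** — grain-size statistics, the surface-to-volume ratio
   `S_VT = 6 (1 - theta) E[1/d_g]`, conversions from areal cell densities to
   volumetric and cell-specific rates, and convex-hull surface roughness;
2. **ratiometric O2 imaging** — Stern–Volmer calibration of two-channel
   (indicator/reference) sensor-particle images and pixel-wise volumetric
   rate maps;
3. **single-grain reactive transport** — a 2D Stokes flow + advection–
   diffusion–reaction model of a colonised grain;
4. **Sand_DBL scaling** — a Damköhler-type dimensionless number predicting
   the anoxic colony fraction through a fitted power law;
5. **areal upscaling** — ripple-driven hydraulics, O2/nitrate penetration
   depths and the partition of areal denitrification between anoxic
   microenvironments in the oxic zone and the anoxic zone below;
6. **synthetic data** — seeded generators for every input, so the chain is
   testable end-to-end without measurements.

## The single-grain model

### Geometry and flow

The model grain is a circle of radius `r = 145` µm carrying a 5 µm reactive
rim, centred in a concentric annular fluid cell whose outer radius is `8 r`
by default. We deliberately use a boundary-fitted polar grid rather than a
rectangular channel with an immersed grain: the radial spacing resolves the
5 µm rim with ~0.8 µm cells (6 cells across the rim by default, geometric
stretching outside it), colony arcs map exactly onto grid faces, and the
creeping-flow field can be written in closed form. The flow is the analytic
Stokes cell-model solution — streamfunction
`psi = U f(r) sin(theta)` with `f(r) = A/r + B r + C r ln r + D r^3` — with
no-slip on the grain and uniform streamwise velocity plus zero vorticity on
the outer cell boundary. It satisfies the Stokes equations exactly, and
because the solute solver takes its face fluxes as streamfunction
differences between face corners, the discrete advecting field is
divergence-free to machine precision. In the vanishing-grain limit the flow
tends to a uniform stream (logarithmically, as expected for 2D creeping
flow); at `U = 0` it is identically zero.

### Surface reaction

Colonies alternate along the grain surface following a shifted sinusoid in
`sin(a * theta)` with `a = 4` colony pairs. The shift thresholds are chosen
so that the arcs where the rate is negative (net consumption) and positive
(net production) have exactly the observed lengths — 76 µm and 38 µm per
pair on a 290 µm grain, i.e. roughly two thirds and one third of the
colonised perimeter — with bare sediment between them. Within a colony the
rate tapers smoothly from the peak at the core (−955 mmol O2 L⁻¹ h⁻¹ for
consumers, +514 mmol O2 L⁻¹ h⁻¹ for producers) to zero at the edges,
emulating rates that decline from the colony centre outwards; a uniform
profile is available (`reaction_shape = "uniform"`) mainly for validation
against the 1D analytic solution.

The peak consumption rate is anchored in the measurement chain implemented
in `grain_geometry`: a bulk 25th-percentile rate of −46 µmol O2 L⁻¹ h⁻¹
divided by 1.3e8 cells cm⁻³ gives ≈ −0.35 fmol O2 cell⁻¹ h⁻¹, and dividing
by a 0.4 µm³ cell biovolume gives a colony-volumetric magnitude of order
−900 mmol O2 L⁻¹ h⁻¹. Note that this chain is not exactly reproducible from
its rounded printed intermediates (−0.35 vs −0.4 fmol cell⁻¹ h⁻¹ changes
the end point from ≈ −885 to −1000); the default −955 is therefore treated
as a stated model constant, not a derived one.

### Solutes and kinetics

O2 and N2 obey stationary advection–diffusion–reaction equations. O2
consumption is limited by Michaelis–Menten kinetics
`f_O2(C) = C / (K_m + C)` with `K_m = 0.1` µmol L⁻¹; production enters as an
unlimited source. The N2 source inside consuming colonies is the *potential*
(nominal) O2 consumption magnitude scaled by the empirical 10:1 O2:N ratio
and gated by the O2 inhibition `f_N(C) = C_inh / (C_inh + C_O2)` with
`C_inh = 0.1` µmol L⁻¹. Using the potential rather than the realised
consumption is a deliberate choice: where a colony is anoxic the realised
O2 consumption is ≈ 0 by definition, so coupling denitrification to the
realised rate would extinguish it exactly where it occurs. The inhibition
factor is what localises N2 production to anoxic cells.

The outer boundary mirrors the inlet/outlet of a flow-through domain: the
inflow half holds the bulk concentrations (Dirichlet + advective influx),
the outflow half is advective-only with zero diffusive flux. In the
stagnant limit the upstream semicircle acts as the inlet. This matters at
low velocity, where holding the bulk concentration on the whole ring would
over-supply O2 relative to any flow-through geometry. A full Dirichlet ring
(`outer_bc = "dirichlet"`) is available for radially symmetric diffusion
studies.

### Discretisation and nonlinear solve

A conservative finite-volume scheme (upwind advection on the streamfunction
face fluxes, central diffusion with harmonic-mean face diffusivities) gives
an M-matrix, hence positivity-preserving solutions. The Michaelis–Menten
sink is handled semi-implicitly — `sigma = R_pot / (K_m + C_old)` on the
diagonal — and iterated with Irons–Tuck (Aitken) adaptive relaxation, which
cuts the iteration count several-fold in starved regimes where the
transition layer (C ~ K_m) makes plain Picard slowly convergent. The solve
stops when the max-norm update falls below 1e-11 relative and errors if the
nonlinear residual exceeds 1e-8 relative; in practice residuals land near
1e-11 and O2/N2 mass balances (boundary influx vs net reaction) close to
~1e-10 relative. The default grid is 56 radial × 180 angular cells
(~10,000 unknowns, ~1–10 s per solve); halving the cell size in both
directions changes the anoxic fraction by < 5 % at a half-anoxic reference
condition, with the angular resolution of colony edges the dominant term.

### What "anoxic" means here

The anoxia threshold is C_O2 < 1 µmol L⁻¹ (configurable; the term is not
defined numerically in the underlying observations). The anoxic fraction is
the area-weighted share of consuming-colony rim volume below the threshold;
a colony counts as anoxic when more than half of its rim area is. Per-grain
N2 production integrates the N2 source over the rim and extrudes the 2D
solution by one median grain diameter (290 µm) — the convention that maps
2D rim areas to 3D colony volumes; it reproduces the expected order of
~0.15 nmol N d⁻¹ per anoxic colony and ~0.5–0.8 nmol N d⁻¹ per grain, and
is configurable because any 2D-to-3D extrusion is a convention, not a
measurement.

## The Sand_DBL scaling

The DBL thickness follows the mass-transfer law `delta = r / Sh` with
`Sh = 1 + 0.62 Re^0.41 Sc^0.33`, `Re = U r / nu`, `Sc = nu / D`; at `U = 0`,
`delta = r`. Surface roughness (measured as the radial deviation of the
outline from its convex hull; observed range ~2–35 µm) thickens the DBL by
up to ~20 %; with only that bound available the correction is first-order
multiplicative, `delta' = delta + c * roughness_max` with `c = 0.4`
calibrated so the observed roughness range stays within the 20 % bound over
the 10–100 µm s⁻¹ velocity range.

The dimensionless number

`Sand_DBL = (delta^2 / D) * (R_O2 / C0)`

compares the diffusive time across the DBL with the reactive time of colony
O2 consumption (`R_O2` is the colony-volumetric magnitude, 955 mol m⁻³ h⁻¹
in SI seconds, not the bulk rate). Below ~10 colonies are mostly oxic;
above ~1000 mostly anoxic. In between, `fit_anoxic_powerlaw()` fits
`fraction = A * Sand_DBL^m` on log–log axes to the partially anoxic runs
(fraction in 0.01–0.99) of a model ensemble, and `predict_anoxic_fraction()`
clamps predictions to 0 below the lower threshold and 1 above the upper.
The thresholds are the printed anchors; the law itself is refit from this
package's own ensemble rather than copied.

Two honest caveats, both visible in the test suite. First, with
photosynthesis active the anoxic fraction is *not* strictly monotone in
velocity: near stagnation, producer O2 lingers around the grain and
oxygenates neighbouring consumer-colony edges, so a faster flow that sweeps
that O2 downstream can slightly *increase* anoxia at very low bulk O2. The
monotone-in-U property holds for the production-off ensemble; monotonicity
in bulk O2 holds in both. Second, a single dimensionless number collapses
(U, C0, photosynthesis) only imperfectly in this geometry: the pooled fit
reaches Spearman rho ≈ 0.93 against the PDE ensemble, but the partially
anoxic runs scatter ~0.18 RMS around it, chiefly because at high bulk O2
(~100 µmol L⁻¹) the colony-scale drawdown saturates below the bulk
concentration and anoxia vanishes even at intermediate Sand_DBL (16–50).
For the same reason, "20–100 % of consuming colonies turn anoxic at low O2
or low flow" should be read as the range attained across that regime — the
deep anoxia occurs where low O2 and low flow compound — not as a pointwise
floor on every combination; a floor of 20 % at, say, (U = 50 µm s⁻¹,
C0 = 100 µmol L⁻¹) would contradict the Sand_DBL law's own oxic threshold.

## Areal upscaling

Per site, grain size `d_g` and bottom-water velocity `U_bw` set the
hydraulics through empirical closures: bedform wavelength
`lambda = 490 d_g`, wavenumber `k = 2 pi / lambda` (the standard
definition; the alternative `lambda / 2 pi` is dimensionally inconsistent),
permeability `P = 9.869e-13 * 735 * d_g^2 * 1e-6` with `d_g` in µm (the
only unit reading that yields realistic sand permeabilities of ~1e-11 m²),
conductivity `K = P g / nu(T, S)`, head `h_m = 0.01 U_bw^2` and pore-water
velocity `U_pore = k K h_m`. The effective mixing depth after time `t` is

`z(t) = (1/k) * ln(1 + 0.42 k^2 K h_m t / theta)`

— the logarithm multiplies `1/k`; the typeset alternative with the
logarithm in the denominator would make depth shrink with time. Evaluating
`z` at the O2 depletion time `t = C_O2 / R_O2` gives the O2 penetration
depth; the nitrate depletion time gives the nitrate penetration depth.

The oxic zone is split into four equal-thickness layers (equal thickness
chosen over equal O2 drop; the construction is not otherwise specified)
with pore-water O2 declining linearly from the bottom-water value to zero
at the penetration depth, evaluated at layer midpoints — the profile a
constant volumetric consumption along a streamline would give. Each layer
gets a Sand_DBL number from `delta(U_pore, r = d_g/2)` and the
colony-scaled O2 consumption rate. Two scaling routes are exposed: the
default biovolume chain (bulk rate → cell-specific rate over 1.3e8
cells cm⁻³ → divided by the 0.4 µm³ biovolume, a factor of ~19,000,
consistent with the −955 mmol O2 L⁻¹ h⁻¹ anchoring of the grain model)
and the pore-fraction route (bulk rate ÷ 1/1000, the fraction of pore
volume colonies occupy). The biovolume default matters: with the
pore-fraction route realistic site tables give layer Sand_DBL numbers of
only ~1–5 and predict no microenvironments at all. The fitted power law
converts each layer's Sand_DBL into an anoxic fraction, and
`anoxic fraction × R_den × layer thickness` summed over layers is the
denitrification flux in oxic-zone anoxic microenvironments. The flux below
the oxic zone is `R_den × (z_NO3 − z_O2)`, floored at zero with a warning
when nitrate runs out first. The ±50 % band on colony rates is propagated
by rerunning the chain at 0.5× and 1.5×.

One structural subtlety: the *share* of total denitrification attributed
to microenvironments is not monotone in bottom-water O2 — more O2 deepens
the O2 penetration depth, which shrinks the anoxic zone below it, so the
microenvironment share can approach 1 at high bottom-water O2 even while
every layer individually becomes less anoxic. The monotone quantity is the
oxic-zone mean per-layer anoxic fraction
(`flux_microenv / (R_den z_O2)`), which declines with both bottom-water O2
and bottom-water velocity; the test suite asserts exactly that.

Bottom-water O2 defaults to air saturation computed from temperature and
salinity (Garcia & Gordon 1992 combined fit with EOS-80 density); kinematic
viscosity uses the Sharqawy et al. (2010) correlation; the O2 diffusivity
is Stokes–Einstein-scaled from 1.1e-9 m² s⁻¹ at 25 °C. These correlations
are implemented in-package.

## Ratiometric imaging

The indicator/reference ratio relates to O2 through the Stern–Volmer curve
`R(C) = R0 / (1 + Ksv C)`, fitted by nonlinear least squares seeded from
the linearised form (an optional two-site variant
`R(C) = R0 (f / (1 + Ksv C) + 1 − f)` covers indicators with an
inaccessible fraction; `f = 1` recovers the simple model). Rates are
per-pixel concentration differences between two frames divided by the
elapsed time in hours, assuming a homogeneous O2 field at the first frame.
Processing order is: invalidate rates beyond a configurable ±500
µmol L⁻¹ h⁻¹ outlier threshold, then smooth with a 5×5 median filter
(reflective borders, invalid pixels ignored within windows) — thresholding
before filtering so that spikes cannot leak into their neighbourhoods. The
phototroph mask thresholds the chlorophyll autofluorescence image with
Otsu's method by default (plateau-midpoint convention), overridable by an
absolute value. The median filter and Otsu threshold are implemented
in-package because the available image-processing routines quantise
intensities to [0, 1] integer bins, which corrupts signed floating-point
rate maps.

## Synthetic data: what it emulates, and what not

The generators produce log-normal grain sizes (median 290 µm, GSD 1.3 — the
spread is a free parameter, chosen as typical for sieved beach sand, since
only the median is constrained); outlines with band-limited Fourier
roughness (modes 5–25) scaled to a requested hull-deviation amplitude;
colonisation maps with the 2:1 consumer:producer split of a half-colonised
perimeter; ratio stacks pushed through the Stern–Volmer forward model with
multiplicative noise whose CV refers to the emitted ratio (each channel
carries an independent share of cv/√2); and site tables spanning the field
envelope (grain sizes 102–700 µm, bottom-water velocities 0.1–0.2 m s⁻¹,
denitrification rates 0.04–11.8 µmol N L⁻¹ h⁻¹ drawn log-uniformly,
temperature 4–25 °C, salinity 30–36, O2 at air saturation). One integer
seed threads every generator; identical seeds give identical bytes.

Passing tests on these fixtures demonstrate that the pipeline inverts its
own forward models and satisfies the physics invariants (conservation,
monotonicity, dimensional consistency); they do not demonstrate robustness
to real-microscopy artefacts (uneven illumination, bleaching beyond the
ratiometric compensation, focus drift, grain motion) or to site tables
whose rates co-vary with temperature in ways the independent draws ignore.

## Problem sizes and numerical defaults

Defaults were chosen so a full analysis runs comfortably on a laptop: the
single-grain grid is 56 × 180 cells; the reference ensemble is 5 pore-water
velocities (0, 10, 50, 150, 500 µm s⁻¹) × 4 bulk O2 levels (1, 10, 25,
100 µmol L⁻¹), i.e. 20 solves of a few seconds each, run once per scenario
(photosynthesis on/off). Tolerances: nonlinear residual ≤ 1e-8 (typically
1e-11), mass-balance closure ≤ 1 % (typically ~1e-10), calibration fits to
≤ 1 % parameter error on clean tables. Degenerate inputs are defined
errors: zero bulk O2 in Sand_DBL, zero rates in penetration depths,
non-monotone calibration tables, self-intersecting outlines.

## Known limitations

- The grain is a circle in 2D; real-outline meshing is out of scope and
  roughness enters only through the DBL correction.
- The 2D-to-3D extrusion by one grain diameter is a convention; per-grain
  N2 numbers carry that factor-of-order-one ambiguity.
- The Stokes cell model imposes the far-field velocity at a finite outer
  radius; neighbouring grains are represented only through that boundary.
- The power law is refit per ensemble; its coefficients are not portable
  constants, only the 10/1000 thresholds are.
- Upscaling treats volumetric rates as depth-constant within each zone and
  ignores carbonate and impermeable sediments.
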