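---
title: "Methods: mechanistic filtration and washing of crystalline drug substances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic filtration and washing of crystalline drug substances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cakewash)
```

## Scope and model structure

`cakewash` simulates the isolation of a crystalline active ingredient as
two chained unit operations: constant-pressure dead-end filtration of the
crystallizer slurry, followed by washing of the filter cake. The package
deliberately brackets reality between two limiting treatments of the
solid phase. In **case 1** the solid is inert — washing only redistributes
the liquid species. In **case 2** the solid and liquid are kept at
solid–liquid equilibrium throughout, so the cake can lose mass where the
local liquor is undersaturated and gain mass where mixing the
crystallization and wash solvents causes an antisolvent effect. Any real
process, with finite dissolution kinetics, lies between the two.

Three washing mechanisms are provided in both cases: plug **displacement**
(models 1a/2a), perfectly mixed **dilution** (1b/2b), and
**diffusion–dispersion** (1c/2c), the last either as a 1-D
advection–dispersion equation or as a tanks-in-series cascade (ten layers
by default, layer 1 at the wash inlet, layer 10 at the filter medium).

## Filtration

The filtrate volume follows Darcy's law at constant pressure,
$\mathrm{d}V/\mathrm{d}t = \Delta P A^2 / \{\mu\,(\alpha w V + R_m A)\}$,
with $w$ the dry cake mass deposited per unit filtrate volume. The
specific cake resistance is Carman–Kozeny,
$\alpha = 180(1-\varepsilon)/(\rho_s x_{sv}^2 \varepsilon^3)$, evaluated
at the *supplied* cake porosity: porosity is an empirical input, not a
prediction, and the porosity relation is used only for volume bookkeeping.
Particle shape enters through the sphericity-scaled Sauter mean diameter
$x_{sv} = \phi\, d_{32}$ of the discretized PSD.

Two endpoints are supported. **Dryland** stops when the free slurry
liquid is exhausted: every pore is then filled with mother liquor, and the
residual liquid volume equals the cake void volume
$\varepsilon/(1-\varepsilon) \times V_\text{solid}$. **Breakthrough**
additionally removes pore liquor until 10% of the void volume remains
(configurable), at unchanged composition. This is bookkeeping only: the
package does not model multiphase flow, capillarity or surface tension,
so breakthrough timing and residual-distribution effects are out of
scope. Washing a breakthrough-fed cake first *rewets* the voids with
fresh wash (no outflow) before displacement begins; the rewetting charge
is counted in the fed wash but not in the wash ratio grid.

Richardson–Zaki hindered settling
($u = u_\text{Stokes}(1-\phi_v)^n$, $n = 4.65$) is available behind an
off-by-default flag; when enabled it only augments the effective
deposition concentration $w$ by $1 + u_h A / Q_0$ at the initial Darcy
flow. The literature this work builds on mentions settling during
filtration without giving equations or parameters, so the package keeps
the correction minimal and clearly optional.

## Washing

All models report against the wash ratio $W_r = V_w / V_v$ on a fixed
grid ($\Delta W_r = 0.01$ by default), which makes case-1 curves
independent of the absolute flow rate. The flow rate — Darcy at constant
pressure with the evolving mixture viscosity, or a prescribed constant
flow — sets the physical time axis and therefore only matters to
finite-rate kinetics.

**Displacement (1a/2a).** The filtrate composition is the mother liquor
for $W_r < 1$ and the wash input for $W_r \ge 1$. With dissolution
(2a), each element of wash saturates once at $c_{sat}(w_{wash}{=}1)$
while traversing the cake, so the dissolved mass grows linearly at
$c_{sat}(1)$ per unit mass of wash fed and the filtrate beyond one void
volume leaves saturated. This linear-accrual reading is the one that
closes the species balance exactly for $W_r > 1$; at $W_r = 1$ (the
displacement model's natural endpoint) it coincides with "one cake
volume of wash saturates once". Dissolution is applied homogeneously
(`uniform_dissolve()`: one cube-root diameter scale factor).

**Dilution (1b/2b) and cascade (1c/2c).** One engine serves both: the
cake voids are $N$ equal well-mixed holdups in series; $N = 1$ *is* the
dilution model (the equivalence is structural, and tested). With matched
inlet/outlet volumetric flows the inert-solute solution is
$c/c_0 = e^{-W_r}$ for $N = 1$ and the Erlang-type cascade response for
larger $N$, approaching the displacement step as $N \to \infty$. The
case-1 balances are linear and integrated with `deSolve::lsoda`
(banded Jacobian, `rtol = 1e-11`), which is what lets the closed-form
check hold to $10^{-8}$.

**Dispersion PDE (1c).** $\partial c/\partial t = D_L\,\partial^2
c/\partial z^2 - u\,\partial c/\partial z$ on the cake height, method of
lines on a conservative finite-volume grid (200 cells by default, 400 in
the verification tests). The inlet is Dirichlet with *no dispersive flux*
at the top of the cake; the outlet is zero-gradient; the initial
condition is mother liquor everywhere; the filtrate concentration is read
at the medium. Central differencing switches to upwinding with a logged
notice when the cell Péclet number exceeds 2 — at the fixed default
diffusivity of $10^{-9}\,\mathrm{m^2\,s^{-1}}$ and realistic Darcy flows
the column Péclet number is enormous, so the model then behaves as a
slightly smeared displacement front, which is its intent (mixing time
approximated as zero). The axial dispersion coefficient is either the
molecular diffusivity (`fixed_D`) or the packed-bed estimate
$D + 0.5\,u_s d_p$ (`correlation`); the published correlation this
substitutes for is not reproduced in the source material, so the packed-bed
default is flagged as a substitute and overridable.

**Case-2 equilibration.** Operator splitting: an RK4 flow step in
$W_r$ (default internal step 0.005) followed by per-layer equilibration
against the binary solubility curve at the layer's local wash-solvent
fraction. Two modes:

* `instantaneous_flash` — algebraic solve. On the g-per-g-solvent basis
  the exchange is exact: $\Delta m = (c_{sat} - c)\,m_\text{solvent}$,
  capped at the available solid.
* `kinetic` — the empirical power law $G = \mathrm{sign}(\sigma)\,k_g
  |\sigma|^g$ (activation energy zero, isothermal) applied as a uniform
  diameter shift $\Delta L = G\,\mathrm{d}t$, clipped at the flash
  exchange so large $k_g$ cannot overshoot equilibrium. If the run ends
  with $\max|\sigma|$ above the tolerance ($10^{-3}$), $k_g$ escalates
  tenfold and the wash re-runs (up to six times) — implementing "a rate
  constant large enough to hold equilibrium" as an automated search. The
  flash mode is the independent cross-check: the two must agree on the
  final solid mass change within 1%.

The supersaturation $\sigma = c/c_{sat} - 1$ is intensive and evaluated
on the solute-free solvent-mixture basis (see *Concentration basis*
below).

**PSD evolution.** The population is a binned mass-by-size distribution.
Growth/dissolution is size-independent in linear rate (McCabe $\Delta L$):
the simplest rule consistent with fines-first dissolution, since a small
particle dies after shrinking by its own diameter while a large one
barely changes. Updates move the bin edges explicitly and re-bin onto the
fixed grid by conservative overlap — exact mass conservation, no
numerical diffusion; mass shrinking past either end of the grid is
credited to the end bins. The flash-mode diameter shift is found by a
Newton solve on the closed-form mass-exchange function (bisection
fallback). Layer porosity is recomputed from the fixed layer geometry and
the evolving solid volume, so porosity moves opposite to local solid
mass by construction.

## The benchmark fixtures

`generate_fixture()` emits five ready-made cases: paracetamol
crystallized from isopropanol washed with water, acetonitrile (both:
solubility maximum on the mixing line — dissolution risk), heptane,
dodecane (negligible/decreasing solubility — antisolvent deposition
risk), and mefenamic acid from 2-butanol washed with heptane. The slurry
masses, liquid-phase fractions, porosity, sphericity, media resistance,
driving force, geometry and PSD moments are the published benchmark
operating conditions; solvent densities and viscosities are handbook
values at 25 °C shipped as clearly substitutable defaults
(`inst/extdata/properties/`), and the solubility curves are *synthetic*
shapes with the documented qualitative features (their CSV files carry a
`_synthetic` suffix). Users holding measured binary solubility data
should substitute them via `read_solubility_curve()`; absolute
dissolved/deposited masses scale directly with the curve, so only
directions, peak locations and morphologies — not magnitudes — should be
read from the synthetic cases.

**Concentration basis.** Binary solubility is expressed as g solute per g
of *solute-free* solvent mixture, against the wash-solvent mass fraction
of that mixture. This makes dilution trajectories linear in mixing and
the flash exchange algebraically exact. The basis of published binary
plots is often left unstated; if a curve is tabulated per gram of
solution it must be converted before loading.

**Curve anchors.** The maximum-type fixtures anchor $c_{sat}(0)$ at the
saturation of the benchmark mother liquor (solute fraction 0.12 ⇒
$c_{sat}(0) = 0.12/0.88$), so washing starts at $\sigma = 0$ exactly. The
heptane fixture instead anchors at the published 0.10 → ≈0.01 g/g
tenfold drop; its feed is then slightly supersaturated at wash start,
which is precisely the antisolvent-deposition driving force that case is
meant to exercise.

**PSD weighting.** The benchmark quotes a mean size of 77 µm and a
standard deviation of 174 µm without stating the weighting, and elsewhere
lists the raw material's D50 as 77 µm. Since a laser-diffraction "mean
size" is a volume statistic and the quoted D50 equals it, the fixtures
interpret the pair as the volume *median* and volume-weighted standard
deviation (`fit_lognormal_psd(..., weighting = "mass")`), which makes the
fixture's D50 exactly 77 µm and gives the mass distribution a genuine
fines shoulder — the prerequisite for the fines-first D50 *increase*
during case-2 washing. The number-weighted reading remains available
(`weighting = "number"`); under it the 0.1–1000 µm grid truncates a very
heavy tail and the mass distribution is dominated by near-millimetre
sizes. Because the grid truncates the ideal lognormal either way, the two
distribution parameters are re-fitted numerically (Nelder–Mead) so the
*realized, discretized* statistics hit the targets; the fit is
deterministic.

What the fixtures do **not** emulate: measured solubility magnitudes,
impurity species, compressible or cracking cakes, agglomeration/breakage,
temperature excursions, and deliquoring physics. A green test suite on
these fixtures therefore demonstrates correct mechanics and bookkeeping,
not quantitative agreement with any particular laboratory isolation.

## Numerical choices

* Default PSD grid: 80 geometric bins over 0.1–1000 µm; quantiles are
  mass-weighted with linear interpolation inside the straddling bin.
* Filtration integrates $\mathrm{d}t/\mathrm{d}V$ (the volume is the
  monotone variable) with `lsoda` at `rtol = 1e-10`; the trajectory is
  checked against the quadratic closed form to $10^{-6}$.
* Case-1 washing: `lsoda`, banded Jacobian, `rtol = 1e-11`; case-2:
  fixed-step RK4 splitting at $\Delta W_r = 0.005$, reported on the 0.01
  grid; checkpoints every 0.25 in $W_r$ store per-layer D10/D50/D90,
  porosity, saturation and $w_{wash}$.
* Equilibrium tolerance $\max|\sigma| \le 10^{-3}$ on accepted case-2
  runs; balance audits must close to $10^{-8}$ relative (they close to
  machine precision in practice because inflow, exchange and outflow are
  integrated by the same scheme).
* Degenerate inputs fail loudly: zero-mass liquids and empty PSDs raise
  degenerate-input errors, infeasible dissolution raises its own error,
  and $c_{sat} = 0$ with solute present reports $\sigma = \infty$
  distinctly.
* Everything is deterministic — there is no random number generation
  anywhere in the pipeline, so re-runs are bit-identical.

The tanks-in-series convergence to the displacement step is verified in
L1 (mean absolute deviation on the $W_r$ grid) plus pointwise away from
$W_r = 1$: the step is discontinuous there, so a supremum over a grid
containing the jump cannot converge and is the wrong metric.

## Model selection

`select_model_guideline()` encodes the decision tree: breakthrough
filtration for large particles (open, fast-deliquoring cakes), and for
small particles whichever endpoint the isolation objective dictates
(minimizing residual liquor → breakthrough; avoiding cake stress or
minimizing solvent use → dryland). An insoluble solid takes 1a (large
particles, or an immiscible solvent pair) or 1c (small particles,
miscible pair); a soluble solid takes 2a (large) or 2c (small). The two
sub-cases the source guideline leaves open — large particles with
miscible solvents, small with immiscible — resolve to 1a, since a sharp
front (immiscible) or low tortuosity (large particles) keeps displacement
the governing mechanism.

## Problem sizes

The shipped tests and the acceptance script run the full benchmark
pipeline at its native scale: 80 PSD bins, 201-point wash grids,
10-layer cascades (up to 200 layers in the convergence study), 400-node
PDE verification. These sizes were chosen so that each verification has
headroom below its tolerance; nothing is scaled down from the cases the
package is meant to model.

## Known limitations

* Breakthrough is an accounting endpoint; rewetting and partial
  saturation during washing are treated volumetrically.
* Wash hydraulics reuse the filtration-derived cake resistance
  (recomputed per layer as porosity evolves) but ignore fines migration
  and cake consolidation.
* Deposition requires existing solid in the layer (growth on present
  crystals); primary nucleation of a solute-rich layer with no seed
  surface is not modelled.
* A single solute; inert extra liquid species are representable, but
  impurity adsorption/desorption is not.
* Ideal-mixture property rules (inverse-specific-volume density,
  log-linear viscosity) stand in for measured mixture data and can be
  overridden with tabulated values.
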