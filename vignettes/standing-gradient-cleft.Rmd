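---
title: "The standing-gradient cleft model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The standing-gradient cleft model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftflow)
```

## The physical model

Absorbing epithelia (small intestine, gall bladder, proximal tubule) move
water across a cell layer even when there is no — or an adverse — osmotic
gradient between lumen and interstitium. The standing-gradient picture
explains this with the geometry of the lateral intercellular cleft: ion
pumps lining the cleft walls keep the paracellular fluid hypertonic, and
that local hypertonicity draws water osmotically through the tight junction
(TJ) at the closed end and through aquaporins in the lateral membranes.

`cleftflow` models the cleft as a one-dimensional channel $y \in [0, L]$ of
width $b \ll L$, with the TJ at $y = 0$ and the open (interstitial) end at
$y = L$. The state variables are the cross-section-averaged osmolyte
concentration $c(y)$ and fluid velocity $v(y)$ (positive toward the
interstitium). After one integration of the convection–diffusion equation —
using the fact that no ions cross the TJ, so the axial ion flux vanishes at
the inlet — the steady state obeys

$$-D\,c' + v\,c = \frac{2 j y}{b}, \qquad
  v' = \frac{2 f_{aq}}{b}\,(c - c_3),$$

with boundary conditions $c(L) = c_4$ (the interstitial osmolarity is
imposed at the open end) and $v(0) = k_{TJ} RT\,(c(0) - c_1)$ (osmotic water
flux through the TJ, driven by the difference between the cleft inlet and
the lumen). Here $j$ is the (uniform) pump flux through the lateral
membrane, $D$ the osmolyte diffusivity, $f_{aq} = k_{aq} V_{wat} n_{aq}$
the aggregate aquaporin coefficient, and $k_{TJ} = P_f V_{wat}
w_{TJ}/(RT\,b)$ the TJ osmotic conductance.

Two assumptions are baked in and are *not* switchable:

* **Hydrostatic pressure is neglected** in both the TJ and aquaporin driving
  forces. At a typical osmotic difference of 100 mM, $RT\,\Delta c \approx
  2.6\times10^6$ CGS, while physiological pressure differences are about
  $10^5$ CGS — a factor ~26 smaller (`pressure_vs_osmotic_ratio()` documents
  the check). Viscosity `mu` is carried in the parameter record but unused.
* **The pump flux $j$ is constant along the cleft.** A position-dependent
  $j(y)$ changes the first integral above and with it the whole analysis;
  no hook for it is provided.

## Parameters and units

All user input is in physiological units (`"290 mM"`, `"40 nm"`,
`"100 um"`); everything internal is CGS with concentrations in mol cm⁻³
(1 mM = 10⁻⁶ mol cm⁻³). Config-file values *must* carry unit suffixes —
the single most dangerous error in this problem is a silent mM ↔ mol cm⁻³
slip, so bare numbers in config files are rejected, and concentrations
outside (0, 10000) mM are treated as conversion mistakes.

The defaults describe a leaky absorbing epithelium:

| field | default | meaning |
|---|---|---|
| `k_aq` | 5e-14 cm³/s | single-aquaporin permeability |
| `n_aq` | 1e3 /µm² | aquaporin density, lateral membrane |
| `j` | 18.5e-9 mol/cm²/s | pump ion flux |
| `D` | 1e-5 cm²/s | osmolyte diffusivity |
| `b` | 400 nm | cleft width (40–400 nm physiological) |
| `L` | 100 µm | cleft length (20–100 µm) |
| `w_TJ` | 2 nm | TJ pore width (moderately leaky) |
| `P_f` | 13.1e-3 cm/s | TJ hydraulic permeability |
| `c1` | 600 mM | lumen osmolarity (200–1000 mM range) |
| `c3`, `c4` | 300 mM | cytosol / interstitium osmolarity |

Width and length default to the wide-cleft baseline used throughout the
length-sweep experiments; `c1 = 600 mM` is the middle of the physiological
range (a moderately hypertonic lumen). One tabulated constant deserves a
note: the source table lists the aquaporin number with units cm s⁻¹, which
cannot multiply a concentration into a velocity. The only reading consistent
with the published homogeneous concentration (≈620 mM at `c3 = 290 mM`) is
that the tabulated number is the *single-channel* permeability `k_aq`
[cm³/s], with `f_aq = k_aq V_wat n_aq = 0.09` cm⁴ mol⁻¹ s⁻¹. `cleftflow`
adopts that reading.

## Derived scales and regimes

```{r scales}
p <- cleft_params(c3 = "290 mM", c4 = "300 mM", c1 = "600 mM")
derived_scales(p)
```

Two quantities organize everything:

* **The homogeneous concentration** $c_{hom}$, the positive root of
  $c^2 - c_3 c - j/f_{aq} = 0$. Far from both ends the concentration settles
  there and the velocity is linear, $v = Ay$ with $A = 2j/(b\,c_{hom})$.
  $c_{hom} > c_3$ always, with equality only when pumping stops.
* **The inhomogeneity length** $y_{inh} = \sqrt{D b c_{hom} / j}$, the
  distance over which the outlet disturbance $c_4 \ne c_{hom}$ relaxes.
  It scales as $\sqrt{b}$: narrow clefts equilibrate sooner.

A cleft is classified **long** when $L \ge r_{long}\, y_{inh}$ (default
$r_{long} = 1$, with the boundary case assigned to "long") and **short**
when $L \le r_{short}\, y_{inh}\sqrt{2(1 + f_{aq} c_{hom}^2/(2j))}$ (default
$r_{short} = 0.5$); anything between is "intermediate". The short-cleft
condition in the source text is typographically damaged; the scale used here
is the reading under which the published 20 and 30 µm examples at
b = 400 nm classify as short while 80 and 100 µm classify as long. Both
thresholds are arguments of `classify_regime()`, so other conventions cost
one keyword.

A caveat on printed reference values: the published $y_{inh}$ figures
(12.2 µm at 40 nm, 38.5 µm at 400 nm) sit ≈5 % above direct evaluation with
the tabulated constants (11.6 / 36.6 µm); the $c_{hom}$ or $j$ behind them
is not stated. The package does not force agreement — the $\sqrt{10}$ width
ratio and the magnitudes are the reproducible content, and the tests check
exactly that.

## Numerical solution

The problem is nondimensionalized before discretization: $Y = y/L$,
$C = c/c_3$, $V = vL/D$ turn the system into $C' = VC - \alpha Y$,
$V' = \beta(C-1)$ with $\alpha = 2jL^2/(bDc_3)$, $\beta = 2f_{aq}c_3L^2/(bD)$
and TJ condition $V(0) = \gamma(C(0) - c_1/c_3)$,
$\gamma = k_{TJ}RT c_3 L/D$. This keeps Newton matrices well conditioned and
makes the convergence tolerance scale-free.

**Relaxation (the workhorse).** A second-order box (midpoint) scheme on a
mesh of 2049 nodes, graded smoothly so the density rises ~4× within two
inhomogeneity lengths of the outlet, where the boundary layer lives. The
nonlinear system is solved by Newton iteration with an analytic sparse
Jacobian and step halving (up to 20 halvings; any step that would drive a
concentration below 5 % of the smallest boundary concentration is rejected).
Convergence requires the scaled residual below 10⁻⁶ (Newton typically lands
far lower). The initial guess is the regime-appropriate analytical
approximation; if Newton still fails, the solver restarts by continuation in
$L$ from a cleft one inhomogeneity length long. The box scheme satisfies the
discrete volume-conservation identity exactly, so the volume residual of a
converged relaxation solve is at machine precision. Halving the mesh spacing
moves $c(0)$ and $v(L)$ by ~10⁻⁹ relative at the default parameters.

**Shooting (the independent oracle).** The inlet concentration $c(0)$ is
the single unknown: $v(0)$ follows from the TJ condition, the ODEs are
integrated with an adaptive integrator (deSolve's `lsoda`, rtol 10⁻¹¹), and
the outlet mismatch $c(L) - c_4$ is bracketed over
$c(0) \in [\min(c_1,c_3,c_4)/10,\; 10\,c_{hom}]$. Trajectories from poor
guesses blow up (or crash through zero) before reaching the outlet; root
detection stops them at a cap/floor and the mismatch is reported as a large
signed value, which keeps the bracket usable. The mismatch is checked to be
monotone in $c(0)$ across the bracket before root-finding. Shooting refuses
clefts with $L/y_{inh} > 3$, where forward deviations grow like
$e^{(L/y_{inh})^2}$ and the initial-value problem becomes hopeless —
relaxation covers that territory. On their common domain the two solvers
agree to better than 10⁻⁵ node-wise in both variables; this cross-check,
plus exact fixtures, is the package's trust anchor. The analytical
approximations are *never* used as truth when testing the solvers — the
dependency runs the other way.

**Exact fixtures.** Two are built into the tests: (i) setting
$c_1 = c_4 = c_{hom}$ makes the homogeneous solution exact, boundary
conditions included, and both solvers reproduce it to round-off; (ii) with
$j = n_{aq} = P_f = 0$ the only solution is $c \equiv c_4$, $v \equiv 0$.
(These limiting cases are why the validator allows exact zeros for `j`,
`n_aq` and `P_f` while every other field must be strictly positive.)

**Dispatch.** `solve_cleft()` uses shooting for short clefts (fast, and
independent of the relaxation machinery) and relaxation otherwise.

One genuinely physical subtlety surfaced during validation: the long-cleft
limit $c(0) \to c_{hom}$ saturates at a relative deviation of ~10⁻⁵ rather
than decaying to zero. That floor is the TJ coupling itself — the inlet
velocity $k_{TJ}RT(c(0)-c_1)$ perturbs the inlet concentration at exactly
the smallness ratio $P_f V_{wat} w_{TJ} c^2 / (2jL) \approx 2\times10^{-5}$
— and is mesh-independent. The limit tests therefore assert monotone decay
to below 10⁻⁴, not to zero.

## Analytical approximations

The package implements the closed-form solutions alongside the solvers:

* `homogeneous_profile()`: $c \equiv c_{hom}$, $v = Ay$ — exact away from
  boundaries.
* `long_cleft_profile()`: $c = c_{hom} + (c_4 - c_{hom})\,E(y)$ with
  $E(y) = e^{(y^2-L^2)/y_{inh}^2} (y/L)^{f_{aq}c_{hom}^2/j}$, and the
  corresponding velocity correction
  $(c_4 - c_{hom})E(y)\,D f_{aq} c_{hom}/(jy)$.
* `short_cleft_profile(variant = 2)`: the fully explicit parabolic form
  $c = c_{hom} + (c_4 - c_{hom})\bigl[1 + (1 + f_{aq}c_{hom}c_4/j)
  (y^2 - L^2)/y_{inh}^2\bigr]$.
* `short_cleft_profile(variant = 1)` with `fit_C0()`: the parabolic ansatz
  $c = c_{hom}(1 + C_0(1 - y^2/L^2)) + (c_4 - c_{hom})\,y^2/L^2$ whose inlet
  coefficient $C_0$ is determined by trapezoid-weighted least squares
  against the numerical solution. A closed form for $C_0$ exists but is not
  transcribable from the available text; `fit_C0()` labels its output
  `source = "fitted"` and the profile function accepts externally supplied
  coefficients should a closed form be preferred later.
* `inlet_shift()`: $c(0) - c_{hom} = (c_4 - c_{hom})\bigl(1 -
  (1 + f_{aq}c_{hom}c_4/j) L^2/y_{inh}^2\bigr)$ — variant 2 evaluated at the
  inlet. The outlet inhomogeneity is always *reduced* at the inlet within
  the short regime.

The printed source for the long- and short-cleft formulas has lost fraction
bars and radicals. Each undetermined grouping was fixed by two hard
constraints — $c(L) = c_4$ must hold exactly, and the disturbance must decay
toward the inlet over the scale $y_{inh}$ — and the result was validated
quantitatively against the solver: the long-cleft form tracks the numerics
within 2 % at the 100 µm / 400 nm baseline, explicit variant 2 within 5 % at
10 µm (it degrades quickly beyond that, as advertised), and fitted variant 1
reproduces the solver's inlet concentration to better than 1 % at 20 µm
while clearly beating variant 2. Velocity expressions for the parabolic
ansätze are obtained by integrating $v' = (2f_{aq}/b)(c - c_3)$ of the
concentration ansatz with $v(0)$ from the TJ condition, which keeps both
boundary conditions exact; the printed velocity line for variant 2 is
dimensionally inconsistent as typeset and was re-derived rather than
transcribed.

## Scenarios and what the tests do (and do not) show

```{r sweep, eval = FALSE}
p <- cleft_params(c3 = "290 mM", c4 = "300 mM", c1 = "600 mM", b = "400 nm")
cleft_sweep(p, "L", c("20 um", "30 um", "80 um", "100 um"))
```

`flux_summary()` partitions the water budget ($Q_{tj} + Q_{lateral} =
Q_{out}$, closed to 10⁻⁶ for every converged solve) and reports the efflux
concentration $c_e = 2jL/(b\,v(L))$ — defined only when fluid actually
leaves the open end. The sweeps reproduce the model's characteristic
behaviours: lengthening a wide cleft under a 600 mM lumen flips the TJ flux
from secretion to absorption between 30 and 80 µm; narrowing a short cleft
drives $c(0)$ up toward $c_{hom}$ and multiplies the open-end flux; at the
100 µm baseline the efflux concentration stays within 600–700 mM across the
full 40–400 nm width range; and with the reference TJ permeability the TJ
carries well under 1 % of the total water flux. When comparing widths, note
that the experimentally observable quantity is the volume flux $Q_{tj} =
v(0)\,b$, not the velocity: narrowing a cleft raises $|v(0)|$ but shrinks
$b$ faster, so the TJ *outflow* under a strongly hypertonic lumen drops.

`volume_per_area()` converts a per-unit-depth flux into mL per m² per day
using a cleft line density; the default (2×10³ cm⁻¹, square cells of 10 µm
side) is a stylized packing, *not* a measured geometry, so only the decade
of the result is meaningful. With it, a 30 µm cleft under a 1000 mM lumen
yields a reverse TJ flux of a few tens of mL m⁻² day⁻¹.

These computations explore the model, not the biology: parameters are
spatially uniform effective constants, the cytosol and interstitium are
fixed reservoirs (`link_cytosol()` offers only a stylized linear coupling
for lumen-tracking scenarios), efflux equilibration outside the cleft is not
modelled, and nothing here is fitted to measured volumes. Agreement between
solvers and approximations demonstrates internal correctness of the
mathematics, not predictive accuracy for any particular tissue.

## Problem sizes and runtime

Defaults everywhere: 2049 mesh nodes (relaxation and shooting), Newton
tolerance 10⁻⁶, `lsoda` rtol 10⁻¹¹. A single solve takes well under a
second; the full test suite — including a 24-point solver cross-validation
grid and several four-point sweeps — completes in well under a minute. All
computations are deterministic; nothing consumes random numbers.

## Known limitations

* Steady state only; no transient dynamics, no membrane elasticity, no
  time-dependent width regulation.
* One-dimensional cross-section averages; the 2-D entrance/exit flow fields
  and 3-D equilibration beyond the outlet are outside the model.
* Electroneutral single-osmolyte treatment; no electro-diffusion.
* Pressure-driven (Poiseuille) transport is neglected by design.
* The variant-1 coefficient $C_0$ is fitted, not closed-form.
* The daily-volume conversion rests on an assumed cell packing.
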