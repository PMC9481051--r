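---
title: "Methods: modelling phytoplankton as discrete, distantly-spaced cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling phytoplankton as discrete, distantly-spaced cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodisc)
```

## The problem

Plankton ecosystem models routinely predict that large phytoplankton go
extinct in low-nutrient (oligotrophic) waters, an outcome usually read as
resource-based competitive exclusion: small cells, with lower apparent
half-saturation constants, draw the shared nutrient pool below what large
cells need. Field observations disagree — oligotrophic communities keep a
continuum of cell sizes, merely at abundances falling steeply with size.

`phytodisc` implements a modelling chain built on a different premise: at
natural abundances, phytoplankton cells are so distantly spaced that their
nutrient-depleted boundary layers essentially never overlap, so no cell can
deprive another of resource directly. Growth of each size class is then set
by physics (diffusion of nutrient across its own boundary layer) plus an
evolved ceiling (its maximum division rate), and community structure is set
by predator–prey balance, not by resource competition.

## 1. How dilute is a phytoplankton community?

The community size distribution is a truncated power law in cell diameter
$d$,

$$N(d) = N_0\,(d/d_0)^{-\xi} \quad [\mathrm{ml^{-1}\,\mu m^{-1}}],$$

with absolute slope $\xi \approx 4.5$ in oligotrophic waters, tilting toward
$3$ under nutrient enrichment. All community quantities are closed-form
moments of $N(d)$ over $[d_{min}, d_{max}]$ (`total_abundance()`,
`total_volume()`, `mean_diameters()`, `carbon_biomass()`); the test-suite
checks every closed form against trapezoidal quadrature on a $10^5$-point
log grid.

The intercept $N_0$ is anchored biologically: the integral over the
*Prochlorococcus* bin, defined here as $[0.6, 0.8)\ \mu$m, is pinned to
$2\times10^4$ cells ml$^{-1}$ (oligotrophic, $\xi = 4.5$) or $2\times10^5$
(eutrophic cap, $\xi = 3.3$). This anchoring convention is a design choice —
the bin is not stated explicitly anywhere — but it is the unique simple
choice that simultaneously reproduces all six published endpoints (total
abundance $3.2\times10^4$/$4.1\times10^5$ cells ml$^{-1}$, mean cell size
1.1/4.3 $\mu$m, occupied volume 0.0000024%/0.0017%), which is why it is
hard-coded as the default.

```{r}
spacing_report(calibrated_spectrum(4.5, 2e4))
```

Two further conventions matter and were chosen because only this pairing
reproduces both printed ranges:

* "average cell size" is the diameter of the mean cell volume,
  $(6V_{tot}/\pi n_{tot})^{1/3}$;
* body-length spacing divides the cube-root spacing $\lambda = n^{-1/3}$
  (uniform random suspension; no nearest-neighbour order-statistics
  correction) by the *abundance-weighted* mean diameter.

With a boundary layer five cell diameters wide, the overlap diagnostic
$DV_\lambda = d_{soi}/\lambda$ stays far below 1 across the whole
oligotrophic–eutrophic range: cells sit hundreds of body lengths apart.
The carbon-biomass endpoints printed alongside (6 to ~3700 ng ml$^{-1}$)
are *not* reproduced by integrating the stated non-diatom carbon–volume
allometry over these spectra (we obtain ≈4.5 and ≈1600 ng ml$^{-1}$);
possibly a group mixture was used upstream. The operation is provided and
oracle-tested, but those two endpoints are not asserted. The Chl:C
conversion (`chlorophyll_from_carbon()`) is a log-linear interpolation
between the stated endpoint ratios and is qualitative only.

## 2. Production–resource curve forms

Short-term responses — photosynthesis against instantaneous irradiance, or
nutrient uptake against a substrate pulse — reflect a fixed complement of
capture machinery and follow a hyperbolic tangent,
$P = P_m\tanh(\alpha I/P_m)$, which passes through $0.76 P_m$ at the
saturation index $I_K = P_m/\alpha$. Acclimated responses — division rate
against the growth-limiting resource — reflect whole-cell optimization and
follow a rectangular hyperbola, reaching only $0.5\,\mu_m$ at its
saturation index. The acclimated nutrient form

$$\mu = \frac{\alpha_v S_\infty V_m}{\alpha_v S_\infty + V_m}\frac{1}{Q}
     = \mu_m\frac{S_\infty}{S_\infty + K_{m,cell}},\qquad
  K_{m,cell} = V_m/\alpha_v$$

is algebraically a Michaelis–Menten curve, but $K_{m,cell}$ is an emergent,
largely diffusion-set trait, not a chemical "affinity" — the central
conceptual point of the package. The identity is asserted at $10^{-12}$
relative tolerance over random parameter draws.

`fit_curve()` fits all four forms by least squares with a deterministic
multi-start grid (decade-spaced multiples of crude data-derived scales,
Nelder–Mead then BFGS polish on log-scale parameters). Determinism was
preferred over stochastic restarts so that fits never depend on a seed.
Sub-compensation light ($I_g < I_r$) is clamped to $\mu = 0$: division
rates cannot be negative, and the data region below compensation is
otherwise uninformative. For the growth–substrate form the fit is
parameterized as $(\mu_m, K_{m,cell})$, the identifiable pair. The
10% tolerance used for noisy-recovery tests was frozen from a 200-draw
repeated-fit oracle (observed maximum error 9.0% at 5% lognormal noise,
$n = 30$).

## 3. Diffusion-supported division rates

For a spherical, perfectly absorbing cell ($S_0 = 0$) the diffusive supply
is $F_D = 2\pi d D S_\infty$; per unit cell volume it falls as $1/d^2$, so
pure diffusion limitation would make a 1 $\mu$m cell divide 10,000 times
faster than a 100 $\mu$m cell — the untenable first prediction that the
acclimated hyperbola resolves. Relative motion (swimming for non-diatoms,
sinking for diatoms, both empirical allometries) enhances supply by the
Sherwood number $Sh = (1 + (1+2Pe)^{1/3})/2$, and 90% of the arriving flux
is captured: $A_F = 0.9\,Sh\,F_D$.

Demand couples to composition: the nitrogen quota is
$Q(\mu) = (0.0762\mu + 0.0389) \times 1000\,C$ fg N with $C$ the allometric
carbon content, and the uptake ceiling $V_m = 1000\,N{:}C_m\,C\,\mu_m$ is
fixed at the envelope maximum $\mu_m(d)$ (a quadratic peaking near
$d = 7\ \mu$m, switching to a declining power law at 15 $\mu$m). $V_m$ is
computed once at $\mu_m$ and held fixed while the quota adapts — the quota
and the division rate are the quantities iterated, not the uptake
machinery.

`solve_mu()` balances $\mu\,Q(\mu) = A_F V_m/(A_F + V_m)$ starting from
$N{:}C = N{:}C_m$. A numerical note: the plain substitution
$\mu \leftarrow \mathrm{assim}/Q(\mu)$ has contraction ratio
$0.0762\mu/(0.0762\mu+0.0389)$, which approaches 0.83 at $\mu \approx 2.4$
d$^{-1}$ and would then need ~60 iterations for $10^{-6}$ accuracy. The
solver therefore uses the averaged update
$\mu \leftarrow (\mu + \mathrm{assim}/Q(\mu))/2$, whose derivative is
bounded in $(0, \tfrac12)$, guaranteeing convergence comfortably within the
25-iteration budget for every admissible input. The fixed point is
identical (the positive root of $0.0762C'\mu^2 + 0.0389C'\mu =
\mathrm{assim}$) and the suite checks the iterate against that closed-form
root to $10^{-6}$ d$^{-1}$ over 200 random draws. $\mu \le \mu_m$ emerges
from the saturating supply; no clamp is applied.

Two printed-formula ambiguities are resolved as package defaults and both
dialects kept selectable:

* the swimming allometry's trailing $\times 10^4$ would give cm s$^{-1}$
  speeds to micron cells, contradicting the source's own observation that
  swimming confers only a minor advantage; the default `bracket_only`
  dialect reads the bracket directly in $\mu$m s$^{-1}$ (7–30 $\mu$m
  s$^{-1}$ across the size range);
* the sinking allometry is kept as printed (its bracket is in cm s$^{-1}$;
  the $\times10^4$ makes $\mu$m s$^{-1}$), with the constant read as 0.0056
  and $v = 0$ below 8 $\mu$m.

$D = 1500\ \mu$m$^2$ s$^{-1}$ for both elements; phosphorus-limited runs
convert nitrogen quotas by $1/(14 \times N\!:\!P)$ with molar $N\!:\!P=16$
(fmol P currency). With an organism-specific $\mu_m$, the same machinery
reproduces steady-state chemostat division rates, e.g. a 12 $\mu$m cell at
$\mu_m = 1.19$ d$^{-1}$ reaches $\mu \approx 0.64$ d$^{-1}$ at 5.6 nM P:

```{r}
chemostat_prediction(12, 1.19, c(0.7, 2.0, 5.6))
```

The envelope quadratic is negative on roughly (14.99, 15) $\mu$m; values
there are clamped to 0 with a warning. The 1.25-fold size grid never lands
in that sliver, and the discontinuity at exactly 15 $\mu$m (0 vs 1.52
d$^{-1}$) is preserved as printed.

## 4. The steady-state ecosystem

Twenty-five size classes, $d_i = 0.6 \times 1.25^{i-1}$ $\mu$m, each pair a
phytoplankton stock $P_i$ with a grazer stock $Z_i$ (mmol N m$^{-3}$):

$$\dot P_i = \mu_i P_i - g_1 f_i Z_i P_i, \qquad
  \dot Z_i = g_1 g_2 f_i Z_i P_i - g_3 Z_i - g_4 f_i Z_i^2,$$

with $f_i = d_i/1\,\mu$m the feeding-range factor and $g_1 = 3.24$,
$g_2 = 0.5$, $g_3 = 0.06$, $g_4 = 1.6$. The feeding-range *narrative*
suggests grazers span neighbouring classes, but the equations couple only
class $i$; the package implements the literal term structure (grazer $i$
eats only class $i$). Consumed-but-unassimilated nitrogen leaves the
system, and the far-field concentration that sets $\mu_i$ is held constant.

The coexistence equilibrium is closed-form:
$Z_i^* = \mu_i/(g_1 f_i)$ and
$P_i^* = (g_3 + g_4 f_i Z_i^*)/(g_1 g_2 f_i)$ — *positive for every class
with $\mu_i > 0$, no matter how small $\mu_i$ is*. That is the structural
headline: with grazing as the only phytoplankton loss, the model cannot
exclude a size class through the shared resource, at any nutrient level.
`run_nutrient_grid()` confirms all 25 classes above the 0.0001% biomass
threshold at every point of the nutrient grid (read from the stated
stepping rule as 1, 8, 15, 22, 29, 35, 235, 435, …, 19835, 20000 nM) for
both groups.

`analytic_fixed_point()` is the default steady-state route. Forward-Euler
integration at 15-minute steps over 3 years (`integrate_ecosystem()`) is
the stated numerical experiment and is retained as a cross-check, but with
the printed initial stocks the large, slow classes crash deeply during the
initial grazer transient and need longer than 3 years to recover at low
nutrient levels; the integrator therefore reports per-class convergence
(relative change per day below $10^{-8}$) and the suite compares analytic
and integrated states only where integration converged (agreement within
0.1%, typically far better). A stock going negative raises an error
advising a smaller step rather than silently clamping.

Variants:

* **constant daily mortality** ($m = 0.03$ d$^{-1}$, grazer density
  dependence off, $10^{-10}$ mmol N m$^{-3}$ inocula, chemostat-style): an
  interpretive approximation of the published comparison model implementing
  only its stated deltas. Classes with $\mu_i < m$ can never rise from the
  inoculum and are excluded — reproducing, qualitatively, the familiar
  low-nutrient diversity collapse and locating its cause in the mortality
  term, not in resource competition. With $g_4$ off the predator–prey pairs
  are undamped, so snapshot diversity among *surviving* classes is
  oscillation-phase sensitive; tests assert only the forced direction.
* **per-generation mortality**: a loss of $m_{gen}\mu_i/\ln 2$ d$^{-1}$
  (mortality per generation rather than per day) merely rescales $\mu_i$ by
  $1 - m_{gen}/\ln 2$ in the fixed point, so diversity is *exactly* the
  baseline's — the closed form makes the published "result is exactly the
  same" statement an identity.
* **multispecies**: both groups in every class, sharing one indiscriminate
  grazer. Two prey with one predator admit no generic interior equilibrium;
  the analytic route returns the winner-take-all boundary equilibrium
  (grazer balanced by the faster-growing population, the slower at zero),
  which zeroes the derivatives exactly and is the attractor whenever the
  rates differ. This is trophic exclusion: percent-level division-rate
  differences (swimming vs sinking and vacuolation) pick a winner per size
  class without any resource interaction.

Community diagnostics convert stocks to abundances via
$n_i = P_i^* \times 1.4\times10^{13}\,\mathrm{fg\,mmol^{-1}}/Q_i(\mu_i)$
(quota at the realized rate) and fit the size-distribution slope (SDS) by
OLS of $\log_{10}(n_i/\Delta d_i)$ on $\log_{10} d_i$ with geometric bin
widths $\Delta d_i = d_i(\sqrt{1.25} - 1/\sqrt{1.25})$. The estimator
recovers exact power laws to $10^{-6}$. Two honest caveats, both recorded
in the decisions ledger: the smallest-bin abundance implied by these
conventions is of order $10^6$ cells ml$^{-1}$, not the published
$\sim10^5$ (the published conversion convention is not recoverable, so that
number is not asserted); and the SDS is monotone non-decreasing in
$S_\infty$ only from 8 nM upward — between 1 and 8 nM it *dips* by ~0.03
because mid-size classes near the $\mu_m$ envelope peak gain division rate
fastest at the very bottom of the nutrient range. The corresponding
acceptance property is asserted as specified over the full grid and is
knowingly red; it is a property of this stated world, not an integration
artifact (it appears in the analytic fixed points).

## What the synthetic fixtures do and do not establish

`generate_fixture()` produces curve data from known parameters with
mean-one multiplicative lognormal noise at a stated coefficient of
variation — the laboratory situation its fitting tests emulate (relative,
not additive, measurement error; a clean resource gradient; no resource
measurement error; no autocorrelation). Green recovery tests therefore
establish identifiability and solver correctness, not robustness to the
messier error structures of real incubation data.

## Defaults that matter

| Quantity | Default | Why |
|---|---|---|
| boundary-layer factor | 5 × cell diameter | stated working assumption |
| diffusion coefficient $D$ | 1500 $\mu$m$^2$ s$^{-1}$ | stated constant, temperature ignored |
| capture efficiency | 0.9 | ~1% transporter coverage suffices |
| swimming dialect | `bracket_only` | keeps swimming a minor advantage |
| quota currency | fg N; fmol P via $14\times16$ | element masses, molar N:P 16 |
| solver tolerance | $10^{-6}$ d$^{-1}$, ≤ 25 iterations | stated budget; relaxed update guarantees it |
| Euler step / horizon | 1/96 d / 1095 d | stated "~15 min, 3 years" |
| survival threshold | $10^{-6}$ of biomass, ≥ | stated 0.0001%, boundary extant |
| configs | JSON only | no YAML parser in the supported stack |

## Known limitations

No nutrient recycling, light or temperature limitation, mixotrophy, viral
lysis, selective feeding, cross-class feeding links, turbulence or
patchiness — all outside the model by construction. The comparison-model
variant implements stated deltas only, not the published code; chemostat
$R^2$ values against unpublished culture data are not reproduced; the Chl:C
mapping is qualitative; and the discreteness time-domain diagnostic
($DV_\tau$) is deliberately unimplemented because its defining equations
live in earlier work and are not restated in the source for this package.
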