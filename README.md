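# phytodisc

Size-structured phytoplankton growth and ecosystem modelling for discrete,
distantly-spaced cells.

## The problem

In the oligotrophic ocean, plankton ecosystem models typically predict
that large phytoplankton size classes are competitively excluded — small
cells, with their apparently higher nutrient "affinities", draw the shared
nutrient pool below what large cells can live on. Observations say
otherwise: size distributions are a continuum everywhere, with large cells
persisting at low abundance. `phytodisc` is for plankton ecologists and
ecosystem modellers who want to work through the quantitative case that
this exclusion is an artifact: at natural abundances cells are hundreds of
body lengths apart, their nutrient boundary layers essentially never
overlap, and steady-state growth is set by diffusion physics plus an
evolved rate ceiling — not by direct competition.

## What it computes

1. **Size-spectrum arithmetic.** For a truncated power-law community
   \(N(d) = N_0 (d/d_0)^{-\xi}\): total abundance
   \(n = \frac{d_0 N_0}{1-\xi}[(d_{max}/d_0)^{1-\xi} -
   (d_{min}/d_0)^{1-\xi}]\), occupied volume, mean diameters, carbon
   biomass, cube-root spacing \(\lambda = n^{-1/3}\) and the
   boundary-layer overlap diagnostic \(DV_\lambda = d_{soi}/\lambda\).
2. **Production–resource curves.** Short-term tanh forms
   \(P = P_m\tanh(\alpha_P I/P_m)\) vs acclimated rectangular hyperbolae
   \(\mu = \mu_m S_\infty/(S_\infty + K_{m,cell})\), their saturation
   anchors (0.76 vs 0.5 of maximum), the Michaelis–Menten equivalence
   \(K_{m,cell} = V_m/\alpha_v\), and deterministic least-squares fitting.
3. **Diffusion-supported division rates.** Supply
   \(A_F = 0.9\,Sh(Pe)\,2\pi d D S_\infty\) balanced against demand
   \(\mu\,Q(\mu)\) with the quota tied to composition,
   \(N\!:\!C = 0.0762\mu + 0.0389\), and the uptake ceiling
   \(V_m = 1000\,N\!:\!C_m\,C\,\mu_m\); solved by a guarded fixed-point
   iteration (≤ 25 iterations) whose answer equals a quadratic closed-form
   root. Includes phosphorus-limited chemostat predictions.
4. **Steady-state NPZ ecosystem.** 25 size classes
   \(d_i = 0.6\times1.25^{i-1}\,\mu\)m with per-class grazers,
   \(\dot P_i = \mu_i P_i - g_1 f_i Z_i P_i\),
   \(\dot Z_i = g_1 g_2 f_i Z_i P_i - g_3 Z_i - g_4 f_i Z_i^2\);
   closed-form coexistence equilibrium
   \(Z_i^* = \mu_i/(g_1 f_i)\),
   \(P_i^* = (g_3 + g_4 f_i Z_i^*)/(g_1 g_2 f_i)\), Euler integration,
   diversity counts, size-distribution slopes, and multispecies /
   mortality variants.

## Worked example

How dilute is an oligotrophic community (slope 4.5, *Prochlorococcus*
anchored at 2×10⁴ cells ml⁻¹)?

```r
library(phytodisc)
spacing_report(calibrated_spectrum(4.5, 2e4))
#> <discreteness_report>
#>   n_total           3.151e+04 cells ml^-1
#>   lambda                316.6 um (377 body lengths)
#>   mean diameter         1.134 um (volume), 0.84 um (number)
#>   vol fraction      2.408e-08 (2.4e-06%)
#>   carbon                4.466 ng ml^-1
#>   DV_lambda           0.01327 (d_soi = 4.2 um)
```

3.2×10⁴ cells ml⁻¹ in total, occupying 0.0000024% of the water, each on
average 377 body lengths from its neighbour, with boundary layers covering
~1% of the spacing (`DV_lambda` ≪ 1): no direct resource competition.

What can a 0.6 µm cell do on 1 nM nitrogen?

```r
solve_mu(0.6, "non_diatom", transport_context(s_inf_nm = 1))
#> <growth_solution> d = 0.6 um (non_diatom, N-limited): mu = 0.631772 d^-1 (mu_m = 0.7579)
#>   Sh = 1.001 (Pe = 0.002971); F_D = 6.84, A_F = 6.162, assim = 1.536 per day
#>   N:C = 0.08704, quota = 2.432 (15 iterations)
```

Diffusion supplies 6.8 fg N d⁻¹, barely enhanced by swimming (Sh ≈ 1.001);
after folding through the acclimated uptake hyperbola the cell assimilates
1.54 fg N d⁻¹ against a 2.43 fg N quota and divides at 0.63 d⁻¹ — already
83% of its maximum rate at one nanomolar nitrogen.

Does anybody go extinct? Steady states across nutrient levels:

```r
run_nutrient_grid(s_inf_nm = c(1, 35, 1000, 20000))
#>   s_inf_nm diversity       sds  total_p  total_z
#> 1        1        25 -5.046816 1.465906 1.172911
#> 2       35        25 -5.037654 2.634403 2.356013
#> 3     1000        25 -4.884783 3.136929 2.864821
#> 4    20000        25 -4.847278 3.203975 2.932705
```

All 25 size classes persist above the 0.0001%-of-biomass threshold at
every concentration from 1 nM to 20 µM — including the 127 µm class
dividing at 0.002 d⁻¹ — and the size-distribution slope tilts upward as
nutrients increase. Re-introducing a constant daily mortality of 0.03 d⁻¹
(`variant_options(m_loss = 0.03, use_g4 = FALSE, ward_init = TRUE)` with
`integrate_ecosystem()`) reproduces the familiar low-nutrient extinction
of large classes: the losses, not resource competition, do the excluding.

## Command line

```sh
Rscript inst/cli/phytodisc spectrum --xi 4.5 --prochlorococcus 2e4
Rscript inst/cli/phytodisc growth --diameter 12 --group non_diatom \
    --s-inf-nm 5.6 --element P --mu-max 1.19
Rscript inst/cli/phytodisc grid --group diatom --out results/
Rscript inst/cli/phytodisc fit --model mu_irradiance --data curve.csv
```

Configuration is JSON (`--config run.json`) mirroring `default_config()`;
unknown keys are rejected by path. CSV outputs come with a JSON manifest
recording the effective configuration.

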