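# Diffusion-supported, acclimated division rates for single cells.
#
# Transport: steady diffusion to a perfect-absorber sphere, F_D = 2 pi d D S,
# enhanced by relative motion through the Sherwood number Sh(Pe) and captured
# with 90% efficiency, A_F = 0.9 Sh F_D. Demand: the nitrogen quota tracks
# division rate through N:C(mu) = 0.0762 mu + 0.0389 and the allometric
# carbon content; the realized mu balances assimilation against mu * Q(mu).
#
# Unit conventions: nitrogen currency in fg N cell^-1 (14 g mol^-1); runs
# limited by phosphorus carry quotas and fluxes in fmol P cell^-1 with a
# molar N:P of 16. 1 nM N = 1.4e-8 fg N um^-3; 1 nM = 1e-9 fmol um^-3.

pd_fg_N_per_um3_per_nM <- 1.4e-8
pd_fmol_per_um3_per_nM <- 1e-9
pd_sec_per_day <- 86400

#' Allometric cell carbon content
#'
#' \eqn{C = 10^a \mathrm{Vol}^b} pg with \eqn{\mathrm{Vol} = (\pi/6) d^3} and
#' group-specific `(a, b)` from [carbon_volume_model()].
#'
#' @param d Cell diameter (\eqn{\mu}m), > 0 (vectorized).
#' @param group `"non_diatom"` or `"diatom"`.
#' @return Carbon content (pg C cell\eqn{^{-1}}).
#' @export
carbon_content <- function(d, group = c("non_diatom", "diatom")) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  cv <- carbon_volume_model(pd_match_group(group))
  10^cv$log_intercept * ((pi / 6) * d^3)^cv$log_exponent
}

#' Maximum division rate envelope across cell size
#'
#' Upper envelope of literature maximum doublings per day, converted to
#' specific rates by ln 2: a quadratic in diameter below 15 \eqn{\mu}m
#' (peaking near d = 7 \eqn{\mu}m) and a declining power law at and above
#' 15 \eqn{\mu}m. The quadratic dips below zero on roughly (14.99, 15)
#' \eqn{\mu}m; such values are clamped to 0 with a warning (the standard
#' 1.25-fold size grid never lands there).
#'
#' @param d Cell diameter (\eqn{\mu}m), > 0 (vectorized).
#' @return \eqn{\mu_m} (d\eqn{^{-1}}).
#' @export
mu_max_envelope <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  out <- ifelse(d < 15,
    (-0.0555 * d^2 + 0.789 * d + 0.64) * log(2),
    9.29 * d^(-0.533) * log(2)
  )
  if (any(out < 0)) {
    warning("mu_max envelope negative (quadratic branch); clamped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Nitrogen-to-carbon ratio as a function of division rate
#'
#' Linear composition relation for nutrient-limited growth:
#' `N:C = 0.0762 mu + 0.0389` (fg N per fg C).
#'
#' @param mu Division rate (d\eqn{^{-1}}), \eqn{\ge 0} (vectorized).
#' @return N:C ratio (fg/fg).
#' @export
nc_of_mu <- function(mu) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    pd_stop("`mu` must be non-negative", "domain_error")
  }
  0.0762 * mu + 0.0389
}

#' Size-dependent swimming velocity (non-diatoms)
#'
#' Power-law allometry \eqn{93 (d/10^4)^{0.26}}. Two dialects are shipped:
#' `"bracket_only"` (default) reads the bracketed expression directly in
#' \eqn{\mu}m s\eqn{^{-1}} (7--30 \eqn{\mu}m s\eqn{^{-1}} over the
#' phytoplankton size range, consistent with swimming conferring only a
#' minor transport advantage); `"as_printed"` multiplies by \eqn{10^4},
#' which yields cm-per-second speeds and is retained only for comparison.
#'
#' @param d Cell diameter (\eqn{\mu}m), > 0 (vectorized).
#' @param dialect `"bracket_only"` or `"as_printed"`.
#' @return Velocity (\eqn{\mu}m s\eqn{^{-1}}).
#' @export
swimming_velocity <- function(d, dialect = c("bracket_only", "as_printed")) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  dialect <- match.arg(dialect)
  v <- 93 * (d / 1e4)^0.26
  if (dialect == "as_printed") v <- v * 1e4
  v
}

#' Size-dependent sinking velocity (diatoms)
#'
#' \eqn{[0.0007 \ln(d/20000) + 0.0056] \times 10^4} \eqn{\mu}m s\eqn{^{-1}}
#' for \eqn{d \ge 8} \eqn{\mu}m, zero below 8 \eqn{\mu}m, floored at 0.
#'
#' @param d Cell diameter (\eqn{\mu}m), > 0 (vectorized).
#' @return Velocity (\eqn{\mu}m s\eqn{^{-1}}).
#' @export
sinking_velocity <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  ifelse(d < 8, 0, pmax(0, (0.0007 * log(d / 20000) + 0.0056) * 1e4))
}

#' Peclet number
#'
#' Ratio of advective to diffusive transport, \eqn{Pe = d v / D}.
#'
#' @param d Diameter (\eqn{\mu}m). @param v Velocity (\eqn{\mu}m
#'   s\eqn{^{-1}}), \eqn{\ge 0}. @param D Diffusion coefficient
#'   (\eqn{\mu}m\eqn{^2} s\eqn{^{-1}}), > 0.
#' @return Dimensionless Peclet number.
#' @export
peclet <- function(d, v, D = 1500) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    pd_stop("`D` must be positive", "domain_error")
  }
  if (any(v < 0)) pd_stop("`v` must be non-negative", "domain_error")
  d * v / D
}

#' Sherwood number for a moving sphere
#'
#' \eqn{Sh = \frac{1}{2}(1 + (1 + 2 Pe)^{1/3})}: the multiplicative
#' enhancement of diffusive flux due to relative motion; `Sh(0) = 1`.
#'
#' @param pe Peclet number, \eqn{\ge 0} (vectorized).
#' @return Sherwood number, \eqn{\ge 1}.
#' @export
sherwood <- function(pe) {
  if (any(!is.finite(pe)) || any(pe < 0)) {
    pd_stop("`pe` must be non-negative", "domain_error")
  }
  0.5 * (1 + (1 + 2 * pe)^(1 / 3))
}

#' Transport context for diffusion-growth calculations
#'
#' Bundles the physical constants of a run: diffusion coefficient, far-field
#' concentration, capture efficiency, swimming-velocity dialect, limiting
#' element and molar N:P. The cell surface is a perfect absorber
#' (\eqn{S_0 = 0}).
#'
#' @param s_inf_nm Far-field concentration of the limiting element (nM),
#'   \eqn{\ge 0}.
#' @param D Diffusion coefficient (\eqn{\mu}m\eqn{^2} s\eqn{^{-1}}),
#'   default 1500 for both N and P.
#' @param capture_eff Fraction of arriving flux captured (default 0.9,
#'   about 1% membrane transporter coverage).
#' @param velocity_dialect Passed to [swimming_velocity()].
#' @param element `"N"` (fluxes and quotas in fg N) or `"P"` (fmol P).
#' @param np_ratio Molar N:P used to convert nitrogen quotas for P-limited
#'   runs (default 16).
#' @return Object of class `"transport_context"`.
#' @export
transport_context <- function(s_inf_nm, D = 1500, capture_eff = 0.9,
                              velocity_dialect = c("bracket_only", "as_printed"),
                              element = c("N", "P"), np_ratio = 16) {
  pd_check_scalar(s_inf_nm, "s_inf_nm", nonneg = TRUE)
  pd_check_scalar(D, "D", positive = TRUE)
  pd_check_scalar(capture_eff, "capture_eff", positive = TRUE)
  if (capture_eff > 1) pd_stop("`capture_eff` must be <= 1", "domain_error")
  pd_check_scalar(np_ratio, "np_ratio", positive = TRUE)
  structure(
    list(
      s_inf_nm = s_inf_nm, D = D, s0 = 0, capture_eff = capture_eff,
      velocity_dialect = match.arg(velocity_dialect),
      element = match.arg(element), np_ratio = np_ratio
    ),
    class = "transport_context"
  )
}

pd_conc_per_um3 <- function(ctx) {
  ctx$s_inf_nm * switch(ctx$element,
    N = pd_fg_N_per_um3_per_nM,
    P = pd_fmol_per_um3_per_nM
  )
}

#' Diffusive flux to a stationary perfect-absorber cell
#'
#' \eqn{F_D = 2\pi d D S_\infty} per day, in fg N d\eqn{^{-1}} (element
#' `"N"`) or fmol P d\eqn{^{-1}} (element `"P"`). Linear in both `d` and
#' \eqn{S_\infty}.
#'
#' @param d Diameter (\eqn{\mu}m), > 0 (vectorized).
#' @param ctx A [transport_context()].
#' @return Flux per cell per day.
#' @export
diffusive_flux <- function(d, ctx) {
  stopifnot(inherits(ctx, "transport_context"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  2 * pi * d * ctx$D * pd_conc_per_um3(ctx) * pd_sec_per_day
}

#' Volume-specific diffusive flux
#'
#' \eqn{F_D / ((\pi/6) d^3) = 3 D S_\infty / (d/2)^2}: scales as
#' \eqn{1/d^2}, so under pure diffusion limitation a 1 \eqn{\mu}m cell would
#' divide 10,000 times faster than a 100 \eqn{\mu}m cell.
#'
#' @inheritParams diffusive_flux
#' @return Flux per unit cell volume per day.
#' @export
volume_specific_flux <- function(d, ctx) {
  diffusive_flux(d, ctx) / ((pi / 6) * d^3)
}

pd_group_velocity <- function(d, group, ctx) {
  switch(group,
    non_diatom = swimming_velocity(d, ctx$velocity_dialect),
    diatom     = sinking_velocity(d)
  )
}

#' Potential nutrient flux available for assimilation
#'
#' \eqn{A_F = 0.9\, Sh\, F_D} using the group-appropriate relative motion
#' (swimming for non-diatoms, sinking for diatoms).
#'
#' @inheritParams diffusive_flux
#' @param group `"non_diatom"` or `"diatom"`.
#' @return Available flux per cell per day (units of [diffusive_flux()]).
#' @export
available_flux <- function(d, group = c("non_diatom", "diatom"), ctx) {
  group <- pd_match_group(group)
  v <- pd_group_velocity(d, group, ctx)
  ctx$capture_eff * sherwood(peclet(d, v, ctx$D)) * diffusive_flux(d, ctx)
}

#' Size-class phenotype for growth calculations
#'
#' Carbon content from allometry, maximum division rate from the envelope
#' (or an override for a specific organism), maximum N:C, and the maximum
#' uptake rate \eqn{V_m = 1000\, N{:}C_m\, C\, \mu_m} (fg N cell\eqn{^{-1}}
#' d\eqn{^{-1}}) that exactly supports \eqn{\mu_m}.
#'
#' @param d Diameter (\eqn{\mu}m), > 0.
#' @param group `"non_diatom"` or `"diatom"`.
#' @param mu_max Optional override of the envelope \eqn{\mu_m}
#'   (d\eqn{^{-1}}).
#' @return Object of class `"cell_phenotype"` with fields `d`, `group`,
#'   `c_pg`, `mu_max`, `nc_max`, `v_max_fg`.
#' @export
cell_phenotype <- function(d, group = c("non_diatom", "diatom"), mu_max = NULL) {
  pd_check_scalar(d, "d", positive = TRUE)
  group <- pd_match_group(group)
  mu_max <- if (is.null(mu_max)) mu_max_envelope(d) else
    pd_check_scalar(mu_max, "mu_max", positive = TRUE)
  c_pg <- carbon_content(d, group)
  nc_max <- nc_of_mu(mu_max)
  structure(
    list(d = d, group = group, c_pg = c_pg, mu_max = mu_max,
         nc_max = nc_max, v_max_fg = 1000 * nc_max * c_pg * mu_max),
    class = "cell_phenotype"
  )
}

# Quota at division rate mu, in the element units of ctx:
# fg N cell^-1 for N runs; fmol P cell^-1 (= fg N / (14 * N:P)) for P runs.
pd_quota <- function(mu, c_pg, ctx) {
  q <- nc_of_mu(mu) * c_pg * 1000
  if (ctx$element == "P") q <- q / (14 * ctx$np_ratio)
  q
}

#' Solve for the diffusion-supported acclimated division rate
#'
#' Combines supply and demand for one cell. Supply: available flux
#' \eqn{A_F} folded against the uptake capacity \eqn{V_m} through the
#' acclimated rectangular hyperbola, giving the assimilation rate
#' \eqn{A_F V_m / (A_F + V_m)}. Demand: division at rate \eqn{\mu} consumes
#' \eqn{\mu\, Q(\mu)} where the quota \eqn{Q(\mu)} tracks the realized N:C.
#' The solver starts from \eqn{\mu_0 =} assimilation\eqn{/Q(\mu_m)} (i.e.
#' N:C at its maximum) and iteratively re-adjusts N:C and \eqn{\mu}; a
#' relaxed (averaged) update guarantees stability within the 25-iteration
#' budget for every input. The fixed point is the positive root of
#' \eqn{0.0762 C' \mu^2 + 0.0389 C' \mu = } assimilation
#' (\eqn{C' = 1000 C}), and \eqn{\mu \le \mu_m} emerges without clamping.
#'
#' @param d Diameter (\eqn{\mu}m). @param group Cell group.
#' @param ctx A [transport_context()] (element `"N"` or `"P"`).
#' @param mu_max Optional \eqn{\mu_m} override (d\eqn{^{-1}}).
#' @param tol Convergence tolerance on successive \eqn{\mu} iterates
#'   (d\eqn{^{-1}}), default 1e-6.
#' @param max_iter Iteration cap, default 25.
#' @return Object of class `"growth_solution"`: `mu`, `nc`, `q` (element
#'   units), `f_d`, `sh`, `pe`, `a_f`, `assim`, `v_max`, `mu_max`,
#'   `iterations`, `converged`, plus the inputs.
#' @export
solve_mu <- function(d, group = c("non_diatom", "diatom"), ctx,
                     mu_max = NULL, tol = 1e-6, max_iter = 25) {
  stopifnot(inherits(ctx, "transport_context"))
  group <- pd_match_group(group)
  phen <- cell_phenotype(d, group, mu_max)
  v <- pd_group_velocity(d, group, ctx)
  pe <- peclet(d, v, ctx$D)
  sh <- sherwood(pe)
  f_d <- diffusive_flux(d, ctx)
  a_f <- ctx$capture_eff * sh * f_d
  v_max <- phen$v_max_fg
  if (ctx$element == "P") v_max <- v_max / (14 * ctx$np_ratio)
  assim <- if (a_f + v_max > 0) a_f * v_max / (a_f + v_max) else 0

  if (assim == 0) {
    mu <- 0
    iters <- 0L
    converged <- TRUE
  } else {
    mu <- assim / pd_quota(phen$mu_max, phen$c_pg, ctx)
    iters <- 0L
    converged <- FALSE
    repeat {
      iters <- iters + 1L
      mu_new <- 0.5 * (mu + assim / pd_quota(mu, phen$c_pg, ctx))
      step <- abs(mu_new - mu)
      mu <- mu_new
      if (step < tol) converged <- TRUE
      if (step < tol * 1e-4 || iters >= max_iter) break
    }
    if (!converged) {
      pd_stop(sprintf(
        "division-rate iteration not stable after %d iterations (last mu = %g)",
        iters, mu), "convergence_error")
    }
  }
  structure(
    list(
      mu = mu, nc = nc_of_mu(mu), q = pd_quota(mu, phen$c_pg, ctx),
      f_d = f_d, sh = sh, pe = pe, a_f = a_f, assim = assim,
      v_max = v_max, mu_max = phen$mu_max, c_pg = phen$c_pg,
      d = d, group = group, element = ctx$element,
      iterations = iters, converged = converged
    ),
    class = "growth_solution"
  )
}

#' @export
print.growth_solution <- function(x, ...) {
  cat(sprintf(
    "<growth_solution> d = %g um (%s, %s-limited): mu = %.6g d^-1 (mu_m = %.4g)\n",
    x$d, x$group, x$element, x$mu, x$mu_max))
  cat(sprintf("  Sh = %.4g (Pe = %.4g); F_D = %.4g, A_F = %.4g, assim = %.4g per day\n",
              x$sh, x$pe, x$f_d, x$a_f, x$assim))
  cat(sprintf("  N:C = %.4g, quota = %.4g (%d iterations)\n", x$nc, x$q, x$iterations))
  invisible(x)
}

#' Chemostat division-rate predictions under phosphorus limitation
#'
#' Applies [solve_mu()] with element `"P"` across a set of far-field
#' phosphate concentrations for a fixed cell size and organism-specific
#' \eqn{\mu_m}, mirroring steady-state chemostat experiments.
#'
#' @param d Cell diameter (\eqn{\mu}m).
#' @param mu_max Organism \eqn{\mu_m} (d\eqn{^{-1}}).
#' @param s_inf_nm Vector of far-field phosphate concentrations (nM).
#' @param group Cell group (default `"non_diatom"`; the classic chemostat
#'   organisms are flagellates).
#' @param ... Further arguments to [transport_context()] (e.g. `np_ratio`).
#' @return Data frame with columns `s_inf_nm`, `mu`.
#' @export
chemostat_prediction <- function(d, mu_max, s_inf_nm, group = "non_diatom", ...) {
  mu <- vapply(s_inf_nm, function(s) {
    ctx <- transport_context(s_inf_nm = s, element = "P", ...)
    solve_mu(d, group, ctx, mu_max = mu_max)$mu
  }, numeric(1))
  data.frame(s_inf_nm = s_inf_nm, mu = mu)
}

#' Division-rate size spectrum at fixed nutrient levels
#'
#' Solves [solve_mu()] on a log-spaced diameter grid for each far-field
#' concentration, for plotting division-rate spectra.
#'
#' @param s_inf_nm Vector of far-field N concentrations (nM).
#' @param dmin,dmax Diameter range (\eqn{\mu}m). @param n Grid size.
#' @param group Cell group. @param ... Passed to [transport_context()].
#' @return Data frame with columns `d`, `s_inf_nm`, `mu`, `sh`, `pe`, `a_f`.
#' @export
growth_spectrum <- function(s_inf_nm, dmin = 0.6, dmax = 130, n = 60,
                            group = "non_diatom", ...) {
  d <- exp(seq(log(dmin), log(dmax), length.out = n))
  out <- lapply(s_inf_nm, function(s) {
    ctx <- transport_context(s_inf_nm = s, ...)
    sols <- lapply(d, solve_mu, group = group, ctx = ctx)
    data.frame(
      d = d, s_inf_nm = s,
      mu = vapply(sols, `[[`, numeric(1), "mu"),
      sh = vapply(sols, `[[`, numeric(1), "sh"),
      pe = vapply(sols, `[[`, numeric(1), "pe"),
      a_f = vapply(sols, `[[`, numeric(1), "a_f")
    )
  })
  do.call(rbind, out)
}
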