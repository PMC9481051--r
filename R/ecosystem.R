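# Steady-state size-structured phytoplankton-zooplankton model.
#
# Each of j size classes pairs a phytoplankton nitrogen stock P_i with a
# dedicated grazer stock Z_i (both mmol N m^-3):
#   dP_i/dt = mu_i P_i - g1 f_i Z_i P_i                      (- extra losses)
#   dZ_i/dt = g1 g2 f_i Z_i P_i - g3 Z_i - g4 f_i Z_i^2      (- outflow)
# with f_i = d_i / 1 um the feeding-range factor. Nitrogen removed by
# inefficient grazing or grazer mortality leaves the system (no recycling);
# the far-field nutrient concentration that sets mu_i is held constant.

#' Geometric size-class grid
#'
#' Diameters \eqn{d_i = 0.6 \times 1.25^{i-1}} \eqn{\mu}m and feeding
#' factors \eqn{f_i = d_i / 1\,\mu m} (a predator with mean prey size 100
#' \eqn{\mu}m feeds over 50--150 \eqn{\mu}m, hence a range of 100).
#' In multispecies mode every class carries one diatom and one non-diatom
#' population sharing the class grazer.
#'
#' @param n_classes Number of size classes (default 25, spanning 0.6 to
#'   127.1 \eqn{\mu}m).
#' @param multispecies If `TRUE`, duplicate each class into both groups.
#' @param group Group used for every population when `multispecies = FALSE`.
#' @return Object of class `"size_class_grid"`: `d`, `f` (length
#'   `n_classes`), `pop_class`, `pop_group` (length `n_pops`),
#'   `n_classes`, `n_pops`, `multispecies`.
#' @export
size_class_grid <- function(n_classes = 25, multispecies = FALSE,
                            group = c("non_diatom", "diatom")) {
  if (!is.numeric(n_classes) || n_classes < 1) {
    pd_stop("`n_classes` must be >= 1", "domain_error")
  }
  n_classes <- as.integer(n_classes)
  d <- 0.6 * 1.25^(seq_len(n_classes) - 1)
  if (multispecies) {
    pop_class <- rep(seq_len(n_classes), each = 2L)
    pop_group <- rep(c("non_diatom", "diatom"), times = n_classes)
  } else {
    pop_class <- seq_len(n_classes)
    pop_group <- rep(pd_match_group(group), n_classes)
  }
  structure(
    list(d = d, f = d / 1, pop_class = pop_class, pop_group = pop_group,
         n_classes = n_classes, n_pops = length(pop_class),
         multispecies = multispecies),
    class = "size_class_grid"
  )
}

#' Ecosystem parameters
#'
#' Grazing and integration constants. Defaults: grazing rate `g1` = 3.24
#' m\eqn{^3} mmol\eqn{^{-1}} d\eqn{^{-1}}, ingestion efficiency `g2` = 0.5,
#' linear zooplankton mortality `g3` = 0.06 d\eqn{^{-1}}, density-dependent
#' zooplankton mortality `g4` = 1.6 m\eqn{^3} mmol\eqn{^{-1}} d\eqn{^{-1}};
#' ~15-minute Euler steps (`dt` = 1/96 d) for 3 years (`t_max` = 1095 d);
#' survival threshold `extinct_frac` = 1e-6 (0.0001% of total biomass);
#' initial stocks 0.18 (phytoplankton) and 0.04 (zooplankton) mmol N
#' m\eqn{^{-3}} per class.
#'
#' @param g1,g2,g3,g4 Grazing constants (see above).
#' @param dt Time step (d). @param t_max Duration (d).
#' @param extinct_frac Diversity threshold as a biomass fraction.
#' @param p_init,z_init Initial stocks (mmol N m\eqn{^{-3}}).
#' @return Object of class `"ecosystem_params"`.
#' @export
ecosystem_params <- function(g1 = 3.24, g2 = 0.5, g3 = 0.06, g4 = 1.6,
                             dt = 1 / 96, t_max = 1095, extinct_frac = 1e-6,
                             p_init = 0.18, z_init = 0.04) {
  for (nm in c("g1", "g2", "g3", "g4", "dt", "t_max", "extinct_frac",
               "p_init", "z_init")) {
    pd_check_scalar(get(nm), nm, positive = nm %in% c("g1", "g2", "g3", "g4", "dt", "t_max"),
                    nonneg = TRUE)
  }
  structure(
    list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, dt = dt, t_max = t_max,
         extinct_frac = extinct_frac, p_init = p_init, z_init = z_init),
    class = "ecosystem_params"
  )
}

#' Model-variant switches
#'
#' Baseline has no non-grazing phytoplankton loss. Variants: a constant
#' daily mortality `m_loss` (the mechanism that drives large-cell extinction
#' in chemostat-style models), a media outflow `kappa` applied to both
#' stocks, disabling the density-dependent grazer mortality (`use_g4 =
#' FALSE`), a per-generation mortality applied as
#' `per_generation_m * mu_i / ln 2` d\eqn{^{-1}} (generations per day =
#' \eqn{\mu/\ln 2}), and `ward_init` which starts every stock at 1e-10
#' mmol N m\eqn{^{-3}}.
#'
#' @param m_loss Non-grazing phytoplankton mortality (d\eqn{^{-1}}).
#' @param kappa Outflow rate (d\eqn{^{-1}}), applied to P and Z.
#' @param use_g4 Keep the quadratic grazer mortality term.
#' @param per_generation_m Mortality per generation (dimensionless).
#' @param ward_init Start all stocks at 1e-10 mmol N m\eqn{^{-3}}.
#' @return Object of class `"variant_options"`.
#' @export
variant_options <- function(m_loss = 0, kappa = 0, use_g4 = TRUE,
                            per_generation_m = 0, ward_init = FALSE) {
  pd_check_scalar(m_loss, "m_loss", nonneg = TRUE)
  pd_check_scalar(kappa, "kappa", nonneg = TRUE)
  pd_check_scalar(per_generation_m, "per_generation_m", nonneg = TRUE)
  structure(
    list(m_loss = m_loss, kappa = kappa, use_g4 = isTRUE(use_g4),
         per_generation_m = per_generation_m, ward_init = isTRUE(ward_init)),
    class = "variant_options"
  )
}

pd_is_baseline <- function(variants) {
  variants$m_loss == 0 && variants$kappa == 0 && variants$use_g4 &&
    variants$per_generation_m == 0
}

# variants whose steady state still has a closed form: baseline, plus
# per-generation mortality (which only rescales mu)
pd_analytic_ok <- function(variants) {
  variants$m_loss == 0 && variants$kappa == 0 && variants$use_g4
}

#' Time derivatives of all stocks
#'
#' Evaluates the right-hand sides for phytoplankton populations `p` (one per
#' population; two per class in multispecies grids) and grazers `z` (one per
#' class). Each grazer consumes every population of its own class without
#' preference.
#'
#' @param p Phytoplankton stocks (mmol N m\eqn{^{-3}}), length `n_pops`.
#' @param z Zooplankton stocks (mmol N m\eqn{^{-3}}), length `n_classes`.
#' @param mu Division rates per population (d\eqn{^{-1}}), length `n_pops`.
#' @param grid A [size_class_grid()].
#' @param params An [ecosystem_params()].
#' @param variants A [variant_options()].
#' @return List with `dp` (length `n_pops`) and `dz` (length `n_classes`).
#' @export
ecosystem_derivatives <- function(p, z, mu, grid, params,
                                  variants = variant_options()) {
  stopifnot(inherits(grid, "size_class_grid"), inherits(params, "ecosystem_params"))
  if (length(p) != grid$n_pops || length(mu) != grid$n_pops ||
      length(z) != grid$n_classes) {
    pd_stop("lengths of `p`, `z`, `mu` must match the grid", "dimension_error")
  }
  f <- grid$f
  ic <- grid$pop_class
  loss <- variants$m_loss + variants$kappa +
    variants$per_generation_m * mu / log(2)
  gz <- params$g1 * f * z
  p_class <- if (grid$n_pops == grid$n_classes) p else
    as.vector(rowsum(p, ic))
  dp <- p * (mu - gz[ic] - loss)
  dz <- params$g2 * gz * p_class - params$g3 * z -
    (if (variants$use_g4) params$g4 * f * z^2 else 0) - variants$kappa * z
  list(dp = dp, dz = dz)
}

pd_steady_state <- function(p_star, z_star, mu, grid, method) {
  structure(
    list(p_star = p_star, z_star = z_star, mu = mu, grid = grid,
         method = method),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %d populations / %d classes (method = %s)\n",
              x$grid$n_pops, x$grid$n_classes, x$method))
  cat(sprintf("  total P = %.4g, total Z = %.4g mmol N m^-3; surviving classes = %d\n",
              sum(x$p_star), sum(x$z_star), diversity_count(x)))
  invisible(x)
}

#' Analytic coexistence fixed point of the baseline model
#'
#' With grazing the only phytoplankton loss, setting both derivatives to
#' zero per class gives \eqn{Z_i^* = \mu_i / (g_1 f_i)} and
#' \eqn{P_i^* = (g_3 + g_4 f_i Z_i^*) / (g_1 g_2 f_i)}: every class with a
#' positive division rate equilibrates at a positive biomass, regardless of
#' how small \eqn{\mu_i} is -- no size class is excluded through the shared
#' resource. In multispecies grids two populations share one grazer and an
#' interior coexistence point does not generically exist; the fixed point
#' returned puts each class's grazer in balance with its fastest-growing
#' population (the attractor when rates differ) and the slower population
#' at zero.
#'
#' @param mu Division rates per population (d\eqn{^{-1}}), all > 0.
#' @param grid A [size_class_grid()].
#' @param params An [ecosystem_params()].
#' @param variants A [variant_options()]; only the baseline and the
#'   per-generation-mortality variant have a closed form (the latter just
#'   rescales \eqn{\mu_i} by \eqn{1 - m_{gen}/\ln 2}); constant daily
#'   losses or outflow require [integrate_ecosystem()].
#' @return A `"steady_state"` object (`method = "analytic"`).
#' @export
analytic_fixed_point <- function(mu, grid, params = ecosystem_params(),
                                 variants = variant_options()) {
  stopifnot(inherits(grid, "size_class_grid"))
  if (length(mu) != grid$n_pops) {
    pd_stop("`mu` must have one rate per population", "dimension_error")
  }
  if (!pd_analytic_ok(variants)) {
    pd_stop("no closed-form steady state with m_loss/kappa losses or g4 disabled",
            "domain_error")
  }
  mu <- mu * (1 - variants$per_generation_m / log(2))
  if (any(mu <= 0)) {
    pd_stop("analytic fixed point requires positive net growth in every class",
            "degenerate_equilibrium")
  }
  f <- grid$f
  if (grid$n_pops == grid$n_classes) {
    mu_win <- mu
    winner <- seq_len(grid$n_pops)
  } else {
    # winner-take-all per class: grazer tracks the fastest population
    mu_win <- vapply(seq_len(grid$n_classes), function(i) {
      max(mu[grid$pop_class == i])
    }, numeric(1))
    winner <- vapply(seq_len(grid$n_classes), function(i) {
      idx <- which(grid$pop_class == i)
      idx[which.max(mu[idx])]
    }, integer(1))
  }
  z_star <- mu_win / (params$g1 * f)
  p_class <- (params$g3 + params$g4 * f * z_star) / (params$g1 * params$g2 * f)
  p_star <- numeric(grid$n_pops)
  p_star[winner] <- p_class
  pd_steady_state(p_star, z_star, mu, grid, "analytic")
}

#' Forward-Euler integration of the ecosystem
#'
#' Steps the model with explicit Euler at `params$dt` (about 15 minutes)
#' until `params$t_max` or until every stock's relative change per day
#' drops below `1e-8`. Stops with an error (suggesting a smaller `dt`) if
#' any stock goes negative, and on overflow.
#'
#' @inheritParams ecosystem_derivatives
#' @param p0,z0 Optional initial stocks; defaults come from `params`
#'   (`p_init`, `z_init`) or 1e-10 under `variants$ward_init`.
#' @return A `"steady_state"` (`method = "integrated"`) with extra fields:
#'   `t` (final time, d), `converged` (per population, relative change per
#'   day < 1e-8 at the end), `z_converged` (per class), `convergence_day`
#'   (per population; `NA` if never met).
#' @export
integrate_ecosystem <- function(mu, grid, params = ecosystem_params(),
                                variants = variant_options(),
                                p0 = NULL, z0 = NULL) {
  stopifnot(inherits(grid, "size_class_grid"))
  if (length(mu) != grid$n_pops) {
    pd_stop("`mu` must have one rate per population", "dimension_error")
  }
  init <- if (variants$ward_init) 1e-10 else NA
  p <- if (!is.null(p0)) rep_len(p0, grid$n_pops) else
    rep(if (is.na(init)) params$p_init else init, grid$n_pops)
  z <- if (!is.null(z0)) rep_len(z0, grid$n_classes) else
    rep(if (is.na(init)) params$z_init else init, grid$n_classes)
  if (any(p < 0) || any(z < 0)) {
    pd_stop("initial stocks must be non-negative", "domain_error")
  }

  dt <- params$dt
  steps_per_day <- max(1L, round(1 / dt))
  n_days <- ceiling(params$t_max / (dt * steps_per_day))
  f <- grid$f
  ic <- grid$pop_class
  single <- grid$n_pops == grid$n_classes
  loss <- variants$m_loss + variants$kappa +
    variants$per_generation_m * mu / log(2)
  g1 <- params$g1; g2 <- params$g2; g3 <- params$g3
  g4f <- if (variants$use_g4) params$g4 * f else 0
  kappa <- variants$kappa
  tiny <- 1e-300
  conv_day <- rep(NA_real_, grid$n_pops)
  day <- 0
  rel_p <- rel_z <- Inf

  while (day < n_days) {
    p_prev <- p
    z_prev <- z
    for (s in seq_len(steps_per_day)) {
      gz <- g1 * f * z
      p_class <- if (single) p else as.vector(rowsum(p, ic))
      dp <- p * (mu - gz[ic] - loss)
      dz <- g2 * gz * p_class - g3 * z - g4f * z * z - kappa * z
      p <- p + dt * dp
      z <- z + dt * dz
      if (any(p < 0) || any(z < 0)) {
        pd_stop("a stock went negative during Euler integration; use a smaller dt",
                "negative_stock")
      }
    }
    if (any(!is.finite(p)) || any(!is.finite(z))) {
      pd_stop("integration overflowed to non-finite stocks", "non_finite")
    }
    day <- day + 1
    rel_p <- abs(p - p_prev) / pmax(p_prev, tiny)
    rel_z <- abs(z - z_prev) / pmax(z_prev, tiny)
    newly <- is.na(conv_day) & rel_p < 1e-8
    conv_day[newly] <- day
    conv_day[rel_p >= 1e-8] <- NA_real_ # must stay settled
    if (max(rel_p) < 1e-8 && max(rel_z) < 1e-8) break
  }

  out <- pd_steady_state(p, z, mu, grid, "integrated")
  out$t <- day
  out$converged <- rel_p < 1e-8
  out$z_converged <- rel_z < 1e-8
  out$convergence_day <- conv_day
  out
}

#' Count surviving size classes
#'
#' A phytoplankton population is extant when its share of total
#' phytoplankton biomass is at least `extinct_frac` (boundary counts as
#' extant). In multispecies grids a class survives if either of its
#' populations does; the count is over classes.
#'
#' @param steady A `"steady_state"`, or a numeric vector of phytoplankton
#'   stocks.
#' @param extinct_frac Threshold biomass fraction (default 1e-6, i.e.
#'   0.0001%).
#' @param grid Required when `steady` is a bare numeric vector of a
#'   multispecies run; otherwise inferred.
#' @return Integer count of surviving size classes.
#' @export
diversity_count <- function(steady, extinct_frac = 1e-6, grid = NULL) {
  if (inherits(steady, "steady_state")) {
    p <- steady$p_star
    grid <- steady$grid
  } else {
    p <- as.numeric(steady)
  }
  total <- sum(p)
  if (total <= 0) {
    pd_stop("diversity is undefined for zero total biomass", "domain_error")
  }
  extant <- p / total >= extinct_frac
  if (!is.null(grid) && grid$n_pops != grid$n_classes &&
      length(p) == grid$n_pops) {
    sum(vapply(seq_len(grid$n_classes),
               function(i) any(extant[grid$pop_class == i]), logical(1)))
  } else {
    sum(extant)
  }
}

#' Convert nitrogen stocks to cell abundances
#'
#' \eqn{n_i = P_i \times 1.4\times10^{13}\,\mathrm{fg\,mmol^{-1}} / Q_i}
#' cells m\eqn{^{-3}}, reported per ml (\eqn{\div 10^6}); `q_fg` is the
#' per-cell nitrogen quota at the realized division rate.
#'
#' @param p Phytoplankton stocks (mmol N m\eqn{^{-3}}), vectorized.
#' @param q_fg Per-cell quotas (fg N cell\eqn{^{-1}}), > 0.
#' @return Cells ml\eqn{^{-1}}.
#' @export
cell_abundance <- function(p, q_fg) {
  if (any(!is.finite(q_fg)) || any(q_fg <= 0)) {
    pd_stop("`q_fg` must be positive", "domain_error")
  }
  if (any(p < 0)) pd_stop("`p` must be non-negative", "domain_error")
  p * 1.4e13 / q_fg / 1e6
}

#' Size-distribution slope of per-class abundances
#'
#' Ordinary least squares of \eqn{\log_{10}(n_i/\Delta d_i)} on
#' \eqn{\log_{10} d_i}, where \eqn{\Delta d_i = d_i(\sqrt{1.25} -
#' 1/\sqrt{1.25})} is the geometric bin width. Returns the signed slope
#' (about -4.5 in oligotrophic communities, rising toward -3 as nutrients
#' increase). Classes with non-positive abundance are dropped; at least two
#' positive classes are required.
#'
#' @param cells_per_ml Per-class abundances (cells ml\eqn{^{-1}}), length
#'   `n_classes`.
#' @param grid A [size_class_grid()].
#' @return Signed slope (dimensionless).
#' @export
size_distribution_slope <- function(cells_per_ml, grid) {
  stopifnot(inherits(grid, "size_class_grid"))
  if (length(cells_per_ml) != grid$n_classes) {
    pd_stop("`cells_per_ml` must have one value per size class", "dimension_error")
  }
  keep <- is.finite(cells_per_ml) & cells_per_ml > 0
  if (sum(keep) < 2) {
    pd_stop("need at least 2 classes with positive abundance", "degenerate_fit")
  }
  width <- grid$d * (sqrt(1.25) - 1 / sqrt(1.25))
  x <- log10(grid$d[keep])
  y <- log10(cells_per_ml[keep] / width[keep])
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Per-population division rates on a size grid
#'
#' Runs the diffusion-growth solver for every population of a grid at one
#' far-field nitrogen concentration.
#'
#' @param grid A [size_class_grid()].
#' @param s_inf_nm Far-field nitrogen concentration (nM).
#' @param ... Passed to [transport_context()] (dialect, D, ...).
#' @return List with `mu` (d\eqn{^{-1}}) and `q_fg` (fg N cell\eqn{^{-1}})
#'   per population, plus `solutions` (list of [solve_mu()] results).
#' @export
class_division_rates <- function(grid, s_inf_nm, ...) {
  stopifnot(inherits(grid, "size_class_grid"))
  ctx <- transport_context(s_inf_nm = s_inf_nm, element = "N", ...)
  sols <- lapply(seq_len(grid$n_pops), function(k) {
    solve_mu(grid$d[grid$pop_class[k]], grid$pop_group[k], ctx)
  })
  list(
    mu = vapply(sols, `[[`, numeric(1), "mu"),
    q_fg = vapply(sols, `[[`, numeric(1), "q"),
    solutions = sols
  )
}

#' Default far-field nitrogen grid
#'
#' 1 to 35 nM in 7-nM steps, then 200-nM steps up to 20 \eqn{\mu}M
#' (endpoints included).
#'
#' @return Numeric vector of concentrations (nM).
#' @export
nutrient_grid <- function() {
  c(seq(1, 29, by = 7), 35, seq(235, 19835, by = 200), 20000)
}

#' Steady states across a nutrient grid
#'
#' For each far-field concentration: per-population division rates from the
#' diffusion solver, then the steady state (analytic fixed point by
#' default, Euler integration on request), then community diagnostics.
#'
#' @param s_inf_nm Vector of far-field N concentrations (nM); default
#'   [nutrient_grid()].
#' @param grid A [size_class_grid()].
#' @param params An [ecosystem_params()].
#' @param variants A [variant_options()] (non-baseline variants require
#'   `method = "integrate"`).
#' @param method `"analytic"` or `"integrate"`.
#' @param ... Passed to [transport_context()].
#' @return Data frame with columns `s_inf_nm`, `diversity`, `sds`,
#'   `total_p`, `total_z`; the per-concentration `"steady_state"` objects
#'   are attached as attribute `"states"`.
#' @export
run_nutrient_grid <- function(s_inf_nm = nutrient_grid(),
                              grid = size_class_grid(),
                              params = ecosystem_params(),
                              variants = variant_options(),
                              method = c("analytic", "integrate"), ...) {
  method <- match.arg(method)
  if (method == "analytic" && !pd_analytic_ok(variants)) {
    pd_stop("variants with m_loss/kappa or g4 disabled require method = \"integrate\"",
            "domain_error")
  }
  states <- vector("list", length(s_inf_nm))
  rows <- lapply(seq_along(s_inf_nm), function(i) {
    rates <- class_division_rates(grid, s_inf_nm[i], ...)
    st <- if (method == "analytic") {
      analytic_fixed_point(rates$mu, grid, params, variants)
    } else {
      integrate_ecosystem(rates$mu, grid, params, variants)
    }
    states[[i]] <<- st
    n_class <- cell_abundance_by_class(st, rates$q_fg)
    sds <- tryCatch(size_distribution_slope(n_class, grid),
                    phytodisc_error = function(e) NA_real_)
    data.frame(
      s_inf_nm = s_inf_nm[i],
      diversity = diversity_count(st, params$extinct_frac),
      sds = sds,
      total_p = sum(st$p_star),
      total_z = sum(st$z_star)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "states") <- states
  out
}

# per-class cell abundance (cells ml^-1), summing multispecies populations
cell_abundance_by_class <- function(steady, q_fg) {
  n_pop <- cell_abundance(steady$p_star, q_fg)
  grid <- steady$grid
  if (grid$n_pops == grid$n_classes) n_pop else
    as.vector(rowsum(n_pop, grid$pop_class))
}
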