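# Power-law size-spectrum arithmetic and discreteness diagnostics.
#
# The community descriptor is the differential number concentration
#   N(d) = N0 * (d / d0)^(-xi)   [ml^-1 um^-1],
# whose moments over [dmin, dmax] give total abundance, total occupied volume,
# mean diameters, carbon biomass and the spacing statistics used to judge
# whether cell boundary layers can overlap.

#' Construct a power-law phytoplankton size spectrum
#'
#' A community size distribution of the form
#' \eqn{N(d) = N_0 (d/d_0)^{-\xi}} (cells ml\eqn{^{-1}} \eqn{\mu}m\eqn{^{-1}}),
#' truncated to diameters in `[dmin, dmax]`. The absolute slope \eqn{\xi} is
#' near 4.5 in oligotrophic waters and tilts toward 3 as nutrients increase.
#'
#' @param N0 Differential number concentration at the reference diameter
#'   (ml\eqn{^{-1}} \eqn{\mu}m\eqn{^{-1}}); must be \eqn{\ge 0}.
#' @param xi Absolute value of the size-distribution slope (dimensionless).
#' @param dmin,dmax Lower and upper diameter limits (\eqn{\mu}m),
#'   `0 < dmin < dmax`.
#' @param d0 Reference diameter (\eqn{\mu}m), default 1.
#' @return An object of class `"size_spectrum"`.
#' @seealso [calibrated_spectrum()] for the abundance-anchored constructor,
#'   [total_abundance()], [total_volume()], [spacing_report()].
#' @examples
#' spec <- size_spectrum(N0 = 1.8e4, xi = 4.5, dmin = 0.6, dmax = 500)
#' total_abundance(spec)
#' @export
size_spectrum <- function(N0, xi, dmin, dmax, d0 = 1) {
  pd_check_scalar(N0, "N0", nonneg = TRUE)
  pd_check_scalar(xi, "xi")
  pd_check_scalar(d0, "d0", positive = TRUE)
  pd_check_scalar(dmin, "dmin", positive = TRUE)
  pd_check_scalar(dmax, "dmax", positive = TRUE)
  if (dmin > dmax) {
    pd_stop("`dmin` must not exceed `dmax`", "domain_error")
  }
  structure(
    list(N0 = N0, xi = xi, d0 = d0, dmin = dmin, dmax = dmax),
    class = "size_spectrum"
  )
}

#' @export
print.size_spectrum <- function(x, ...) {
  cat(sprintf(
    "<size_spectrum> N0 = %g ml^-1 um^-1 at d0 = %g um, slope xi = %g, d in [%g, %g] um\n",
    x$N0, x$d0, x$xi, x$dmin, x$dmax
  ))
  invisible(x)
}

# Closed-form moment integral of d^k * N(d) over [lo, hi]; handles the
# logarithmic antiderivative when the integrand exponent k - xi hits -1.
spectrum_moment <- function(spec, k, lo = spec$dmin, hi = spec$dmax) {
  p <- k - spec$xi + 1
  scale <- spec$N0 * spec$d0^spec$xi
  if (p == 0) {
    scale * log(hi / lo)
  } else {
    scale * (hi^p - lo^p) / p
  }
}

#' Total cell abundance of a size spectrum
#'
#' Integrates the differential number concentration between the spectrum's
#' size limits, giving the total number of individuals per ml:
#' \deqn{n = \frac{d_0 N_0}{1-\xi}\left[(d_{max}/d_0)^{1-\xi} -
#'   (d_{min}/d_0)^{1-\xi}\right].}
#'
#' @param spec A [size_spectrum()].
#' @return Total abundance (cells ml\eqn{^{-1}}).
#' @export
total_abundance <- function(spec) {
  stopifnot(inherits(spec, "size_spectrum"))
  if (spec$xi == 1) {
    pd_stop("total abundance is singular at slope xi = 1", "slope_singular")
  }
  spectrum_moment(spec, 0)
}

#' Calibrate the spectrum intercept to a target abundance in a size bin
#'
#' Inverts the closed-form bin integral so that the spectrum integrated over
#' `bin` equals `target_count` exactly. The convention used throughout for
#' *Prochlorococcus*-anchored spectra is the bin `[0.6, 0.8)` \eqn{\mu}m.
#'
#' @param target_count Cells ml\eqn{^{-1}} required in the bin; \eqn{\ge 0}.
#' @param bin Length-2 numeric, `(lo, hi)` diameters in \eqn{\mu}m, `lo < hi`.
#' @param xi Absolute slope of the spectrum.
#' @param d0 Reference diameter (\eqn{\mu}m).
#' @return The intercept `N0` (ml\eqn{^{-1}} \eqn{\mu}m\eqn{^{-1}}).
#' @examples
#' calibrate_N0(2e4, c(0.6, 0.8), xi = 4.5) # 1.846e4
#' @export
calibrate_N0 <- function(target_count, bin, xi, d0 = 1) {
  pd_check_scalar(target_count, "target_count", nonneg = TRUE)
  pd_check_scalar(xi, "xi")
  if (length(bin) != 2L || !all(is.finite(bin)) || any(bin <= 0) || bin[1] >= bin[2]) {
    pd_stop("`bin` must be positive diameters (lo, hi) with lo < hi", "domain_error")
  }
  unit <- size_spectrum(1, xi, bin[1], bin[2], d0 = d0)
  target_count / spectrum_moment(unit, 0)
}

#' Abundance-anchored size spectrum
#'
#' Convenience constructor: builds a spectrum whose integral over the
#' anchor `bin` equals `anchor_count`. Defaults reproduce the oligotrophic
#' (`xi = 4.5`, 2e4 cells ml^-1) parameterization over 0.6--500 um.
#'
#' @param xi Absolute slope.
#' @param anchor_count Cells ml\eqn{^{-1}} in the anchor bin.
#' @param bin Anchor bin (\eqn{\mu}m), default `c(0.6, 0.8)`.
#' @param dmin,dmax Spectrum limits (\eqn{\mu}m).
#' @param d0 Reference diameter (\eqn{\mu}m).
#' @return A [size_spectrum()].
#' @export
calibrated_spectrum <- function(xi, anchor_count = 2e4, bin = c(0.6, 0.8),
                                dmin = 0.6, dmax = 500, d0 = 1) {
  size_spectrum(calibrate_N0(anchor_count, bin, xi, d0 = d0), xi, dmin, dmax, d0 = d0)
}

#' Total cell volume per unit water volume
#'
#' \deqn{V = \frac{1}{4-\xi}\frac{\pi}{6} N_0 d_0^4
#'   \left[(d_{max}/d_0)^{4-\xi} - (d_{min}/d_0)^{4-\xi}\right]}
#' in \eqn{\mu}m\eqn{^3} ml\eqn{^{-1}}. Dividing by \eqn{10^{12}}
#' \eqn{\mu}m\eqn{^3} ml\eqn{^{-1}} gives the dimensionless occupied volume
#' fraction, which is below \eqn{10^{-4}} for all realistic parameterizations
#' (the diluteness at the heart of the discreteness argument).
#'
#' @inheritParams total_abundance
#' @return Total cell volume (\eqn{\mu}m\eqn{^3} ml\eqn{^{-1}}).
#' @export
total_volume <- function(spec) {
  stopifnot(inherits(spec, "size_spectrum"))
  if (spec$xi == 4) {
    pd_stop("total volume is singular at slope xi = 4", "slope_singular")
  }
  (pi / 6) * spectrum_moment(spec, 3)
}

#' Mean cell diameters of a size spectrum
#'
#' Two distinct population means:
#' * `mean_vol_diameter` -- the diameter of the mean cell volume,
#'   \eqn{(6 V_{tot} / (\pi n_{tot}))^{1/3}} ("average cell size");
#' * `mean_num_diameter` -- the abundance-weighted mean diameter,
#'   \eqn{\int d N(d) dd / \int N(d) dd} (the body-length yardstick).
#'
#' @inheritParams total_abundance
#' @return Named list with `mean_vol_diameter` and `mean_num_diameter`
#'   (\eqn{\mu}m).
#' @export
mean_diameters <- function(spec) {
  n <- total_abundance(spec)
  if (n <= 0) {
    pd_stop("mean diameters are undefined for an empty spectrum", "domain_error")
  }
  v <- total_volume(spec)
  list(
    mean_vol_diameter = (6 * v / (pi * n))^(1 / 3),
    mean_num_diameter = spectrum_moment(spec, 1) / n
  )
}

#' Carbon-volume allometry for phytoplankton cells
#'
#' Log-log carbon content model `log10 C = a + b log10 Vol` with `C` in pg
#' cell\eqn{^{-1}} and `Vol` in \eqn{\mu}m\eqn{^3}. Defaults follow the
#' Menden-Deuer & Lessard regressions: non-diatoms `(a, b) = (-0.665, 0.939)`;
#' diatoms `(-0.541, 0.811)` (vacuolation makes diatoms carbon-sparse per
#' volume).
#'
#' @param group `"non_diatom"` or `"diatom"`.
#' @param log_intercept,log_exponent Optional overrides for `a` and `b`.
#' @return An object of class `"carbon_volume_model"`.
#' @export
carbon_volume_model <- function(group = c("non_diatom", "diatom"),
                                log_intercept = NULL, log_exponent = NULL) {
  group <- match.arg(group)
  defaults <- switch(group,
    non_diatom = c(a = -0.665, b = 0.939),
    diatom     = c(a = -0.541, b = 0.811)
  )
  a <- if (is.null(log_intercept)) defaults[["a"]] else log_intercept
  b <- if (is.null(log_exponent)) defaults[["b"]] else log_exponent
  pd_check_scalar(b, "log_exponent", positive = TRUE)
  structure(list(group = group, log_intercept = a, log_exponent = b),
            class = "carbon_volume_model")
}

#' Carbon biomass of a size spectrum
#'
#' Integrates per-cell carbon \eqn{c(d) = 10^a ((\pi/6) d^3)^b} pg against the
#' number spectrum, in closed form (the exponent `3b - xi` integrates to a
#' logarithm when `3b + 1 = xi`).
#'
#' @inheritParams total_abundance
#' @param cv A [carbon_volume_model()].
#' @return Carbon biomass (ng C ml\eqn{^{-1}}).
#' @export
carbon_biomass <- function(spec, cv = carbon_volume_model("non_diatom")) {
  stopifnot(inherits(spec, "size_spectrum"), inherits(cv, "carbon_volume_model"))
  a <- cv$log_intercept
  b <- cv$log_exponent
  pg_per_ml <- 10^a * (pi / 6)^b * spectrum_moment(spec, 3 * b)
  pg_per_ml / 1000
}

#' Qualitative chlorophyll from carbon biomass
#'
#' Chl:C rises with biomass (self-shading drives pigment up); modelled as a
#' ratio interpolated linearly in log10 carbon between (6 ng ml^-1, 0.006)
#' and (3700 ng ml^-1, 0.02), clamped outside. Qualitative only.
#'
#' @param c_phyto Carbon biomass (ng C ml\eqn{^{-1}}).
#' @return Chlorophyll (ng Chl ml\eqn{^{-1}}).
#' @export
chlorophyll_from_carbon <- function(c_phyto) {
  if (any(c_phyto < 0)) pd_stop("carbon biomass must be >= 0", "domain_error")
  lo <- log10(6)
  hi <- log10(3700)
  w <- pmin(1, pmax(0, (log10(pmax(c_phyto, .Machine$double.xmin)) - lo) / (hi - lo)))
  c_phyto * (0.006 + w * (0.02 - 0.006))
}

#' Spacing and boundary-layer discreteness diagnostics
#'
#' Summarizes how distantly spaced the cells of a spectrum are. Mean
#' nearest-neighbour spacing uses the cube-root rule for a uniform random
#' suspension, \eqn{\lambda = n^{-1/3}} (with n per \eqn{\mu}m\eqn{^3});
#' the boundary-layer ("sphere of influence") diameter is `d_soi_factor`
#' times the abundance-weighted mean cell diameter; their ratio
#' `dv_lambda` \eqn{= d_{soi}/\lambda} exceeds 1 only when boundary layers
#' routinely overlap and direct resource competition can occur.
#'
#' @inheritParams total_abundance
#' @param d_soi_factor Boundary-layer diameter as a multiple of cell
#'   diameter (default 5).
#' @param cv Carbon model used for the biomass entry.
#' @return A `"discreteness_report"` list: `n_total` (cells ml\eqn{^{-1}}),
#'   `lambda_spacing` (\eqn{\mu}m), `mean_vol_diameter`, `mean_num_diameter`
#'   (\eqn{\mu}m), `body_lengths`, `vol_fraction`, `c_phyto` (ng ml\eqn{^{-1}}),
#'   `d_soi` (\eqn{\mu}m), `dv_lambda`, `tau_bio` (s).
#' @export
spacing_report <- function(spec, d_soi_factor = 5,
                           cv = carbon_volume_model("non_diatom")) {
  pd_check_scalar(d_soi_factor, "d_soi_factor", positive = TRUE)
  n <- total_abundance(spec)
  if (n <= 0) {
    pd_stop("spacing is undefined for zero total abundance", "domain_error")
  }
  md <- mean_diameters(spec)
  lambda <- (1e12 / n)^(1 / 3)
  d_soi <- d_soi_factor * md$mean_num_diameter
  structure(
    list(
      n_total = n,
      lambda_spacing = lambda,
      mean_vol_diameter = md$mean_vol_diameter,
      mean_num_diameter = md$mean_num_diameter,
      body_lengths = lambda / md$mean_num_diameter,
      vol_fraction = total_volume(spec) / 1e12,
      c_phyto = carbon_biomass(spec, cv),
      d_soi = d_soi,
      dv_lambda = d_soi / lambda,
      tau_bio = 86400
    ),
    class = "discreteness_report"
  )
}

#' @export
print.discreteness_report <- function(x, ...) {
  cat("<discreteness_report>\n")
  cat(sprintf("  n_total        %12.4g cells ml^-1\n", x$n_total))
  cat(sprintf("  lambda         %12.4g um (%.3g body lengths)\n",
              x$lambda_spacing, x$body_lengths))
  cat(sprintf("  mean diameter  %12.4g um (volume), %.4g um (number)\n",
              x$mean_vol_diameter, x$mean_num_diameter))
  cat(sprintf("  vol fraction   %12.4g (%.2g%%)\n",
              x$vol_fraction, 100 * x$vol_fraction))
  cat(sprintf("  carbon         %12.4g ng ml^-1\n", x$c_phyto))
  cat(sprintf("  DV_lambda      %12.4g (d_soi = %.4g um)\n", x$dv_lambda, x$d_soi))
  invisible(x)
}

#' @export
as.data.frame.discreteness_report <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Threshold abundance for direct resource competition
#'
#' The abundance at which mean spacing equals the boundary-layer diameter
#' (`dv_lambda = 1`) for a monodisperse population of diameter `d`:
#' \eqn{10^{12} / (f d)^3} cells ml\eqn{^{-1}}. Cubic in size: doubling `d`
#' divides the threshold by 8.
#'
#' @param d Cell diameter (\eqn{\mu}m), > 0 (vectorized).
#' @param d_soi_factor Boundary-layer multiple of `d` (default 5).
#' @return Threshold abundance (cells ml\eqn{^{-1}}).
#' @export
competition_threshold <- function(d, d_soi_factor = 5) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    pd_stop("`d` must be positive and finite", "domain_error")
  }
  pd_check_scalar(d_soi_factor, "d_soi_factor", positive = TRUE)
  1e12 / (d_soi_factor * d)^3
}
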