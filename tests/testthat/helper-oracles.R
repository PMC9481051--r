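# Independent oracles used across the suite. These deliberately avoid the
# closed forms in R/: brute-force quadrature for spectrum moments, and the
# quadratic closed-form root for the division-rate balance.

# Trapezoidal integral of fn(d) * N(d) on a dense log grid.
oracle_spectrum_integral <- function(spec, fn = function(d) 1, n = 1e5) {
  d <- exp(seq(log(spec$dmin), log(spec$dmax), length.out = n))
  y <- fn(d) * spec$N0 * (d / spec$d0)^(-spec$xi)
  sum(diff(d) * (y[-1] + y[-n]) / 2)
}

# Positive root of 0.0762 C' mu^2 + 0.0389 C' mu - assim = 0 with
# C' = 1000 * c_pg fg C (divided by 14 * np for phosphorus currency).
oracle_mu_root <- function(c_pg, assim, element = "N", np_ratio = 16) {
  cp <- 1000 * c_pg
  if (element == "P") cp <- cp / (14 * np_ratio)
  a <- 0.0762 * cp
  b <- 0.0389 * cp
  (-b + sqrt(b^2 + 4 * a * assim)) / (2 * a)
}

# Deterministic stream of random spectra within the calibrated regime.
oracle_random_spectra <- function(n, seed = 42) {
  set.seed(seed)
  replicate(n, simplify = FALSE, {
    xi <- runif(1, 2.5, 5.5)
    while (abs(xi - 4) < 0.05 || abs(xi - 1) < 0.05) xi <- runif(1, 2.5, 5.5)
    lim <- sort(exp(runif(2, log(0.4), log(600))))
    while (lim[2] / lim[1] < 2) lim <- sort(exp(runif(2, log(0.4), log(600))))
    size_spectrum(N0 = 10^runif(1, 2, 6), xi = xi,
                  dmin = lim[1], dmax = lim[2])
  })
}

# Single-class grid with arbitrary diameter/feeding factor, for hand-value
# checks of the NPZ right-hand sides.
toy_grid <- function(d = 2, f = d) {
  structure(
    list(d = d, f = f, pop_class = seq_along(d), pop_group = rep("non_diatom", length(d)),
         n_classes = length(d), n_pops = length(d), multispecies = FALSE),
    class = "size_class_grid"
  )
}
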