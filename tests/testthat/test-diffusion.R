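# Transport pieces (hand-arithmetic anchors), the division-rate solver
# against its quadratic closed-form oracle, and chemostat predictions.

test_that("carbon allometry matches hand arithmetic and is monotone", {
  expect_equal(carbon_content(12, "non_diatom"), 129.2, tolerance = 1e-3)
  expect_equal(carbon_content(127, "diatom"), 2.24e4, tolerance = 1e-2)
  d <- c(0.6, 2, 12, 90)
  expect_true(all(carbon_content(2 * d) > carbon_content(d)))
  expect_error(carbon_content(0), class = "domain_error")
})

test_that("mu_max envelope peaks near 7 um and handles the branch point", {
  expect_equal(mu_max_envelope(0.6), 0.758, tolerance = 1e-3)
  expect_equal(mu_max_envelope(15), 1.521, tolerance = 1e-3)   # power branch
  peak <- stats::optimize(mu_max_envelope, c(0.1, 14.9), maximum = TRUE)$maximum
  expect_equal(peak, 0.789 / (2 * 0.0555), tolerance = 1e-4)
  expect_warning(v <- mu_max_envelope(14.999), "clamped")
  expect_identical(v, 0)
})

test_that("N:C is linear in division rate", {
  expect_identical(nc_of_mu(0), 0.0389)
  expect_equal(nc_of_mu(1), 0.1151)
  a <- 0.37; b <- 1.9
  expect_equal(nc_of_mu(a) + nc_of_mu(b), nc_of_mu(a + b) + 0.0389)
})

test_that("velocity allometries and dialects", {
  expect_equal(swimming_velocity(0.6), 7.43, tolerance = 1e-3)
  expect_equal(swimming_velocity(12), 16.2, tolerance = 1e-2)
  d <- c(0.6, 5, 70)
  expect_equal(swimming_velocity(d, "as_printed"), 1e4 * swimming_velocity(d))
  expect_identical(sinking_velocity(5), 0)
  expect_equal(sinking_velocity(8), 1.23, tolerance = 1e-2)
  expect_equal(sinking_velocity(127), 20.6, tolerance = 1e-2)
})

test_that("Peclet and Sherwood numbers", {
  expect_identical(peclet(12, 0, 1500), 0)
  expect_equal(peclet(127, 20.6, 1500), 1.74, tolerance = 1e-2)
  expect_equal(2 * peclet(3, 5), peclet(6, 5))
  expect_identical(sherwood(0), 1)
  expect_identical(sherwood(13), 2) # (1 + 2*13)^(1/3) = 3 exactly, (1+3)/2 = 2
  expect_equal(sherwood(1.74), 1.325, tolerance = 1e-3)
  pe <- seq(0, 40, length.out = 30)
  expect_true(all(diff(sherwood(pe)) > 0) && all(sherwood(pe) >= 1))
  expect_error(sherwood(-0.1), class = "domain_error")
  expect_error(peclet(1, 1, 0), class = "domain_error")
})

test_that("diffusive flux is linear and the volume-specific form is 1/d^2", {
  ctx <- transport_context(s_inf_nm = 1)
  expect_equal(diffusive_flux(127, ctx), 1.45e3, tolerance = 1e-2)
  expect_equal(diffusive_flux(254, ctx), 2 * diffusive_flux(127, ctx))
  expect_identical(diffusive_flux(5, transport_context(0)), 0)

  # a nutrient-limited 1 um cell outpaces a 100 um cell 10,000-fold
  expect_equal(volume_specific_flux(1, ctx) / volume_specific_flux(100, ctx),
               1e4, tolerance = 1e-9)
  d <- c(0.7, 4, 33)
  expect_equal(volume_specific_flux(d, ctx),
               3 * ctx$D * 1.4e-8 * 86400 / (d / 2)^2, tolerance = 1e-12)
  expect_equal(volume_specific_flux(d / 2, ctx), 4 * volume_specific_flux(d, ctx))
})

test_that("available flux applies capture efficiency and Sherwood", {
  ctx <- transport_context(s_inf_nm = 1)
  # diatoms below 8 um do not sink: Sh = 1, A_F = 0.9 F_D
  expect_equal(available_flux(5, "diatom", ctx), 0.9 * diffusive_flux(5, ctx),
               tolerance = 1e-12)
  expect_equal(available_flux(127, "diatom", ctx), 1.73e3, tolerance = 1e-2)
  ctx1 <- transport_context(s_inf_nm = 1, capture_eff = 1)
  expect_equal(available_flux(5, "diatom", ctx1), diffusive_flux(5, ctx1),
               tolerance = 1e-12)
  d <- c(0.6, 8, 127)
  for (g in c("non_diatom", "diatom")) {
    expect_true(all(available_flux(d, g, ctx) >= 0.9 * diffusive_flux(d, ctx) - 1e-12))
  }
})

test_that("solve_mu reproduces the worked division rates", {
  ctx <- transport_context(s_inf_nm = 1)
  sol_small <- solve_mu(0.6, "non_diatom", ctx)
  expect_equal(sol_small$mu, 0.632, tolerance = 1e-3)
  expect_lte(sol_small$iterations, 25)
  expect_true(sol_small$converged)

  sol_big <- solve_mu(127, "diatom", ctx)
  expect_equal(sol_big$mu, 2.0e-3, tolerance = 2e-2)
  # bookkeeping invariants
  expect_lte(sol_big$assim, min(sol_big$a_f, sol_big$v_max))
  expect_gte(sol_big$sh, 1)
  expect_equal(sol_big$mu * sol_big$q, sol_big$assim, tolerance = 1e-5)
})

test_that("solve_mu saturates to mu_max and vanishes without nutrient", {
  sat <- transport_context(s_inf_nm = 1e6)
  for (d in c(0.6, 7, 40, 127)) {
    sol <- solve_mu(d, "non_diatom", sat)
    expect_equal(sol$mu, sol$mu_max, tolerance = 0.02)
    expect_lt(sol$mu, sol$mu_max) # emergent bound, no clamping
  }
  expect_identical(solve_mu(12, "non_diatom", transport_context(0))$mu, 0)
})

test_that("iterative solver equals the quadratic closed form (200 draws)", {
  set.seed(99)
  for (i in 1:200) {
    d <- exp(runif(1, log(0.6), log(130)))
    group <- sample(c("non_diatom", "diatom"), 1)
    ctx <- transport_context(s_inf_nm = 10^runif(1, 0, 4.3))
    sol <- solve_mu(d, group, ctx)
    expect_equal(sol$mu, oracle_mu_root(sol$c_pg, sol$assim),
                 tolerance = 1e-6)
    expect_lte(sol$mu, sol$mu_max)
    expect_lte(sol$iterations, 25)
  }
})

test_that("division-rate spectra stay between the 1/d^2 floor and mu_max", {
  d <- exp(seq(log(0.6), log(130), length.out = 40))
  for (s in c(3, 17, 3000)) {
    ctx <- transport_context(s_inf_nm = s)
    mu <- vapply(d, function(di) solve_mu(di, "non_diatom", ctx)$mu, numeric(1))
    mm <- mu_max_envelope(d)
    expect_true(all(mu <= mm))
    # shallower than pure diffusion: mu falls off more slowly than 1/d^2
    expect_true(all(mu / mu[1] >= (d[1] / d)^2 - 1e-12))
  }
})

test_that("chemostat predictions are monotone and match the quadratic oracle", {
  pred <- chemostat_prediction(12, 1.19, c(0.7, 2, 5.6))
  expect_equal(pred$mu[3], 0.64, tolerance = 1e-2)
  expect_true(all(diff(pred$mu) > 0))
  expect_identical(chemostat_prediction(12, 1.19, 0)$mu, 0)

  ctx <- transport_context(s_inf_nm = 5.6, element = "P")
  sol <- solve_mu(12, "non_diatom", ctx, mu_max = 1.19)
  expect_equal(sol$mu, oracle_mu_root(sol$c_pg, sol$assim, element = "P"),
               tolerance = 1e-6)
})
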