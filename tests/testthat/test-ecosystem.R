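# NPZ grid construction, derivatives against hand arithmetic, analytic
# fixed points, Euler integration, and community diagnostics.

test_that("size-class grid follows the 1.25-fold geometry", {
  g <- size_class_grid()
  expect_identical(g$n_classes, 25L)
  expect_equal(g$d[1], 0.6)
  expect_equal(g$d[25], 0.6 * 1.25^24, tolerance = 1e-12)
  expect_equal(signif(g$d[25], 4), 127.1)
  expect_true(all(diff(g$d) > 0))
  expect_identical(g$f, g$d) # feeding range: (d + d/2) - (d - d/2) per um

  gm <- size_class_grid(multispecies = TRUE)
  expect_identical(gm$n_pops, 50L)
  expect_identical(unique(table(gm$pop_class)), 2L)
  expect_setequal(unique(gm$pop_group), c("non_diatom", "diatom"))
})

test_that("derivatives match hand arithmetic", {
  g <- toy_grid(d = 2)
  params <- ecosystem_params()
  dv <- ecosystem_derivatives(0.1, 0.01, 0.5, g, params)
  # dP = 0.5*0.1 - 3.24*2*0.01*0.1; dZ = 3.24*0.5*2*0.01*0.1 - 0.06*0.01 - 1.6*2*0.01^2
  expect_equal(dv$dp, 0.04352, tolerance = 1e-12)
  expect_equal(dv$dz, 0.00232, tolerance = 1e-12)
  expect_identical(ecosystem_derivatives(0, 0, 0.5, g, params),
                   list(dp = 0, dz = 0))
  expect_error(ecosystem_derivatives(c(0.1, 0.2), 0.01, 0.5, g, params),
               class = "dimension_error")
})

test_that("analytic fixed point zeroes the derivatives", {
  g <- toy_grid(d = 2)
  st <- analytic_fixed_point(0.5, g)
  expect_equal(st$z_star, 0.07716, tolerance = 1e-4)
  expect_equal(st$p_star, 0.09473, tolerance = 1e-4)
  expect_error(analytic_fixed_point(0, g), class = "degenerate_equilibrium")

  # oracle self-consistency on the full grid with random positive rates
  gg <- size_class_grid()
  set.seed(4)
  for (i in 1:10) {
    mu <- 10^runif(25, -3, 0.3)
    fp <- analytic_fixed_point(mu, gg)
    dv <- ecosystem_derivatives(fp$p_star, fp$z_star, mu, gg, ecosystem_params())
    expect_lt(max(abs(dv$dp), abs(dv$dz)), 1e-12)
    expect_true(all(fp$p_star > 0)) # no resource-based exclusion
  }
})

test_that("Euler integration holds equilibria and converges to them", {
  g <- toy_grid(d = 2)
  fp <- analytic_fixed_point(0.5, g)
  params10 <- ecosystem_params(t_max = 10)
  held <- integrate_ecosystem(0.5, g, params10,
                              p0 = fp$p_star, z0 = fp$z_star)
  expect_equal(held$p_star, fp$p_star, tolerance = 1e-8)
  expect_equal(held$z_star, fp$z_star, tolerance = 1e-8)

  st <- integrate_ecosystem(0.5, g)
  expect_true(all(st$converged))
  expect_equal(st$p_star, fp$p_star, tolerance = 1e-3)
  expect_equal(st$z_star, fp$z_star, tolerance = 1e-3)

  # Euler refinement: halving dt moves the converged state by < 0.01%
  st2 <- integrate_ecosystem(0.5, g, ecosystem_params(dt = 1 / 192))
  expect_equal(st2$p_star, st$p_star, tolerance = 1e-4)

  expect_error(
    integrate_ecosystem(0.5, g, p0 = -0.1),
    class = "domain_error"
  )
})

test_that("diversity counting uses the >= threshold convention", {
  # a population at exactly the threshold fraction counts as extant
  expect_identical(diversity_count(c(1 - 1e-6, 1e-6)), 2L)
  expect_identical(diversity_count(c(1, 1e-7, 1e-8)), 1L)
  expect_identical(diversity_count(0.5), 1L)
  expect_error(diversity_count(c(0, 0)), class = "domain_error")
})

test_that("cell abundance conversion is linear in P and inverse in quota", {
  expect_equal(cell_abundance(0.3818, 2.45), 0.3818 * 1.4e13 / 2.45 / 1e6)
  expect_identical(cell_abundance(0, 2.45), 0)
  expect_equal(cell_abundance(1, 2 * 2.45), cell_abundance(1, 2.45) / 2)
  expect_error(cell_abundance(1, 0), class = "domain_error")
})

test_that("size-distribution slope recovers exact power laws", {
  g <- size_class_grid()
  width <- g$d * (sqrt(1.25) - 1 / sqrt(1.25))
  for (xi in c(4.5, 3.0)) {
    n <- 1e5 * g$d^(-xi) * width # per-unit-length concentration ~ d^-xi
    expect_equal(size_distribution_slope(n, g), -xi, tolerance = 1e-6)
  }
  expect_error(size_distribution_slope(c(1, rep(0, 24)), g),
               class = "degenerate_fit")
})

test_that("multispecies classes collapse to the faster group (trophic exclusion)", {
  gm <- size_class_grid(multispecies = TRUE)
  rates <- class_division_rates(gm, 8)
  st <- analytic_fixed_point(rates$mu, gm)
  for (i in seq_len(gm$n_classes)) {
    idx <- which(gm$pop_class == i)
    frac <- st$p_star[idx] / sum(st$p_star[idx])
    expect_gte(max(frac), 0.99)
    expect_identical(which.max(frac), which.max(rates$mu[idx]))
  }
  dv <- ecosystem_derivatives(st$p_star, st$z_star, rates$mu, gm,
                              ecosystem_params())
  expect_lt(max(abs(dv$dp), abs(dv$dz)), 1e-12)
  # a class survives through its winning population
  expect_identical(diversity_count(st), 25L)
})

test_that("per-generation mortality only rescales the fixed point", {
  g <- size_class_grid()
  mu <- mu_max_envelope(g$d) * 0.3
  vg <- variant_options(per_generation_m = 0.03)
  fp <- analytic_fixed_point(mu, g, ecosystem_params(), vg)
  dv <- ecosystem_derivatives(fp$p_star, fp$z_star, mu, g, ecosystem_params(), vg)
  expect_lt(max(abs(dv$dp), abs(dv$dz)), 1e-12)
  expect_error(
    analytic_fixed_point(mu, g, ecosystem_params(), variant_options(m_loss = 0.03)),
    class = "domain_error"
  )
})

test_that("run_nutrient_grid assembles diagnostics per concentration", {
  res <- run_nutrient_grid(s_inf_nm = c(1, 35, 1000))
  expect_identical(nrow(res), 3L)
  expect_named(res, c("s_inf_nm", "diversity", "sds", "total_p", "total_z"))
  expect_true(all(res$diversity == 25))
  expect_true(all(res$sds < 0))
  states <- attr(res, "states")
  expect_length(states, 3)
  expect_s3_class(states[[1]], "steady_state")
  expect_error(
    run_nutrient_grid(s_inf_nm = 1, variants = variant_options(m_loss = 0.03)),
    class = "domain_error"
  )
})

test_that("default nutrient grid follows the printed stepping rule", {
  s <- nutrient_grid()
  expect_identical(s[1:6], c(1, 8, 15, 22, 29, 35))
  expect_true(all(diff(s[7:(length(s) - 1)]) == 200))
  expect_identical(range(s), c(1, 20000))
})
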