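# Geography, covariate, latent-field and observation generators.

test_that("a single tract covers the whole study square", {
  tr <- generate_tracts(1, extent = 1000, seed = 0)
  poly <- tr$geometry[[1]]
  expect_equal(nrow(poly), 4)
  expect_setequal(poly[, 1], c(0, 1000))
  expect_setequal(poly[, 2], c(0, 1000))
  expect_equal(hurdlemap:::polygon_area(poly), 1000^2)
})

test_that("tract generation is deterministic and non-degenerate", {
  a <- generate_tracts(50, extent = 10000, seed = 7)
  b <- generate_tracts(50, extent = 10000, seed = 7)
  expect_identical(a, b)
  d <- dist(cbind(a$x, a$y))
  expect_true(all(d > 0))
  expect_true(all(a$population >= 500 & a$population <= 3000))
  # Voronoi cells tile the square
  areas <- vapply(a$geometry, hurdlemap:::polygon_area, numeric(1))
  expect_equal(sum(areas), 10000^2, tolerance = 1e-6)
  expect_error(generate_tracts(0, 100, 1), class = "hurdlemap_invalid_argument")
  expect_error(generate_tracts(5, -1, 1), class = "hurdlemap_invalid_argument")
})

test_that("covariate marginals hit their calibration targets", {
  tr <- bare_tracts(10000, seed = 2)
  cv <- generate_covariates(tr, seed = 1)
  expect_equal(mean(cv$unemployment), 24.46, tolerance = 1 / 24.46)
  pct_cols <- setdiff(names(cv), c("tract_id", "x", "y", "population"))
  for (col in pct_cols) {
    expect_true(all(cv[[col]] >= 0 & cv[[col]] <= 100), label = col)
  }
  expect_true(all(
    cv$foreign_africa + cv$foreign_southamerican + cv$foreign_asian <=
      cv$foreign + 1e-9
  ))
  # the six indicators share a latent factor, so they are correlated
  ind <- cor(as.matrix(cv[deprivation_indicators()]))
  expect_true(all(ind[upper.tri(ind)] > 0.2))
  expect_error(generate_covariates(tr[0, ], seed = 1),
    class = "hurdlemap_invalid_argument"
  )
})

test_that("latent fields honour degenerate variances and constraints", {
  tr <- bare_tracts(40, seed = 3)
  mp <- matern_params(sigma2 = 0.3, nu = 1, rho = 3000)
  eff <- simulate_latent_fields(tr, 7, mp, var_eta = 0, var_tau = 0, seed = 5)
  expect_identical(eff$eta, rep(0, 40))
  expect_identical(eff$tau, rep(0, 7))
  eff2 <- simulate_latent_fields(tr, 7, mp, var_eta = 0.1, var_tau = 0.1, seed = 5)
  expect_lt(abs(mean(eff2$tau)), 1e-10)
  expect_identical(
    eff2$S,
    simulate_latent_fields(tr, 7, mp, 0.1, 0.1, seed = 5)$S
  )
})

test_that("spatial field realisations have the configured marginal variance", {
  # widely separated points: empirical variance across tracts estimates
  # the marginal variance of the field
  set.seed(11)
  n <- 2000
  tr <- tibble::tibble(
    tract_id = sprintf("T%04d", 1:n),
    x = runif(n, 0, 5e6), y = runif(n, 0, 5e6)
  )
  mp <- matern_params(sigma2 = 1, nu = 1, rho = 1000)
  eff <- simulate_latent_fields(tr, 1, mp, 0, 0, seed = 9)
  expect_equal(var(eff$S), 1, tolerance = 0.1)
})

test_that("the reporting gate produces the promised count distributions", {
  # gate closed everywhere: every count is zero
  tr <- bare_tracts(20, seed = 4)
  tr <- generate_covariates(tr, seed = 4)
  tr$deprivation <- compute_deprivation_index(tr)
  sc_closed <- synthetic_scenario(
    n_tracts = 20, seed = 4,
    true_betas_binomial = c("(Intercept)" = -700),
    true_betas_poisson = c("(Intercept)" = 1),
    missing_frac = 0
  )
  eff0 <- latent_effects(eta = rep(0, 20), tau = rep(0, 7), S = rep(0, 20))
  panel <- simulate_observations(tr, eff0, sc_closed)
  expect_true(all(panel$observations$count == 0))
  expect_true(all(panel$observations$gate == 0))

  # gate open, unit Poisson rate: sample mean near 1 over 1e5 tract-periods
  n <- 1000
  tp <- 100
  big <- generate_covariates(bare_tracts(n, seed = 6), seed = 6)
  big$deprivation <- compute_deprivation_index(big)
  sc_open <- synthetic_scenario(
    n_tracts = n, n_periods = tp, seed = 8,
    true_betas_binomial = c("(Intercept)" = 700),
    true_betas_poisson = c("(Intercept)" = 0),
    missing_frac = 0
  )
  eff_big <- latent_effects(eta = rep(0, n), tau = rep(0, tp), S = rep(0, n))
  panel_big <- simulate_observations(big, eff_big, sc_open)
  expect_equal(nrow(panel_big$observations), n * tp)
  expect_equal(mean(panel_big$observations$count), 1, tolerance = 0.02)
})

test_that("simulation is a pure function of scenario and seed", {
  sc <- synthetic_scenario(n_tracts = 15, seed = 99)
  a <- simulate_hurdle_data(sc)
  b <- simulate_hurdle_data(sc)
  expect_identical(a$panel$observations, b$panel$observations)
  expect_identical(a$effects, b$effects)
})

test_that("selection gating induces excess zeros over a matched Poisson", {
  sc <- synthetic_scenario(
    n_tracts = 200, seed = 31,
    true_betas_binomial = c("(Intercept)" = 0.4),
    true_betas_poisson = c("(Intercept)" = 1.5),
    matern = matern_params(sigma2 = 1e-8, nu = 1, rho = 3000),
    var_eta = 0, var_tau = 0, missing_frac = 0
  )
  y <- simulate_hurdle_data(sc)$panel$observations$count
  dispersion <- var(y) / mean(y)
  expect_gt(dispersion, 1.5)
  expect_gt(mean(y == 0), exp(-mean(y))) # more zeros than Poisson implies
})

test_that("panel layout options and missingness behave as configured", {
  sc <- synthetic_scenario(n_tracts = 30, seed = 12, missing_frac = 0.3)
  sim <- simulate_hurdle_data(sc)
  expect_lt(nrow(sim$panel$observations), 30 * 7)
  sc2 <- synthetic_scenario(n_tracts = 30, seed = 12, zeros = "absent")
  sim2 <- simulate_hurdle_data(sc2)
  expect_true(all(sim2$panel$observations$count > 0))
  expect_warning(
    synthetic_scenario(n_tracts = 6, seed = 1),
    "Fewer than 10 tracts"
  )
  expect_error(
    synthetic_scenario(n_tracts = 3, seed = 1),
    class = "hurdlemap_invalid_argument"
  )
})
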