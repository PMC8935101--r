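# MCMC fit, posterior summaries, and convergence diagnostics.

test_that("fits are deterministic given seed and configuration", {
  qc <- quick_fit()
  again <- suppressWarnings(fit_hurdle(
    qc$sim$panel,
    control = sampler_config(chains = 2, iter = 150, warmup = 150),
    seed = 17, response = "indicator"
  ))
  expect_identical(qc$fit$chains, again$chains)
  different <- suppressWarnings(fit_hurdle(
    qc$sim$panel,
    control = sampler_config(chains = 2, iter = 150, warmup = 150),
    seed = 18, response = "indicator"
  ))
  expect_false(identical(qc$fit$chains, different$chains))
})

test_that("posterior summaries expose odds ratios with unity flags", {
  # degenerate posteriors with known summaries
  f0 <- fake_fit(rep(0, 500))
  t0 <- tidy(f0)
  expect_equal(t0$estimate, rep(1, 4))
  expect_equal(t0$conf.low, rep(1, 4))
  expect_equal(t0$conf.high, rep(1, 4))
  expect_true(all(t0$contains_one))
  f2 <- fake_fit(rep(log(2), 500))
  expect_equal(tidy(f2, level = 0.9)$estimate, rep(2, 4))
  # standard-normal coefficient draws: OR interval near exp(+-1.96)
  set.seed(1)
  fn <- fake_fit(rnorm(1e5))
  tn <- tidy(fn)
  expect_equal(tn$conf.low[1], exp(-1.96), tolerance = 0.02)
  expect_equal(tn$conf.high[1], exp(1.96), tolerance = 0.02)
  expect_error(tidy(f0, level = 1.2), class = "hurdlemap_invalid_argument")
})

test_that("split-Rhat and ESS behave at their reference points", {
  set.seed(2)
  # IID chains: Rhat near 1
  chains <- lapply(1:2, function(k) {
    matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "a"))
  })
  d <- hurdlemap:::compute_diagnostics(chains, "a")
  expect_gt(d$rhat, 0.99)
  expect_lt(d$rhat, 1.02)
  expect_gt(d$ess, 1000)
  # disjoint chains: flagged divergence
  chains2 <- list(
    matrix(rnorm(500, 0), ncol = 1, dimnames = list(NULL, "a")),
    matrix(rnorm(500, 100), ncol = 1, dimnames = list(NULL, "a"))
  )
  d2 <- hurdlemap:::compute_diagnostics(chains2, "a")
  expect_gt(d2$rhat, 10)
  expect_true(d2$flagged)
  # constant chains: Rhat 1 by convention, ESS flagged as degenerate
  chains3 <- lapply(1:2, function(k) {
    matrix(5, nrow = 400, ncol = 1, dimnames = list(NULL, "a"))
  })
  d3 <- hurdlemap:::compute_diagnostics(chains3, "a")
  expect_equal(d3$rhat, 1)
  expect_true(is.na(d3$ess))
  expect_true(d3$flagged)
})

test_that("diagnostics demand enough chains and draws", {
  qc <- quick_fit()
  single <- qc$fit
  single$control$chains <- 1L
  expect_error(diagnostics(single), class = "hurdlemap_diagnostics_unavailable")
  short <- qc$fit
  short$control$iter <- 50L
  expect_error(diagnostics(short), class = "hurdlemap_diagnostics_unavailable")
  d <- diagnostics(qc$fit)
  expect_true(all(is.finite(d$rhat) | is.na(d$rhat)))
  expect_named(d, c("param", "rhat", "ess", "flagged"))
})

test_that("with no data the coefficient posterior reproduces its prior", {
  tracts <- toy_panel()$tracts
  empty <- hurdle_panel(
    tibble::tibble(
      tract_id = character(0), period = integer(0), count = numeric(0)
    ),
    tracts, toy_panel()$design
  )
  fit <- suppressWarnings(fit_hurdle(
    empty,
    priors = prior_config(beta_sd = 5),
    control = sampler_config(chains = 2, iter = 1500, warmup = 500),
    seed = 4,
    fixed = list(var_eta = 0, var_tau = 0, sigma2 = 0, kappa = 1e-3)
  ))
  for (par in c("bin_(Intercept)", "pois_depr")) {
    dr <- posterior_draws(fit, paste0("^", gsub("\\(", "\\\\(", par), "$"))[, 1]
    ks <- suppressWarnings(ks.test(dr, pnorm, sd = 5))
    expect_lt(unname(ks$statistic), 0.1)
  }
})

test_that("posterior means match IRLS in the small-variance limit", {
  sc <- synthetic_scenario(
    n_tracts = 60, seed = 77, var_eta = 0, var_tau = 0,
    matern = matern_params(sigma2 = 1e-12, nu = 1, rho = 3000)
  )
  sim <- simulate_hurdle_data(sc)
  fit <- suppressWarnings(fit_hurdle(
    sim$panel,
    control = sampler_config(chains = 2, iter = 500, warmup = 400),
    seed = 9,
    fixed = list(var_eta = 0, var_tau = 0, sigma2 = 0, kappa = 1e-3),
    response = "count"
  ))
  obs <- sim$panel$observations
  X <- as.matrix(sim$panel$design[setdiff(names(sim$panel$design), "tract_id")])
  i <- match(obs$tract_id, sim$panel$tracts$tract_id)
  pop <- sim$panel$tracts$population[i]
  g1 <- glm(cbind(obs$count, pop - obs$count) ~ X[i, ], family = binomial())
  g2 <- glm(obs$count ~ X[i, ], family = poisson())
  m <- posterior_draws(fit)
  bin_cols <- grep("^bin_", colnames(m))
  pois_cols <- grep("^pois_", colnames(m))
  z1 <- (colMeans(m[, bin_cols]) - coef(g1)) / apply(m[, bin_cols], 2, sd)
  z2 <- (colMeans(m[, pois_cols]) - coef(g2)) / apply(m[, pois_cols], 2, sd)
  expect_lt(max(abs(z1)), 3)
  expect_lt(max(abs(z2)), 3)
})

test_that("glance reports dimensions and worst diagnostics", {
  qc <- quick_fit()
  g <- glance(qc$fit)
  expect_equal(g$n_tracts, 25L)
  expect_equal(g$chains, 2L)
  expect_equal(g$draws, 300L)
  expect_true(is.finite(g$max_rhat))
})
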