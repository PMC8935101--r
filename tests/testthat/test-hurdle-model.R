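# Linear predictors and the two-part likelihood.

test_that("linear predictor is the exact sum the link functions state", {
  lat <- latent_effects(eta = c(0.1, 0), tau = c(0, 0), S = c(-0.1, 0))
  row <- c(v1 = 2)
  beta0 <- c("(Intercept)" = 0, v1 = 0)
  zero_lat <- latent_effects(eta = c(0, 0), tau = c(0, 0), S = c(0, 0))
  expect_equal(linear_predictor(row, beta0, zero_lat, 1, 1), 0)
  beta <- c("(Intercept)" = 1, v1 = 0.5)
  expect_equal(linear_predictor(row, beta, lat, 1, 1), 2.0)
  expect_error(linear_predictor(row, beta, lat, 3, 1),
    class = "hurdlemap_invalid_argument"
  )
  # moving a constant between the intercept and eta leaves predictors fixed
  cc <- 0.37
  beta_shift <- c("(Intercept)" = 1 + cc, v1 = 0.5)
  lat_shift <- latent_effects(
    eta = lat$eta - cc, tau = lat$tau, S = lat$S
  )
  for (i in 1:2) {
    expect_equal(
      linear_predictor(row, beta_shift, lat_shift, i, 1),
      linear_predictor(row, beta, lat, i, 1)
    )
  }
})

test_that("binomial log-likelihood is exact and stable", {
  expect_equal(binomial_loglik(1, 2, 0), log(0.5), tolerance = 1e-12)
  expect_equal(binomial_loglik(0, 10, -50), 0, tolerance = 1e-12)
  # brute-force pmf oracle
  p <- plogis(0.4)
  expect_equal(
    binomial_loglik(3, 7, 0.4),
    log(choose(7, 3) * p^3 * (1 - p)^4),
    tolerance = 1e-10
  )
  expect_equal(binomial_loglik(2, 9, 1.3), dbinom(2, 9, plogis(1.3), log = TRUE))
  # extreme predictors stay finite
  expect_true(is.finite(binomial_loglik(5, 10, 700)))
  expect_true(is.finite(binomial_loglik(5, 10, -700)))
  expect_error(binomial_loglik(3, 2, 0), class = "hurdlemap_invalid_argument")
})

test_that("poisson log-likelihood is exact, normalised, and validated", {
  expect_equal(poisson_loglik(0, 0), -1)
  expect_equal(poisson_loglik(2, log(2)), log(2) - 2, tolerance = 1e-12)
  expect_equal(poisson_loglik(4, 1.1), dpois(4, exp(1.1), log = TRUE))
  total <- sum(exp(poisson_loglik(0:100, log(3))))
  expect_equal(total, 1, tolerance = 1e-8)
  expect_error(poisson_loglik(-1, 0), class = "hurdlemap_invalid_argument")
  expect_error(poisson_loglik(1.5, 0), class = "hurdlemap_invalid_argument")
  expect_true(all(is.finite(poisson_loglik(1e5, c(-30, 30)))))
})

test_that("joint log-likelihood equals the term-by-term brute-force sum", {
  panel <- toy_panel()
  params <- toy_params()
  lat <- toy_latents()
  got <- joint_loglik(panel, params, lat)

  # independent recomputation, observation by observation
  obs <- panel$observations
  design <- panel$design
  expected <- 0
  for (k in seq_len(nrow(obs))) {
    i <- match(obs$tract_id[k], panel$tracts$tract_id)
    t <- obs$period[k]
    x <- design[i, c("depr", "pct")]
    lp1 <- params$beta_binomial[["(Intercept)"]] +
      params$beta_binomial[["depr"]] * x$depr +
      params$beta_binomial[["pct"]] * x$pct +
      lat$eta[i] + lat$S[i] + lat$tau[t]
    lp2 <- params$beta_poisson[["(Intercept)"]] +
      params$beta_poisson[["depr"]] * x$depr +
      params$beta_poisson[["pct"]] * x$pct +
      params$alpha_share * (lat$eta[i] + lat$S[i] + lat$tau[t])
    ntr <- panel$tracts$population[i]
    expected <- expected +
      dbinom(obs$count[k], ntr, plogis(lp1), log = TRUE) +
      dpois(obs$count[k], exp(lp2), log = TRUE)
  }
  # latent prior terms via independent densities
  xy <- as.matrix(panel$tracts[c("x", "y")])
  sig <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    matern_covariance(sqrt(sum((xy[i, ] - xy[j, ])^2)), params$matern)
  }))
  diag(sig) <- params$matern$sigma2 * (1 + 1e-8)
  expected <- expected + dmvnorm_log_oracle(lat$S, sig)
  expected <- expected + sum(dnorm(lat$eta, 0, sqrt(params$var_eta), log = TRUE))
  expected <- expected + dnorm(diff(lat$tau), 0, sqrt(params$var_tau), log = TRUE)
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("empty panel leaves only the latent prior density", {
  tracts <- toy_panel()$tracts
  empty <- hurdle_panel(
    tibble::tibble(
      tract_id = character(0), period = integer(0), count = numeric(0)
    ),
    tracts, toy_panel()$design
  )
  params <- toy_params(var_eta = 0, var_tau = 0)
  lat <- latent_effects(eta = rep(0, 3), tau = numeric(0), S = rep(0, 3))
  got <- joint_loglik(empty, params, lat)
  xy <- as.matrix(tracts[c("x", "y")])
  sig <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j) {
    matern_covariance(sqrt(sum((xy[i, ] - xy[j, ])^2)), params$matern)
  }))
  diag(sig) <- params$matern$sigma2 * (1 + 1e-8)
  expect_equal(got, dmvnorm_log_oracle(rep(0, 3), sig), tolerance = 1e-10)
})

test_that("joint log-likelihood respects count monotonicity and permutation", {
  panel <- toy_panel()
  params <- toy_params()
  lat <- toy_latents()
  # doubling counts lowers the Poisson contribution when every rate < 1
  small <- model_parameters(
    beta_binomial = params$beta_binomial,
    beta_poisson = c("(Intercept)" = -1.5, depr = 0, pct = 0),
    matern = params$matern, var_eta = params$var_eta,
    var_tau = params$var_tau
  )
  doubled <- panel
  doubled$observations$count <- doubled$observations$count * 2
  expect_lt(
    joint_loglik(doubled, small, lat),
    joint_loglik(panel, small, lat)
  )
  # permuting the tract order consistently leaves the value unchanged
  perm <- c(3L, 1L, 2L)
  panel_p <- hurdle_panel(
    panel$observations, panel$tracts[perm, ], panel$design[perm, ]
  )
  lat_p <- latent_effects(
    eta = lat$eta[perm], tau = lat$tau, S = lat$S[perm]
  )
  expect_equal(
    joint_loglik(panel_p, toy_params(), lat_p),
    joint_loglik(panel, toy_params(), lat),
    tolerance = 1e-10
  )
})

test_that("panel validation enforces the structural invariants", {
  tracts <- toy_panel()$tracts
  expect_error(
    hurdle_panel(
      tibble::tibble(tract_id = "Z", period = 1L, count = 1),
      tracts
    ),
    class = "hurdlemap_schema_error"
  )
  expect_error(
    hurdle_panel(
      tibble::tibble(tract_id = "A", period = 1L, count = 5000),
      tracts, toy_panel()$design
    ),
    class = "hurdlemap_invalid_argument"
  )
  expect_error(
    hurdle_panel(
      tibble::tibble(tract_id = "A", period = 0L, count = 1),
      tracts, toy_panel()$design
    ),
    class = "hurdlemap_invalid_argument"
  )
})
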