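# Shared fixtures, all built in code.

# A minimal tract frame without geometry (enough for covariate generation
# and likelihood work); unit-square-ish centroids scaled to `extent`.
bare_tracts <- function(n, extent = 10000, seed = 1, population = 1000) {
  set.seed(seed)
  tibble::tibble(
    tract_id = sprintf("T%04d", seq_len(n)),
    x = runif(n, 0, extent),
    y = runif(n, 0, extent),
    population = rep_len(population, n)
  )
}

# A tiny fully-explicit 3-tract x 2-period panel with hand-picked numbers,
# used for brute-force likelihood oracles.
toy_panel <- function() {
  tracts <- tibble::tibble(
    tract_id = c("A", "B", "C"),
    x = c(0, 1000, 500),
    y = c(0, 0, 800),
    population = c(1200, 800, 2000)
  )
  design <- tibble::tibble(
    tract_id = c("A", "B", "C"),
    depr = c(1, 0, 0),
    pct = c(12.5, 30.0, 21.0)
  )
  obs <- tibble::tibble(
    tract_id = rep(c("A", "B", "C"), each = 2),
    period = rep(1:2, 3),
    count = c(3, 0, 1, 2, 0, 5)
  )
  hurdle_panel(obs, tracts, design)
}

toy_params <- function(var_eta = 0.4, var_tau = 0.25, alpha_share = 1) {
  model_parameters(
    beta_binomial = c("(Intercept)" = -5.5, depr = -0.6, pct = 0.01),
    beta_poisson = c("(Intercept)" = 0.3, depr = 0.2, pct = -0.02),
    matern = matern_params(sigma2 = 0.5, nu = 1, rho = 900),
    var_eta = var_eta, var_tau = var_tau, alpha_share = alpha_share
  )
}

toy_latents <- function() {
  latent_effects(
    eta = c(0.2, -0.1, 0.05),
    tau = c(0.15, -0.15),
    S = c(-0.3, 0.1, 0.25)
  )
}

# Independent multivariate-normal log-density via determinant() and
# solve(), deliberately avoiding the package's Cholesky path.
dmvnorm_log_oracle <- function(x, sigma) {
  n <- length(x)
  -0.5 * (n * log(2 * pi) +
    as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
    as.numeric(t(x) %*% solve(sigma) %*% x))
}

# A fabricated minimal posterior object for summary-level unit tests:
# one coefficient per part, no latents.
fake_fit <- function(bin_draws, pois_draws = bin_draws) {
  stopifnot(length(bin_draws) == length(pois_draws))
  m <- cbind(
    "bin_(Intercept)" = bin_draws, "bin_depr" = bin_draws,
    "pois_(Intercept)" = pois_draws, "pois_depr" = pois_draws
  )
  structure(
    list(
      chains = list(m),
      par_names = colnames(m),
      design_columns = "depr",
      panel = NULL,
      control = list(chains = 1, iter = length(bin_draws)),
      estimate_alpha = FALSE,
      diagnostics = tibble::tibble(
        param = colnames(m), rhat = 1, ess = length(bin_draws), flagged = FALSE
      )
    ),
    class = "hurdle_fit"
  )
}

# Small simulated dataset + short fit, reused by several test files.
quick_fit_cache <- new.env(parent = emptyenv())
quick_fit <- function() {
  if (is.null(quick_fit_cache$fit)) {
    sc <- synthetic_scenario(n_tracts = 25, seed = 404)
    quick_fit_cache$sim <- simulate_hurdle_data(sc)
    quick_fit_cache$fit <- suppressWarnings(fit_hurdle(
      quick_fit_cache$sim$panel,
      control = sampler_config(chains = 2, iter = 150, warmup = 150),
      seed = 17, response = "indicator"
    ))
  }
  quick_fit_cache
}
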