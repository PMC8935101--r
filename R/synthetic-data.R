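#' Synthetic study scenario
#'
#' Describes one synthetic study: a tessellated square study area, a
#' seven-period annual panel by default, true fixed effects for the
#' reporting (binomial) and count (Poisson) parts, and latent-field
#' hyperparameters.  Defaults mirror a mid-sized city observed over seven
#' annual periods: 100 tracts on a 10 km square, a spatial field with a
#' 3 km practical range and variance 0.3, modest unstructured and temporal
#' variances, and a reporting part in which high deprivation lowers the
#' odds of a report being filed (odds ratio 0.573).
#'
#' @param n_tracts Number of tracts, >= 4 (a warning is issued below 10,
#'   where quintile coding is hardly meaningful).
#' @param n_periods Number of annual periods (default 7).
#' @param extent Side of the square study area, metres.
#' @param true_betas_binomial,true_betas_poisson Named coefficient vectors;
#'   `"(Intercept)"` plus any subset of [design_columns()].
#' @param matern [matern_params()] of the latent spatial field.
#' @param var_eta,var_tau Variances (>= 0) of the tract-level IID effect
#'   and of the RW1 temporal innovations.
#' @param missing_frac Fraction of tract-periods removed completely at
#'   random to make the panel unbalanced.
#' @param zeros `"explicit"` keeps zero-count rows; `"absent"` drops them
#'   (both layouts occur in administrative extracts).
#' @param seed Integer master seed; every generator derives its stream
#'   from it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_tracts = 100,
                               n_periods = 7,
                               extent = 10000,
                               true_betas_binomial = c(
                                 "(Intercept)" = 2.2,
                                 deprivation_q45 = log(0.573)
                               ),
                               true_betas_poisson = c("(Intercept)" = 2),
                               matern = matern_params(
                                 sigma2 = 0.3, nu = 1, rho = 3000
                               ),
                               var_eta = 0.05,
                               var_tau = 0.05,
                               missing_frac = 0.05,
                               zeros = c("explicit", "absent"),
                               seed = 1) {
  n_tracts <- check_count(n_tracts, "n_tracts", min = 4L)
  if (n_tracts < 10) {
    warn("Fewer than 10 tracts: quintile categories will be very coarse.")
  }
  n_periods <- check_count(n_periods, "n_periods", min = 1L)
  check_positive(extent, "extent")
  stopifnot(inherits(matern, "matern_params"))
  check_nonneg(var_eta, "var_eta")
  check_nonneg(var_tau, "var_tau")
  check_nonneg(missing_frac, "missing_frac")
  if (missing_frac >= 1) stop_invalid("`missing_frac` must be < 1.")
  zeros <- match.arg(zeros)
  for (nm in list(true_betas_binomial, true_betas_poisson)) {
    bad <- setdiff(names(nm), c("(Intercept)", design_columns()))
    if (length(bad) > 0) {
      stop_invalid(paste0(
        "Unknown coefficient name(s): ", paste(bad, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      n_tracts = n_tracts, n_periods = n_periods, extent = extent,
      true_betas_binomial = true_betas_binomial,
      true_betas_poisson = true_betas_poisson,
      matern = matern, var_eta = var_eta, var_tau = var_tau,
      missing_frac = missing_frac, zeros = zeros, seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

#' Generate a synthetic tract geography
#'
#' Places tract centroids uniformly on a square study area, forms their
#' Voronoi polygons clipped to the square, and assigns populations at risk
#' drawn log-uniformly between 500 and 3000 (the size range of Spanish
#' census tracts).
#'
#' @param n_tracts Number of tracts, >= 1 (>= 4 for downstream modelling).
#' @param extent Side of the square, metres, > 0.
#' @param seed Integer seed; output is deterministic given `(inputs, seed)`.
#' @return A tibble with columns `tract_id`, `x`, `y` (centroid metres),
#'   `population`, and a `geometry` list-column of polygon vertex matrices.
#' @examples
#' tr <- generate_tracts(20, extent = 5000, seed = 3)
#' tr
#' @export
generate_tracts <- function(n_tracts, extent, seed) {
  n_tracts <- check_count(n_tracts, "n_tracts", min = 1L)
  check_positive(extent, "extent")
  with_seed(seed, {
    xy <- cbind(runif(n_tracts, 0, extent), runif(n_tracts, 0, extent))
    pop <- round(exp(runif(n_tracts, log(500), log(3000))))
    cells <- voronoi_cells(xy, extent)
    tibble::tibble(
      tract_id = sprintf("T%04d", seq_len(n_tracts)),
      x = xy[, 1],
      y = xy[, 2],
      population = as.numeric(pop),
      geometry = cells
    )
  })
}

# Calibration targets for the covariate generator: marginal means and SDs
# of tract-level percentages in a deprived mid-sized Catalan city.
covariate_targets <- function() {
  tibble::tribble(
    ~name,                ~mean,  ~sd,   ~loading,
    "unemployment",        24.46,  9.47,  0.7,
    "manual_workers",      52.24, 17.42,  0.7,
    "temporary_workers",   24.84,  8.27,  0.7,
    "schooling",           30.13, 10.00,  0.7,
    "schooling_young",     13.81,  5.00,  0.7,
    "without_internet",    33.38,  9.73,  0.7,
    "housing45",            4.25,  5.82,  0.0,
    "housing4560",         10.68,  5.12,  0.0,
    "foreign",             21.51, 15.46,  0.0
  )
}

#' Generate tract-level socioeconomic covariates
#'
#' Adds the twelve raw covariates used by the model: the six deprivation
#' indicators (driven by one shared latent deprivation factor plus
#' indicator-specific noise, so a composite index is meaningful), two
#' small-housing percentages, and the overall and origin-specific foreign
#' percentages (origin shares drawn from a Dirichlet so the three subgroups
#' never exceed the total).  Marginal means and SDs are calibrated to a
#' deprived mid-sized city; all percentages are clipped to `[0, 100]`.
#'
#' @param tracts Tract frame from [generate_tracts()] (non-empty).
#' @param seed Integer seed.
#' @return The input tibble with twelve covariate columns appended.
#' @export
generate_covariates <- function(tracts, seed) {
  if (!is.data.frame(tracts) || nrow(tracts) == 0) {
    stop_invalid("`tracts` must be a non-empty tract frame.")
  }
  n <- nrow(tracts)
  tg <- covariate_targets()
  with_seed(seed, {
    f <- rnorm(n) # shared latent deprivation factor
    for (k in seq_len(nrow(tg))) {
      lam <- tg$loading[k]
      z <- lam * f + sqrt(1 - lam^2) * rnorm(n)
      tracts[[tg$name[k]]] <- pmin(100, pmax(0, tg$mean[k] + tg$sd[k] * z))
    }
    # Split the foreign percentage into origin shares; mean shares follow
    # the city-level composition (Africa 6.73, South America 12.98,
    # Asia 1.54 out of 21.51), the rest being other origins.
    alpha <- c(6.73, 12.98, 1.54, 0.26) / 21.51 * 4
    g <- matrix(rgamma(n * 4, shape = rep(alpha, each = n)), n, 4)
    shares <- g / rowSums(g)
    tracts$foreign_africa <- tracts$foreign * shares[, 1]
    tracts$foreign_southamerican <- tracts$foreign * shares[, 2]
    tracts$foreign_asian <- tracts$foreign * shares[, 3]
    tracts
  })
}

#' Latent effects container
#'
#' Holds one realisation (or one posterior draw) of the three random
#' effects: tract-level IID heterogeneity `eta`, the sum-to-zero RW1
#' temporal effect `tau`, and the Matern spatial field `S`.
#'
#' @param eta Numeric vector, one value per tract.
#' @param tau Numeric vector, one value per period, summing to zero.
#' @param S Numeric vector, one value per tract.
#' @return An object of class `latent_effects`.
#' @export
latent_effects <- function(eta, tau, S) {
  if (length(eta) != length(S)) {
    stop_invalid("`eta` and `S` must have one value per tract each.")
  }
  if (length(tau) > 0 && abs(sum(tau)) > 1e-10 * max(1, max(abs(tau)))) {
    stop_invalid("`tau` must sum to zero (sum-to-zero constraint).")
  }
  structure(list(eta = eta, tau = tau, S = S), class = "latent_effects")
}

#' Simulate the three latent fields
#'
#' Draws the spatial field `S` once from a zero-mean Gaussian field with
#' Matern covariance over the tract centroids, `eta` IID normal per tract,
#' and `tau` as a first-order random walk with the given innovation
#' variance, centred to sum to zero.  Zero variances yield exactly-zero
#' effects.
#'
#' @param tracts Tract frame with centroid columns `x`, `y`.
#' @param n_periods Number of periods.
#' @param matern [matern_params()] of the spatial field.
#' @param var_eta,var_tau Variances >= 0.
#' @param seed Integer seed.
#' @return A [latent_effects()] object.
#' @export
simulate_latent_fields <- function(tracts, n_periods, matern,
                                   var_eta, var_tau, seed) {
  stopifnot(inherits(matern, "matern_params"))
  check_nonneg(var_eta, "var_eta")
  check_nonneg(var_tau, "var_tau")
  n_periods <- check_count(n_periods, "n_periods", min = 1L)
  n <- nrow(tracts)
  S <- sample_field(tracts[c("x", "y")], matern, seed = derive_seed(seed, 31L))
  eta <- if (var_eta == 0) {
    rep(0, n)
  } else {
    with_seed(derive_seed(seed, 32L), rnorm(n, 0, sqrt(var_eta)))
  }
  tau <- if (var_tau == 0 || n_periods == 1) {
    rep(0, n_periods)
  } else {
    inc <- with_seed(
      derive_seed(seed, 33L),
      rnorm(n_periods - 1, 0, sqrt(var_tau))
    )
    walk <- cumsum(c(0, inc))
    walk - mean(walk)
  }
  latent_effects(eta = eta, tau = tau, S = S)
}

# Named-coefficient linear predictor over a design tibble (tract_id +
# design columns).  `betas` is a named vector: "(Intercept)" plus design
# column names; unnamed columns contribute zero.
predictor_from_betas <- function(design, betas) {
  lp <- rep(betas[["(Intercept)"]] %||% 0, nrow(design))
  for (nm in setdiff(names(betas), "(Intercept)")) {
    lp <- lp + design[[nm]] * betas[[nm]]
  }
  lp
}

#' Simulate selection-biased report counts
#'
#' Generates the tract-period panel from the gate-then-count hurdle that
#' motivates the two-part model: for each tract-period the reporting gate
#' is Bernoulli with probability `logistic(l1)`, and conditional on the
#' gate being open the count is Poisson with rate `exp(l2)`, where both
#' linear predictors share the intercepts, fixed effects, and the latent
#' fields (`l = b0 + x'b + eta_i + S_i + tau_t`).  Closed gates produce
#' structural zeros, the endogenous-selection mechanism that makes naive
#' count models biased.  A configurable fraction of tract-periods is then
#' removed completely at random to unbalance the panel.
#'
#' @param tracts Covariate-augmented tract frame.
#' @param effects [latent_effects()] for these tracts.
#' @param scenario [synthetic_scenario()] carrying the true coefficients,
#'   missingness fraction and seed.
#' @param design Optional design tibble; built with
#'   [build_design_matrix()] when `NULL`.
#' @return A [hurdle_panel()] whose observation table also carries the
#'   simulation truth (`gate`, `true_p`, `true_rate`) for recovery tests.
#' @export
simulate_observations <- function(tracts, effects, scenario, design = NULL) {
  stopifnot(
    inherits(effects, "latent_effects"),
    inherits(scenario, "synthetic_scenario")
  )
  if (length(effects$eta) != nrow(tracts)) {
    stop_invalid("`effects` and `tracts` disagree on the number of tracts.")
  }
  design <- design %||% build_design_matrix(tracts)
  n <- nrow(tracts)
  tt <- length(effects$tau)
  grid <- tidyr::expand_grid(i = seq_len(n), t = seq_len(tt))
  lat <- effects$eta[grid$i] + effects$S[grid$i] + effects$tau[grid$t]
  l1 <- predictor_from_betas(design, scenario$true_betas_binomial)[grid$i] + lat
  l2 <- predictor_from_betas(design, scenario$true_betas_poisson)[grid$i] + lat
  if (any(l2 > 30)) {
    abort(
      paste0(
        "Poisson linear predictor exceeds 30 (rate overflow); rescale the ",
        "true coefficients or covariates."
      ),
      class = "hurdlemap_numerical_error"
    )
  }
  obs <- with_seed(derive_seed(scenario$seed, 41L), {
    gate <- rbinom(nrow(grid), 1L, plogis(l1))
    y <- ifelse(gate == 1L, rpois(nrow(grid), exp(l2)), 0L)
    keep <- runif(nrow(grid)) >= scenario$missing_frac
    tibble::tibble(
      tract_id = design$tract_id[grid$i],
      period = grid$t,
      count = as.numeric(y),
      gate = gate,
      true_p = plogis(l1),
      true_rate = exp(l2)
    )[keep, ]
  })
  if (scenario$zeros == "absent") {
    obs <- obs[obs$count > 0, ]
  }
  hurdle_panel(obs, tracts, design)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generative chain — geography, covariates, deprivation
#' index, design matrix, latent fields, selection-biased counts — under a
#' single scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `hurdle_sim` with elements `panel` (a
#'   [hurdle_panel()]), `effects` (the true [latent_effects()]) and
#'   `scenario`.
#' @examples
#' sim <- simulate_hurdle_data(synthetic_scenario(n_tracts = 20, seed = 9))
#' sim$panel
#' @export
simulate_hurdle_data <- function(scenario = synthetic_scenario()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  tracts <- generate_tracts(
    scenario$n_tracts, scenario$extent,
    seed = derive_seed(scenario$seed, 11L)
  )
  tracts <- generate_covariates(tracts, seed = derive_seed(scenario$seed, 12L))
  tracts$deprivation <- compute_deprivation_index(tracts)
  design <- build_design_matrix(tracts)
  effects <- simulate_latent_fields(
    tracts, scenario$n_periods, scenario$matern,
    scenario$var_eta, scenario$var_tau,
    seed = derive_seed(scenario$seed, 13L)
  )
  panel <- simulate_observations(tracts, effects, scenario, design)
  structure(
    list(panel = panel, effects = effects, scenario = scenario),
    class = "hurdle_sim"
  )
}
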