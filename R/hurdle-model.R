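#' Tract-period panel dataset
#'
#' Bundles the (possibly unbalanced) tract-period observations with the
#' static tract frame (centroids, population at risk, geometry) and the
#' fixed-effects design matrix.  Validates the structural invariants:
#' counts are non-negative and never exceed the tract population, periods
#' are integers in `1..T`, and every observed tract exists in both the
#' tract frame and the design.
#'
#' @param observations Data frame with columns `tract_id`, `period`,
#'   `count` (extra columns are kept).
#' @param tracts Tract frame with `tract_id`, centroid columns `x`, `y`,
#'   and `population`.
#' @param design Design tibble from [build_design_matrix()]; built from
#'   `tracts` when `NULL`.
#' @return An object of class `hurdle_panel`.
#' @export
hurdle_panel <- function(observations, tracts, design = NULL) {
  for (col in c("tract_id", "period", "count")) {
    if (!col %in% names(observations)) {
      abort(paste0("`observations` lacks column `", col, "`."),
        class = "hurdlemap_schema_error"
      )
    }
  }
  for (col in c("tract_id", "x", "y", "population")) {
    if (!col %in% names(tracts)) {
      abort(paste0("`tracts` lacks column `", col, "`."),
        class = "hurdlemap_schema_error"
      )
    }
  }
  design <- design %||% build_design_matrix(tracts)
  observations <- tibble::as_tibble(observations)
  tracts <- tibble::as_tibble(tracts)

  orphans <- setdiff(observations$tract_id, tracts$tract_id)
  if (length(orphans) > 0) {
    abort(
      paste0(
        "Observation tract id(s) missing from the tract frame: ",
        paste(head(orphans, 5), collapse = ", ")
      ),
      class = "hurdlemap_schema_error"
    )
  }
  if (!setequal(design$tract_id, tracts$tract_id)) {
    abort("`design` and `tracts` must cover the same tract ids.",
      class = "hurdlemap_schema_error"
    )
  }
  p <- observations$period
  if (any(p != as.integer(p)) || (nrow(observations) > 0 && min(p) < 1)) {
    stop_invalid("`period` must contain integers starting at 1.")
  }
  observations$period <- as.integer(observations$period)
  if (any(observations$count < 0)) {
    stop_invalid("Counts must be non-negative.")
  }
  pop <- tracts$population[match(observations$tract_id, tracts$tract_id)]
  if (any(observations$count > pop)) {
    stop_invalid("A count exceeds its tract's population at risk.")
  }
  # align design rows with the tract frame
  design <- design[match(tracts$tract_id, design$tract_id), ]
  structure(
    list(
      observations = observations,
      tracts = tracts,
      design = design,
      n_tracts = nrow(tracts),
      n_periods = if (nrow(observations) > 0) max(observations$period) else 0L
    ),
    class = "hurdle_panel"
  )
}

#' @export
print.hurdle_panel <- function(x, ...) {
  cat(sprintf(
    "Tract-period panel: %d observations, %d tracts, %d periods\n",
    nrow(x$observations), x$n_tracts, x$n_periods
  ))
  print(x$observations, ...)
  invisible(x)
}

#' Model parameters of the two-part model
#'
#' Fixed effects of both parts (each a coefficient per design column, plus
#' an intercept), the Matern hyperparameters of the spatial field, the two
#' remaining latent variances, and the scaling of the shared latents in
#' the Poisson part.
#'
#' @param beta_binomial,beta_poisson Named numeric vectors:
#'   `"(Intercept)"` plus any subset of [design_columns()].
#' @param matern [matern_params()].
#' @param var_eta,var_tau Variances >= 0.
#' @param alpha_share Scaling applied to `eta + S + tau` in the Poisson
#'   part (1 = fully shared latents).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(beta_binomial, beta_poisson, matern,
                             var_eta = 0, var_tau = 0, alpha_share = 1) {
  stopifnot(inherits(matern, "matern_params"))
  check_nonneg(var_eta, "var_eta")
  check_nonneg(var_tau, "var_tau")
  for (b in list(beta_binomial, beta_poisson)) {
    if (!is.numeric(b) || is.null(names(b)) || any(names(b) == "")) {
      stop_invalid("Coefficient vectors must be fully named numerics.")
    }
  }
  structure(
    list(
      beta_binomial = beta_binomial, beta_poisson = beta_poisson,
      matern = matern, var_eta = var_eta, var_tau = var_tau,
      alpha_share = alpha_share
    ),
    class = "model_parameters"
  )
}

#' Linear predictor of either model part
#'
#' Evaluates `b0 + x'b + eta_i + S_i + tau_t` for one design row, exactly
#' as written in the two link functions.
#'
#' @param design_row Named numeric vector (or one-row data frame) of design
#'   covariate values.
#' @param beta Named coefficient vector (`"(Intercept)"` plus design
#'   names); names absent from `beta` contribute zero.
#' @param latents [latent_effects()].
#' @param i Tract index, `t` period index (1-based).
#' @param t Period index.
#' @return A single numeric value.
#' @export
linear_predictor <- function(design_row, beta, latents, i, t) {
  stopifnot(inherits(latents, "latent_effects"))
  if (i < 1 || i > length(latents$eta) || t < 1 || t > length(latents$tau)) {
    stop_invalid("Tract or period index out of range.")
  }
  if (is.data.frame(design_row)) {
    design_row <- unlist(design_row[setdiff(names(design_row), "tract_id")])
  }
  lp <- beta[["(Intercept)"]] %||% 0
  for (nm in setdiff(names(beta), "(Intercept)")) {
    lp <- lp + beta[[nm]] * design_row[[nm]]
  }
  lp + latents$eta[i] + latents$S[i] + latents$tau[t]
}

#' Binomial log-likelihood of the reporting part
#'
#' Log binomial pmf of `count` successes in `n_trials` Bernoulli trials
#' with success probability `logistic(predictor)`, evaluated on the log
#' scale so it stays finite for predictors up to `|700|`.
#'
#' @param count Successes, `0 <= count <= n_trials`.
#' @param n_trials Trials (the population at risk).
#' @param predictor Linear predictor on the logit scale.
#' @return Log-probability (vectorised over its arguments).
#' @examples
#' binomial_loglik(1, 2, 0)  # log(0.5)
#' @export
binomial_loglik <- function(count, n_trials, predictor) {
  if (any(count < 0) || any(count > n_trials)) {
    stop_invalid("`count` must lie in [0, n_trials].")
  }
  # log p = eta - log(1+e^eta); log(1-p) = -log(1+e^eta)
  lse <- log1p_exp(predictor)
  lchoose(n_trials, count) + count * (predictor - lse) - (n_trials - count) * lse
}

#' Poisson log-likelihood of the count part
#'
#' Log Poisson pmf with rate `exp(predictor)`:
#' `count * predictor - exp(predictor) - log(count!)`.
#'
#' @param count Non-negative integer count(s).
#' @param predictor Linear predictor on the log scale.
#' @return Log-probability (vectorised).
#' @examples
#' poisson_loglik(0, 0)  # -1
#' @export
poisson_loglik <- function(count, predictor) {
  if (any(count < 0) || any(count != round(count))) {
    stop_invalid("`count` must be non-negative integers.")
  }
  count * predictor - exp(predictor) - lgamma(count + 1)
}

# Vectorised data log-likelihood over a panel.  Returns the sum of the
# binomial rows and the Poisson rows given per-observation predictors.
panel_data_loglik <- function(panel, lp1, lp2, response = "count") {
  obs <- panel$observations
  if (nrow(obs) == 0) return(0)
  pop <- panel$tracts$population[match(obs$tract_id, panel$tracts$tract_id)]
  bin <- if (response == "indicator") {
    binomial_loglik(as.numeric(obs$count > 0), 1, lp1)
  } else {
    binomial_loglik(obs$count, pop, lp1)
  }
  sum(bin) + sum(poisson_loglik(obs$count, lp2))
}

# Per-observation predictors for both parts from betas + latents.
panel_predictors <- function(panel, params, latents) {
  obs <- panel$observations
  i <- match(obs$tract_id, panel$tracts$tract_id)
  t <- obs$period
  lat <- latents$eta[i] + latents$S[i] + latents$tau[t]
  x1 <- predictor_from_betas(panel$design, params$beta_binomial)[i]
  x2 <- predictor_from_betas(panel$design, params$beta_poisson)[i]
  list(lp1 = x1 + lat, lp2 = x2 + params$alpha_share * lat)
}

# Log prior densities of the latent fields given the hyperparameters:
# MVN(0, Matern) for S, IID N(0, var_eta) for eta, RW1 increments for tau.
# Zero variances require exactly-zero effects (contribution 0).
latent_logprior <- function(panel, params, latents) {
  lp <- 0
  # spatial field
  sigma <- covariance_matrix(panel$tracts[c("x", "y")], params$matern)
  ll <- chol_with_jitter(sigma, 1e-8 * params$matern$sigma2)
  z <- forwardsolve(ll, latents$S)
  n <- length(latents$S)
  lp <- lp - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ll))) + sum(z^2))
  # IID heterogeneity
  if (params$var_eta == 0) {
    if (any(latents$eta != 0)) {
      stop_invalid("var_eta = 0 requires eta identically zero.")
    }
  } else {
    lp <- lp + sum(dnorm(latents$eta, 0, sqrt(params$var_eta), log = TRUE))
  }
  # RW1 temporal effect (density of the increments)
  tt <- length(latents$tau)
  if (tt >= 2) {
    if (params$var_tau == 0) {
      if (any(latents$tau != 0)) {
        stop_invalid("var_tau = 0 requires tau identically zero.")
      }
    } else {
      d <- diff(latents$tau)
      lp <- lp + sum(dnorm(d, 0, sqrt(params$var_tau), log = TRUE))
    }
  }
  lp
}

#' Joint log-likelihood of the two-part model
#'
#' Sum of the binomial reporting-part terms and the Poisson count-part
#' terms over all observations — both parts evaluated on every
#' tract-period, sharing the latent fields (scaled by `alpha_share` in the
#' Poisson part) — plus the log prior densities of the latent fields:
#' multivariate normal with Matern covariance for `S`, IID normal for
#' `eta`, and first-order random-walk increments for `tau`.
#'
#' @param panel [hurdle_panel()].
#' @param params [model_parameters()].
#' @param latents [latent_effects()].
#' @param response `"count"` evaluates the binomial part on the report
#'   count out of the tract population; `"indicator"` on the binary
#'   any-report outcome.
#' @return A single numeric value.
#' @export
joint_loglik <- function(panel, params, latents,
                         response = c("count", "indicator")) {
  stopifnot(
    inherits(panel, "hurdle_panel"),
    inherits(params, "model_parameters"),
    inherits(latents, "latent_effects")
  )
  response <- match.arg(response)
  if (length(latents$eta) != panel$n_tracts) {
    abort("Latent fields and panel disagree on the number of tracts.",
      class = "hurdlemap_schema_error"
    )
  }
  if (nrow(panel$observations) > 0 &&
      max(panel$observations$period) > length(latents$tau)) {
    abort("Panel has periods beyond the length of `tau`.",
      class = "hurdlemap_schema_error"
    )
  }
  lp <- panel_predictors(panel, params, latents)
  panel_data_loglik(panel, lp$lp1, lp$lp2, response) +
    latent_logprior(panel, params, latents)
}
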