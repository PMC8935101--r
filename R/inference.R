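#' Prior configuration
#'
#' Weakly-informative defaults for the Bayesian fit: zero-mean Gaussian
#' priors on all coefficients, half-normal priors on the latent standard
#' deviations, and a log-normal prior on the spatial range centred (by
#' default) at 20% of the study-area diameter.  The Matern smoothness `nu`
#' is fixed, not sampled.
#'
#' @param beta_sd SD of the Gaussian coefficient priors.
#' @param sd_scale Scale of the half-normal priors on `sqrt(var_eta)`,
#'   `sqrt(var_tau)` and `sqrt(sigma2)`.
#' @param rho_median Median of the log-normal prior on the practical range
#'   `rho` (metres); when `NULL`, 20% of the diameter of the tract
#'   centroid bounding box is used at fit time.
#' @param rho_logsd SD of the range prior on the log scale.
#' @param nu Fixed Matern smoothness.
#' @param alpha_mean,alpha_sd Gaussian prior on the latent-sharing scale
#'   `alpha` (only used when `estimate_alpha = TRUE` in [fit_hurdle()]).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(beta_sd = 5, sd_scale = 1, rho_median = NULL,
                         rho_logsd = 0.7, nu = 1,
                         alpha_mean = 1, alpha_sd = 0.5) {
  check_positive(beta_sd, "beta_sd")
  check_positive(sd_scale, "sd_scale")
  if (!is.null(rho_median)) check_positive(rho_median, "rho_median")
  check_positive(rho_logsd, "rho_logsd")
  check_positive(nu, "nu")
  check_positive(alpha_sd, "alpha_sd")
  structure(
    list(
      beta_sd = beta_sd, sd_scale = sd_scale, rho_median = rho_median,
      rho_logsd = rho_logsd, nu = nu,
      alpha_mean = alpha_mean, alpha_sd = alpha_sd
    ),
    class = "prior_config"
  )
}

#' Sampler configuration
#'
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics).
#' @param iter Post-warmup draws kept per chain.
#' @param warmup Adaptation iterations discarded per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 2, iter = 1000, warmup = 1000, thin = 1) {
  chains <- check_count(chains, "chains", min = 1L)
  iter <- check_count(iter, "iter", min = 1L)
  warmup <- check_count(warmup, "warmup", min = 0L)
  thin <- check_count(thin, "thin", min = 1L)
  structure(
    list(chains = chains, iter = iter, warmup = warmup, thin = thin),
    class = "sampler_config"
  )
}

# ---- adaptive random-walk Metropolis block ---------------------------------

am_new <- function(dim, init_scale = 0.1, init_chol = NULL) {
  env <- new.env(parent = emptyenv())
  env$dim <- dim
  env$n <- 0
  env$mean <- numeric(dim)
  env$m2 <- matrix(0, dim, dim)
  env$log_scale <- log(init_scale)
  env$chol_prop <- init_chol %||% diag(dim) / sqrt(dim)
  env
}

am_observe <- function(am, x) {
  am$n <- am$n + 1
  d <- x - am$mean
  am$mean <- am$mean + d / am$n
  am$m2 <- am$m2 + tcrossprod(d, x - am$mean)
}

am_adapt <- function(am, accepted, it) {
  # Robbins-Monro scale tuning towards 0.234 acceptance
  am$log_scale <- am$log_scale +
    (as.numeric(accepted) - 0.234) / sqrt(max(it, 20))
  if (am$n > 2 * am$dim && it %% 25 == 0) {
    cv <- am$m2 / (am$n - 1) + diag(1e-10, am$dim)
    ch <- tryCatch(chol(cv), error = function(e) NULL)
    if (!is.null(ch)) am$chol_prop <- t(ch)
  }
}

am_propose <- function(am, x) {
  x + exp(am$log_scale) * 2.38 *
    as.vector(am$chol_prop %*% rnorm(am$dim))
}

# ---- elliptical slice sampling ---------------------------------------------

# One elliptical-slice update of a standard-normal-prior vector `u` with
# respect to log-likelihood `loglik_fn`.  Returns list(u, ll).
ess_update <- function(u, ll_cur, loglik_fn) {
  nu <- rnorm(length(u))
  logy <- ll_cur + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    up <- u * cos(theta) + nu * sin(theta)
    ll <- loglik_fn(up)
    if (ll > logy) return(list(u = up, ll = ll))
    if (theta < 0) lo <- theta else hi <- theta
    theta <- runif(1, lo, hi)
    if (hi - lo < 1e-12) return(list(u = u, ll = ll_cur))
  }
}

# ---- the fit ---------------------------------------------------------------

#' Fit the spatial-temporal two-part model
#'
#' Bayesian estimation of the joint binomial/Poisson model by MCMC: the
#' non-centred latent block (IID heterogeneity, Matern spatial field, RW1
#' temporal effect — all sum-to-zero centred) is updated by elliptical
#' slice sampling, while each part's coefficient vector and the
#' hyperparameter block use adaptive random-walk Metropolis with proposal
#' covariance learned during warmup.  The posterior targets
#' [joint_loglik()] plus the [prior_config()] log-priors; runs are
#' deterministic given `(data, config, seed)`.
#'
#' @param panel A [hurdle_panel()].
#' @param priors [prior_config()].
#' @param control [sampler_config()].
#' @param seed Integer seed.
#' @param response Binomial-part response: `"count"` models the report
#'   count out of the tract population (the link as written), `"indicator"`
#'   the binary any-report outcome — the reporting gate of the generative
#'   hurdle.
#' @param fixed Named list fixing hyperparameters instead of sampling
#'   them: any of `var_eta`, `var_tau`, `sigma2`, `kappa`, `rho`.  A
#'   variance fixed at 0 removes that latent component exactly.
#' @param estimate_alpha Estimate the latent-sharing scale `alpha` of the
#'   Poisson part (default: fixed at 1).
#' @return An object of class `hurdle_fit` with per-chain draw matrices,
#'   split-Rhat/ESS diagnostics, and the data and configuration used.
#' @examples
#' \donttest{
#' sim <- simulate_hurdle_data(synthetic_scenario(n_tracts = 20, seed = 5))
#' fit <- fit_hurdle(sim$panel,
#'   control = sampler_config(chains = 2, iter = 200, warmup = 200),
#'   seed = 1
#' )
#' tidy(fit)
#' }
#' @export
fit_hurdle <- function(panel,
                       priors = prior_config(),
                       control = sampler_config(),
                       seed = 1,
                       response = c("count", "indicator"),
                       fixed = list(),
                       estimate_alpha = FALSE) {
  stopifnot(
    inherits(panel, "hurdle_panel"),
    inherits(priors, "prior_config"),
    inherits(control, "sampler_config")
  )
  response <- match.arg(response)
  bad_fixed <- setdiff(names(fixed), c("var_eta", "var_tau", "sigma2", "kappa", "rho"))
  if (length(bad_fixed) > 0) {
    stop_invalid(paste0("Unknown `fixed` entries: ", paste(bad_fixed, collapse = ", ")))
  }
  if (!is.null(fixed$rho) && is.null(fixed$kappa)) {
    fixed$kappa <- sqrt(8 * priors$nu) / fixed$rho
  }

  xy <- as.matrix(panel$tracts[c("x", "y")])
  if (is.null(priors$rho_median)) {
    diam <- sqrt(sum((apply(xy, 2, max) - apply(xy, 2, min))^2))
    priors$rho_median <- max(0.2 * diam, 1e-6)
  }

  n <- panel$n_tracts
  tt <- max(panel$n_periods, 1L)
  obs <- panel$observations
  oi <- match(obs$tract_id, panel$tracts$tract_id)
  ot <- obs$period
  y <- obs$count
  pop <- panel$tracts$population[oi]
  ybin <- if (response == "indicator") as.numeric(y > 0) else y
  ntri <- if (response == "indicator") rep(1, length(y)) else pop
  xcols <- setdiff(names(panel$design), "tract_id")
  X <- as.matrix(panel$design[xcols])
  p <- ncol(X)

  # which hyperparameters are sampled
  sd_eta_fix <- if (!is.null(fixed$var_eta)) sqrt(fixed$var_eta) else NULL
  sd_tau_fix <- if (!is.null(fixed$var_tau)) sqrt(fixed$var_tau) else NULL
  sigma_fix <- if (!is.null(fixed$sigma2)) sqrt(fixed$sigma2) else NULL
  kappa_fix <- fixed$kappa
  hyper_names <- c(
    if (is.null(sd_eta_fix)) "log_sd_eta",
    if (is.null(sd_tau_fix) && tt >= 2) "log_sd_tau",
    if (is.null(sigma_fix)) "log_sigma",
    if (is.null(kappa_fix)) "log_kappa",
    if (estimate_alpha) "alpha"
  )

  use_eta <- is.null(sd_eta_fix) || sd_eta_fix > 0
  use_s <- is.null(sigma_fix) || sigma_fix > 0
  use_tau <- tt >= 2 && (is.null(sd_tau_fix) || sd_tau_fix > 0)
  n_u <- use_eta * n + use_s * n + use_tau * (tt - 1)

  # correlation Cholesky cache (depends on kappa only); the pairwise
  # distances are fixed, so they are computed once up front
  dvec <- as.vector(stats::dist(xy))
  n_xy <- nrow(xy)
  corr_cache <- new.env(parent = emptyenv())
  corr_chol <- function(kappa) {
    key <- format(kappa, digits = 17)
    if (!is.null(corr_cache[[key]])) return(corr_cache[[key]])
    pr <- matern_params(sigma2 = 1, nu = priors$nu, kappa = kappa)
    cm <- matrix(0, n_xy, n_xy)
    if (n_xy > 1) cm[lower.tri(cm)] <- matern_covariance(dvec, pr)
    cm <- cm + t(cm)
    diag(cm) <- 1 + 1e-8
    ll <- chol_with_jitter(cm, 1e-8)
    # keep the cache tiny: only the latest few kappa values matter
    if (length(ls(corr_cache)) > 4) rm(list = ls(corr_cache), envir = corr_cache)
    corr_cache[[key]] <- ll
    ll
  }

  center <- function(v) v - mean(v)

  # unpack hyper vector -> natural scale, honouring fixed values
  hyper_natural <- function(th) {
    list(
      sd_eta = if (is.null(sd_eta_fix)) exp(th[["log_sd_eta"]]) else sd_eta_fix,
      sd_tau = if (!is.null(sd_tau_fix)) sd_tau_fix
      else if (tt >= 2) exp(th[["log_sd_tau"]]) else 0,
      sigma = if (is.null(sigma_fix)) exp(th[["log_sigma"]]) else sigma_fix,
      kappa = if (is.null(kappa_fix)) exp(th[["log_kappa"]]) else kappa_fix,
      alpha = if (estimate_alpha) th[["alpha"]] else 1
    )
  }

  # natural-scale latent fields from (hypers, u)
  latents_from <- function(hy, u) {
    pos <- 0L
    eta <- if (use_eta) {
      ue <- u[pos + seq_len(n)]; pos <- pos + n
      hy$sd_eta * ue
    } else rep(0, n)
    s <- if (use_s) {
      z <- u[pos + seq_len(n)]; pos <- pos + n
      hy$sigma * as.vector(corr_chol(hy$kappa) %*% z)
    } else rep(0, n)
    tau <- if (use_tau) {
      ut <- u[pos + seq_len(tt - 1)]
      hy$sd_tau * center(cumsum(c(0, ut)))
    } else rep(0, tt)
    list(eta = eta, s = s, tau = tau)
  }

  # invert the non-centred transform: raw u from natural latents
  u_from_lat <- function(hy, lat, u) {
    pos <- 0L
    if (use_eta) {
      u[pos + seq_len(n)] <- lat$eta / hy$sd_eta
      pos <- pos + n
    }
    if (use_s) {
      u[pos + seq_len(n)] <-
        forwardsolve(corr_chol(hy$kappa), lat$s) / hy$sigma
      pos <- pos + n
    }
    if (use_tau) {
      u[pos + seq_len(tt - 1)] <- diff(lat$tau) / hy$sd_tau
    }
    u
  }

  data_ll <- function(xb1, xb2, lat, alpha) {
    if (length(y) == 0) return(0)
    lo <- lat$eta[oi] + lat$s[oi] + lat$tau[ot]
    lp1 <- xb1[oi] + lo
    lp2 <- xb2[oi] + alpha * lo
    lse <- log1p_exp(lp1)
    sum(ybin * (lp1 - lse) - (ntri - ybin) * lse) +
      sum(y * lp2 - exp(lp2) - lgamma(y + 1))
  }

  prior_lsd <- function(l) {
    # half-normal on the sd, with the log-scale Jacobian
    dnorm(exp(l), 0, priors$sd_scale, log = TRUE) + log(2) + l
  }
  prior_lkappa <- function(lk) {
    dnorm(log(sqrt(8 * priors$nu)) - lk, log(priors$rho_median),
      priors$rho_logsd,
      log = TRUE
    )
  }

  hyper_logprior <- function(th, hy) {
    lp <- 0
    if (is.null(sd_eta_fix)) {
      lp <- lp + dnorm(hy$sd_eta, 0, priors$sd_scale, log = TRUE) +
        log(2) + th[["log_sd_eta"]]
    }
    if (is.null(sd_tau_fix) && tt >= 2) {
      lp <- lp + dnorm(hy$sd_tau, 0, priors$sd_scale, log = TRUE) +
        log(2) + th[["log_sd_tau"]]
    }
    if (is.null(sigma_fix)) {
      lp <- lp + dnorm(hy$sigma, 0, priors$sd_scale, log = TRUE) +
        log(2) + th[["log_sigma"]]
    }
    if (is.null(kappa_fix)) {
      log_rho <- log(sqrt(8 * priors$nu)) - th[["log_kappa"]]
      lp <- lp + dnorm(log_rho, log(priors$rho_median), priors$rho_logsd, log = TRUE)
    }
    if (estimate_alpha) {
      lp <- lp + dnorm(th[["alpha"]], priors$alpha_mean, priors$alpha_sd, log = TRUE)
    }
    lp
  }

  # GLM-based starting values and proposal preconditioners: the IRLS
  # coefficient estimates seed the chains and the asymptotic covariance
  # Cholesky seeds the adaptive proposals (a standard data-driven
  # preconditioner; adaptation refines it during warmup).
  glm_start <- function(yy, fam) {
    fallback <- list(b = numeric(p + 1), ch = diag(p + 1) * 0.02)
    if (length(y) == 0) {
      return(list(b = numeric(p + 1), ch = diag(p + 1) * priors$beta_sd))
    }
    tryCatch(
      {
        fit <- suppressWarnings(glm.fit(
          cbind(1, X[oi, , drop = FALSE]), yy,
          family = fam
        ))
        cf <- coef(fit)
        cf[!is.finite(cf)] <- 0
        # prior-regularised Laplace covariance: bounded even under
        # separation, where the raw IRLS covariance blows up
        r <- qr.R(fit$qr)
        fisher <- crossprod(r)
        prec <- fisher + diag(1 / priors$beta_sd^2, p + 1)
        vp <- chol2inv(chol(prec))
        b <- as.vector(vp %*% (fisher %*% cf))
        ch <- t(chol((vp + t(vp)) / 2 + diag(1e-12, p + 1)))
        list(b = b, ch = ch)
      },
      error = function(e) fallback
    )
  }
  init_betas <- function() {
    list(
      bin = glm_start(cbind(ybin, ntri - ybin), binomial()),
      pois = glm_start(y, poisson())
    )
  }

  n_keep <- control$iter
  total_iter <- control$warmup + control$iter * control$thin
  par_names <- c(
    paste0("bin_", c("(Intercept)", xcols)),
    paste0("pois_", c("(Intercept)", xcols)),
    if (is.null(sd_eta_fix)) "sd_eta",
    if (is.null(sd_tau_fix) && tt >= 2) "sd_tau",
    if (is.null(sigma_fix)) "sigma2",
    if (is.null(kappa_fix)) c("kappa", "rho"),
    if (estimate_alpha) "alpha",
    paste0("eta[", seq_len(n), "]"),
    paste0("S[", seq_len(n), "]"),
    paste0("tau[", seq_len(tt), "]"),
    "lp__"
  )

  run_chain <- function(chain_id) {
    with_seed(derive_seed(seed, 100L + chain_id), {
      ini <- init_betas()
      b1 <- ini$bin$b + as.vector(ini$bin$ch %*% rnorm(p + 1))
      b2 <- ini$pois$b + as.vector(ini$pois$ch %*% rnorm(p + 1))
      th <- setNames(numeric(length(hyper_names)), hyper_names)
      for (nm in hyper_names) {
        th[nm] <- switch(nm,
          log_sd_eta = log(0.3), log_sd_tau = log(0.3), log_sigma = log(0.3),
          log_kappa = log(sqrt(8 * priors$nu) / priors$rho_median),
          alpha = priors$alpha_mean
        )
      }
      th <- th + rnorm(length(th), 0, 0.05)
      u <- rnorm(n_u, 0, 0.1)

      hy <- hyper_natural(th)
      lat <- latents_from(hy, u)
      xb1 <- as.vector(X %*% b1[-1]) + b1[1]
      xb2 <- as.vector(X %*% b2[-1]) + b2[1]
      ll <- data_ll(xb1, xb2, lat, hy$alpha)
      if (!is.finite(ll)) {
        abort(
          paste0(
            "Non-finite data log-likelihood at initialisation (chain ",
            chain_id, "); check for extreme covariate scales or counts."
          ),
          class = "hurdlemap_initialisation_error"
        )
      }

      am1 <- am_new(p + 1, init_chol = ini$bin$ch)
      am2 <- am_new(p + 1, init_chol = ini$pois$ch)
      sh_chol <- ini$bin$ch
      sh_log_scale <- log(0.3)
      amh <- if (length(hyper_names) > 0) am_new(length(hyper_names)) else NULL

      draws <- matrix(NA_real_, n_keep, length(par_names),
        dimnames = list(NULL, par_names)
      )
      keep_row <- 0L

      for (it in seq_len(total_iter)) {
        adapting <- it <= control$warmup

        # 1. latent block: elliptical slice on the standard-normal u
        if (n_u > 0) {
          for (rep in 1:2) {
            up <- ess_update(u, ll, function(uu) {
              data_ll(xb1, xb2, latents_from(hy, uu), hy$alpha)
            })
            u <- up$u
            ll <- up$ll
          }
          lat <- latents_from(hy, u)
        }
        lo_obs <- lat$eta[oi] + lat$s[oi] + lat$tau[ot]

        # 2. binomial-part coefficients (several cheap MH sweeps per
        # latent update: the blocks are correlated across updates)
        bin_ll <- function(b) {
          lp1 <- as.vector(X[oi, , drop = FALSE] %*% b[-1]) + b[1] + lo_obs
          lse <- log1p_exp(lp1)
          sum(ybin * (lp1 - lse) - (ntri - ybin) * lse) +
            sum(dnorm(b, 0, priors$beta_sd, log = TRUE))
        }
        cur1 <- bin_ll(b1)
        for (rep in 1:3) {
          prop <- am_propose(am1, b1)
          new1 <- bin_ll(prop)
          acc <- is.finite(new1) && log(runif(1)) < new1 - cur1
          if (acc) {
            b1 <- prop
            cur1 <- new1
          }
          if (adapting) {
            am_observe(am1, b1)
            am_adapt(am1, acc, it)
          }
        }
        xb1 <- as.vector(X %*% b1[-1]) + b1[1]

        # 3. Poisson-part coefficients
        pois_ll <- function(b) {
          lp2 <- as.vector(X[oi, , drop = FALSE] %*% b[-1]) + b[1] +
            hy$alpha * lo_obs
          sum(y * lp2 - exp(lp2) - lgamma(y + 1)) +
            sum(dnorm(b, 0, priors$beta_sd, log = TRUE))
        }
        cur2 <- pois_ll(b2)
        for (rep in 1:3) {
          prop <- am_propose(am2, b2)
          new2 <- pois_ll(prop)
          acc <- is.finite(new2) && log(runif(1)) < new2 - cur2
          if (acc) {
            b2 <- prop
            cur2 <- new2
          }
          if (adapting) {
            am_observe(am2, b2)
            am_adapt(am2, acc, it)
          }
        }
        xb2 <- as.vector(X %*% b2[-1]) + b2[1]

        # 4. hyperparameters (latent u held fixed; non-centred, so the
        # standard-normal prior on u is unaffected by the move)
        if (length(hyper_names) > 0) {
          cur <- data_ll(xb1, xb2, lat, hy$alpha) + hyper_logprior(th, hy)
          for (rep in 1:2) {
            thp <- setNames(am_propose(amh, th), hyper_names)
            hyp <- hyper_natural(thp)
            latp <- latents_from(hyp, u)
            new <- data_ll(xb1, xb2, latp, hyp$alpha) + hyper_logprior(thp, hyp)
            acc <- is.finite(new) && log(runif(1)) < new - cur
            if (acc) {
              th <- thp
              hy <- hyp
              lat <- latp
              cur <- new
            }
            if (adapting) {
              am_observe(amh, th)
              am_adapt(amh, acc, it)
            }
          }
          lo_obs <- lat$eta[oi] + lat$s[oi] + lat$tau[ot]
        }

        # 5. interweaving (ASIS): re-update the variance hyperparameters
        # in the centred parameterisation — natural latents held fixed, so
        # only the latent prior densities enter — then map u back.  This
        # breaks the strong coupling between the latent fields and their
        # variances that the non-centred moves alone traverse very slowly.
        if (use_eta && is.null(sd_eta_fix)) {
          q <- sum(lat$eta^2)
          lsd <- th[["log_sd_eta"]]
          tgt <- function(l) -n * l - q / (2 * exp(2 * l)) + prior_lsd(l)
          for (rep in 1:3) {
            lp_ <- lsd + rnorm(1, 0, 0.3)
            if (log(runif(1)) < tgt(lp_) - tgt(lsd)) lsd <- lp_
          }
          th[["log_sd_eta"]] <- lsd
          hy$sd_eta <- exp(lsd)
        }
        if (use_tau && is.null(sd_tau_fix)) {
          q <- sum(diff(lat$tau)^2)
          lsd <- th[["log_sd_tau"]]
          tgt <- function(l) -(tt - 1) * l - q / (2 * exp(2 * l)) + prior_lsd(l)
          for (rep in 1:3) {
            lp_ <- lsd + rnorm(1, 0, 0.3)
            if (log(runif(1)) < tgt(lp_) - tgt(lsd)) lsd <- lp_
          }
          th[["log_sd_tau"]] <- lsd
          hy$sd_tau <- exp(lsd)
        }
        if (use_s && is.null(sigma_fix)) {
          # sigma-only centred update at the current kappa (whose own
          # moves live in the adaptive joint block above), so the cached
          # correlation factor is reused
          lc <- corr_chol(hy$kappa)
          q <- sum(forwardsolve(lc, lat$s)^2)
          lsig <- th[["log_sigma"]]
          tgt <- function(l) -n * l - q / (2 * exp(2 * l)) + prior_lsd(l)
          for (rep in 1:3) {
            lp_ <- lsig + rnorm(1, 0, 0.25)
            if (log(runif(1)) < tgt(lp_) - tgt(lsig)) lsig <- lp_
          }
          th[["log_sigma"]] <- lsig
          hy$sigma <- exp(lsig)
        }
        if (use_s && is.null(kappa_fix) && it %% 2 == 0) {
          # occasional centred (kappa, sigma) move; one Bessel-matrix
          # evaluation per proposal keeps this affordable
          s_tgt <- function(lsig, lkap) {
            lc <- corr_chol(exp(lkap))
            z <- forwardsolve(lc, lat$s) / exp(lsig)
            val <- -n * lsig - sum(log(diag(lc))) - 0.5 * sum(z^2) +
              prior_lkappa(lkap)
            if (is.null(sigma_fix)) val <- val + prior_lsd(lsig)
            val
          }
          lsig <- log(hy$sigma)
          lkap <- th[["log_kappa"]]
          lsig_p <- if (is.null(sigma_fix)) lsig + rnorm(1, 0, 0.25) else lsig
          lkap_p <- lkap + rnorm(1, 0, 0.4)
          if (log(runif(1)) < s_tgt(lsig_p, lkap_p) - s_tgt(lsig, lkap)) {
            if (is.null(sigma_fix)) {
              th[["log_sigma"]] <- lsig_p
              hy$sigma <- exp(lsig_p)
            }
            th[["log_kappa"]] <- lkap_p
            hy$kappa <- exp(lkap_p)
          }
        }
        # 5b. exact redraw of the eta/S decomposition given their sum
        # (conjugate normal split; the likelihood sees only eta + S, so
        # this Gibbs step is what actually mixes the two fields)
        if (use_eta && use_s && hy$sd_eta > 0 && hy$sigma > 0) {
          v <- lat$eta + lat$s
          lc <- corr_chol(hy$kappa)
          cinv <- chol2inv(t(lc)) / hy$sigma^2
          qmat <- cinv + diag(1 / hy$sd_eta^2, n)
          rq <- chol(qmat)
          mu <- backsolve(rq, forwardsolve(t(rq), cinv %*% v))
          lat$eta <- as.vector(mu + backsolve(rq, rnorm(n)))
          lat$s <- v - lat$eta
        }
        u <- u_from_lat(hy, lat, u)

        # 6. shift move: a likelihood-invariant exchange between the
        # fixed effects (intercept included) and the IID field along the
        # span of the design (the flat direction of latent confounding);
        # accepted on the prior ratios alone.
        if (use_eta && hy$sd_eta > 0) {
          for (rep in 1:2) {
            dd <- exp(sh_log_scale) *
              as.vector(sh_chol %*% rnorm(p + 1))
            w <- dd[1] + as.vector(X %*% dd[-1])
            eta_p <- lat$eta - w
            b1_p <- b1 + dd
            b2_p <- b2 + hy$alpha * dd
            logr <- sum(dnorm(b1_p, 0, priors$beta_sd, log = TRUE)) -
              sum(dnorm(b1, 0, priors$beta_sd, log = TRUE)) +
              sum(dnorm(b2_p, 0, priors$beta_sd, log = TRUE)) -
              sum(dnorm(b2, 0, priors$beta_sd, log = TRUE)) +
              (sum(lat$eta^2) - sum(eta_p^2)) / (2 * hy$sd_eta^2)
            acc <- is.finite(logr) && log(runif(1)) < logr
            if (acc) {
              b1 <- b1_p
              b2 <- b2_p
              lat$eta <- eta_p
              xb1 <- as.vector(X %*% b1[-1]) + b1[1]
              xb2 <- as.vector(X %*% b2[-1]) + b2[1]
            }
            if (adapting) {
              sh_log_scale <- sh_log_scale +
                (as.numeric(acc) - 0.234) / sqrt(max(it, 20))
            }
          }
          u <- u_from_lat(hy, lat, u)
          lo_obs <- lat$eta[oi] + lat$s[oi] + lat$tau[ot]
        }

        ll <- data_ll(xb1, xb2, lat, hy$alpha)

        if (!adapting && (it - control$warmup) %% control$thin == 0) {
          keep_row <- keep_row + 1L
          row <- c(
            b1, b2,
            if (is.null(sd_eta_fix)) hy$sd_eta,
            if (is.null(sd_tau_fix) && tt >= 2) hy$sd_tau,
            if (is.null(sigma_fix)) hy$sigma^2,
            if (is.null(kappa_fix)) c(hy$kappa, sqrt(8 * priors$nu) / hy$kappa),
            if (estimate_alpha) hy$alpha,
            lat$eta, lat$s, lat$tau,
            ll
          )
          draws[keep_row, ] <- row
        }
      }
      draws
    })
  }

  chains <- lapply(seq_len(control$chains), run_chain)

  diag_tbl <- compute_diagnostics(chains, par_names)
  core <- diag_tbl[!grepl("^(eta|S|tau)\\[|^lp__$", diag_tbl$param), ]
  bad <- core$param[is.finite(core$rhat) & core$rhat > 1.05]
  if (length(bad) > 0) {
    warn(paste0(
      "Convergence warning: split-Rhat > 1.05 for ",
      paste(head(bad, 8), collapse = ", "),
      if (length(bad) > 8) " ..." else "",
      ". Consider more iterations."
    ))
  }

  structure(
    list(
      chains = chains,
      par_names = par_names,
      design_columns = xcols,
      panel = panel,
      priors = priors,
      control = control,
      response = response,
      fixed = fixed,
      estimate_alpha = estimate_alpha,
      seed = as.integer(seed),
      diagnostics = diag_tbl
    ),
    class = "hurdle_fit"
  )
}

# stack kept draws of all chains into one matrix
all_draws <- function(fit) {
  do.call(rbind, fit$chains)
}

#' Extract posterior draws
#'
#' @param fit A [fit_hurdle()] result.
#' @param pars Optional regular expression selecting parameter columns.
#' @return Matrix of stacked post-warmup draws (all chains).
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "hurdle_fit"))
  m <- all_draws(fit)
  if (!is.null(pars)) m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  m
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf(
    "Two-part spatial-temporal model fit: %d chains x %d draws (%s response)\n",
    x$control$chains, x$control$iter, x$response
  ))
  cat(sprintf(
    "  %d observations, %d tracts, %d periods; max split-Rhat (core) %.3f\n",
    nrow(x$panel$observations), x$panel$n_tracts, x$panel$n_periods,
    max_core_rhat(x)
  ))
  invisible(x)
}

max_core_rhat <- function(fit) {
  core <- fit$diagnostics[
    !grepl("^(eta|S|tau)\\[|^lp__$", fit$diagnostics$param),
  ]
  r <- core$rhat[is.finite(core$rhat)]
  if (length(r) == 0) NA_real_ else max(r)
}

# ---- convergence diagnostics -----------------------------------------------

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    m <- nrow(ch)
    h <- floor(m / 2)
    out <- c(out, list(ch[seq_len(h), , drop = FALSE],
                       ch[(m - h + 1):m, , drop = FALSE]))
  }
  out
}

rhat_ess_scalar <- function(seqs) {
  m <- length(seqs)
  nn <- length(seqs[[1]])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  w <- mean(vars)
  b <- if (m > 1) nn * var(means) else 0
  if (w == 0) {
    if (b == 0) return(c(rhat = 1, ess = NA_real_)) # constant chains
    return(c(rhat = Inf, ess = NA_real_))
  }
  varplus <- (nn - 1) / nn * w + b / nn
  rhat <- sqrt(varplus / w)
  # combined autocorrelation (Stan-style), Geyer initial positive sequence
  maxlag <- min(nn - 1, 100)
  acov <- rowMeans(vapply(
    seqs,
    function(s) {
      a <- acf(s, lag.max = maxlag, plot = FALSE, type = "covariance",
               demean = TRUE)$acf[, 1, 1]
      length(a) <- maxlag + 1
      a[is.na(a)] <- 0
      a
    },
    numeric(maxlag + 1)
  ))
  rho <- 1 - (w - acov[-1]) / varplus
  sum_rho <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    sum_rho <- sum_rho + pair
    k <- k + 2
  }
  ess <- m * nn / (1 + 2 * sum_rho)
  ess <- min(ess, m * nn)
  c(rhat = rhat, ess = ess)
}

compute_diagnostics <- function(chains, par_names) {
  halves <- split_chains(chains)
  res <- vapply(
    seq_along(par_names),
    function(j) rhat_ess_scalar(lapply(halves, function(h) h[, j])),
    numeric(2)
  )
  tibble::tibble(
    param = par_names,
    rhat = unname(res[1, ]),
    ess = unname(res[2, ]),
    flagged = (is.finite(res[1, ]) & res[1, ] > 1.05) |
      (!is.na(res[2, ]) & res[2, ] < 100) | is.na(res[2, ])
  )
}

#' Convergence diagnostics table
#'
#' Split-Rhat and effective sample size for every stored scalar; scalars
#' with Rhat above 1.05 or ESS below 100 (or degenerate, constant chains)
#' are flagged.
#'
#' @param fit A [fit_hurdle()] result (>= 2 chains, >= 100 draws each).
#' @return A tibble with columns `param`, `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  if (fit$control$chains < 2) {
    abort("Diagnostics need at least 2 chains.",
      class = "hurdlemap_diagnostics_unavailable"
    )
  }
  if (fit$control$iter < 100) {
    abort("Diagnostics need at least 100 kept draws per chain.",
      class = "hurdlemap_diagnostics_unavailable"
    )
  }
  fit$diagnostics
}

# ---- posterior summaries ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

summarize_beta_draws <- function(draws, level) {
  a <- (1 - level) / 2
  or <- exp(draws)
  qs <- quantile(or, c(a, 1 - a), names = FALSE)
  tibble::tibble(
    estimate = mean(or),
    conf.low = qs[1],
    conf.high = qs[2],
    contains_one = qs[1] <= 1 && 1 <= qs[2]
  )
}

#' Tidy posterior summary (odds/rate ratios)
#'
#' One row per fixed-effect term and part, on the ratio scale
#' (`exp(coefficient)`: odds ratio in the reporting part, rate ratio in
#' the count part), with the posterior mean and equal-tailed credible
#' interval, and a flag for whether the interval contains 1 — the
#' conventional significance reading.
#'
#' @param x A [fit_hurdle()] result.
#' @param level Credible level, e.g. 0.95 or 0.90.
#' @param ... Unused.
#' @return A tibble with columns `part`, `term`, `estimate`, `conf.low`,
#'   `conf.high`, `contains_one`.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, level = 0.95, ...) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_invalid("`level` must be in (0, 1).")
  }
  m <- all_draws(x)
  if (nrow(m) == 0) stop_invalid("Empty posterior.")
  terms <- c("(Intercept)", x$design_columns)
  purrr::map_dfr(c("bin", "pois"), function(part) {
    purrr::map_dfr(terms, function(tm) {
      col <- paste0(part, "_", tm)
      dplyr::bind_cols(
        tibble::tibble(
          part = if (part == "bin") "binomial" else "poisson",
          term = tm
        ),
        summarize_beta_draws(m[, col], level)
      )
    })
  })
}

#' Posterior fit at a glance
#'
#' @param x A [fit_hurdle()] result.
#' @param ... Unused.
#' @return One-row tibble with data dimensions, sampler settings, and the
#'   worst core convergence diagnostics.
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  core <- x$diagnostics[!grepl("^(eta|S|tau)\\[|^lp__$", x$diagnostics$param), ]
  tibble::tibble(
    n_obs = nrow(x$panel$observations),
    n_tracts = x$panel$n_tracts,
    n_periods = x$panel$n_periods,
    chains = x$control$chains,
    draws = x$control$chains * x$control$iter,
    max_rhat = max_core_rhat(x),
    min_ess = suppressWarnings(min(core$ess, na.rm = TRUE)),
    response = x$response
  )
}

#' @export
summary.hurdle_fit <- function(object, level = 0.95, ...) {
  out <- tidy(object, level = level)
  attr(out, "level") <- level
  out
}
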