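#' Run configuration
#'
#' Assembles and validates the full configuration of a pipeline run.  A
#' run is fully reproducible from `(config, seed)`; unknown keys are
#' rejected so that typos fail fast rather than silently falling back to
#' defaults.
#'
#' @param scenario [synthetic_scenario()] for simulated inputs.
#' @param priors [prior_config()].
#' @param sampler [sampler_config()].
#' @param response Binomial-part response variant, see [fit_hurdle()].
#' @param fixed Named list of fixed hyperparameters, see [fit_hurdle()].
#' @param estimate_alpha See [fit_hurdle()].
#' @param hi_cutoff,lo_cutoff Hotspot cut-offs.
#' @param map_part Which part's latents feed the risk map.
#' @param png Render choropleth images.
#' @param seed Master seed of the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = synthetic_scenario(),
                       priors = prior_config(),
                       sampler = sampler_config(),
                       response = c("count", "indicator"),
                       fixed = list(),
                       estimate_alpha = FALSE,
                       hi_cutoff = 0.8,
                       lo_cutoff = 0.2,
                       map_part = c("binomial", "poisson"),
                       png = FALSE,
                       seed = 1) {
  stopifnot(
    inherits(scenario, "synthetic_scenario"),
    inherits(priors, "prior_config"),
    inherits(sampler, "sampler_config")
  )
  structure(
    list(
      scenario = scenario, priors = priors, sampler = sampler,
      response = match.arg(response), fixed = fixed,
      estimate_alpha = isTRUE(estimate_alpha),
      hi_cutoff = hi_cutoff, lo_cutoff = lo_cutoff,
      map_part = match.arg(map_part), png = isTRUE(png),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Strictly validated: unknown keys at any level abort the run.
#'
#' @param path YAML file with any of the blocks `scenario`, `priors`,
#'   `sampler`, and the scalar keys of [run_config()]; `scenario` may
#'   contain a `matern` sub-block (`sigma2`, `nu`, and `kappa` or `rho`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c(
    "scenario", "priors", "sampler", "response", "fixed", "estimate_alpha",
    "hi_cutoff", "lo_cutoff", "map_part", "png", "seed"
  )
  check_keys <- function(x, known, where) {
    bad <- setdiff(names(x), known)
    if (length(bad) > 0) {
      abort(
        paste0(
          "Unknown configuration key(s) in ", where, ": ",
          paste(bad, collapse = ", ")
        ),
        class = "hurdlemap_config_error"
      )
    }
  }
  check_keys(raw, known_top, "top level")
  sc_args <- raw$scenario %||% list()
  check_keys(sc_args, c(
    "n_tracts", "n_periods", "extent", "true_betas_binomial",
    "true_betas_poisson", "matern", "var_eta", "var_tau", "missing_frac",
    "zeros", "seed"
  ), "scenario")
  if (!is.null(sc_args$matern)) {
    check_keys(sc_args$matern, c("sigma2", "nu", "kappa", "rho"), "scenario$matern")
    sc_args$matern <- do.call(matern_params, sc_args$matern)
  }
  for (nm in c("true_betas_binomial", "true_betas_poisson")) {
    if (!is.null(sc_args[[nm]])) sc_args[[nm]] <- unlist(sc_args[[nm]])
  }
  pr_args <- raw$priors %||% list()
  check_keys(pr_args, c(
    "beta_sd", "sd_scale", "rho_median", "rho_logsd", "nu",
    "alpha_mean", "alpha_sd"
  ), "priors")
  sa_args <- raw$sampler %||% list()
  check_keys(sa_args, c("chains", "iter", "warmup", "thin"), "sampler")
  args <- raw[setdiff(names(raw), c("scenario", "priors", "sampler"))]
  args$scenario <- do.call(synthetic_scenario, sc_args)
  args$priors <- do.call(prior_config, pr_args)
  args$sampler <- do.call(sampler_config, sa_args)
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)),
      class = "hurdlemap_pipeline_error", parent = e
    )
  })
}

# FNV-1a over a canonical deparse; good enough to fingerprint a config.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Simulate inputs and write them to disk
#'
#' Writes the synthetic geography (`tracts.geojson`), the tract covariate
#' table (`covariates.csv`), the tract-period count panel (`panel.csv`)
#' and the simulation truth (`truth.csv`: gates and true probabilities).
#'
#' @param config A [run_config()] (its `scenario` block is used).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `hurdle_sim` object.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_hurdle_data(config$scenario)
  tr <- sim$panel$tracts
  write_geojson(
    tr, file.path(out_dir, "tracts.geojson"),
    properties = as.data.frame(tr[c("tract_id", "x", "y", "population")])
  )
  readr::write_csv(
    tr[c("tract_id", "population", covariate_columns(), "deprivation")],
    file.path(out_dir, "covariates.csv")
  )
  obs <- sim$panel$observations
  readr::write_csv(
    obs[c("tract_id", "period", "count")],
    file.path(out_dir, "panel.csv")
  )
  readr::write_csv(
    obs[c("tract_id", "period", "gate", "true_p", "true_rate")],
    file.path(out_dir, "truth.csv")
  )
  invisible(sim)
}

#' Assemble a panel dataset from files
#'
#' Reads the tract covariate CSV, the count panel CSV (or a CSV of point
#' observations with coordinates), and the tract geometry GeoJSON, and
#' validates them into a [hurdle_panel()].  Point observations are
#' assigned to the containing tract polygon and counted; a point on a
#' shared boundary goes to the tract with the lexicographically smallest
#' id.
#'
#' @param covariates_csv Tract-level CSV keyed on `tract_id`, with
#'   `population` and the covariates of [covariate_columns()].
#' @param geometry_geojson Tract polygons keyed on `tract_id`.
#' @param panel_csv Pre-aggregated counts (`tract_id`, `period`, `count`).
#' @param points_csv Alternative to `panel_csv`: point observations with
#'   columns `x`, `y` and optionally `period` (default 1).
#' @return A [hurdle_panel()].
#' @export
read_panel <- function(covariates_csv, geometry_geojson,
                       panel_csv = NULL, points_csv = NULL) {
  if (is.null(panel_csv) == is.null(points_csv)) {
    stop_invalid("Provide exactly one of `panel_csv` and `points_csv`.")
  }
  covs <- readr::read_csv(covariates_csv, show_col_types = FALSE)
  geo <- read_geojson(geometry_geojson)
  orphans <- c(
    setdiff(covs$tract_id, geo$tract_id),
    setdiff(geo$tract_id, covs$tract_id)
  )
  if (length(orphans) > 0) {
    abort(
      paste0(
        "tract_id mismatch between covariates and geometry: ",
        paste(head(unique(orphans), 5), collapse = ", ")
      ),
      class = "hurdlemap_schema_error"
    )
  }
  tracts <- dplyr::left_join(
    geo[c("tract_id", "x", "y", "geometry")], covs,
    by = "tract_id"
  )
  if (!is.null(panel_csv)) {
    obs <- readr::read_csv(panel_csv, show_col_types = FALSE)
  } else {
    pts <- readr::read_csv(points_csv, show_col_types = FALSE)
    if (!"period" %in% names(pts)) pts$period <- 1L
    obs <- assign_points(pts, tracts)
  }
  hurdle_panel(obs, tracts)
}

# Count point observations per tract-period by point-in-polygon, with the
# lexicographically-smallest-id tie rule on shared boundaries.  Emits an
# explicit zero for every tract-period in the observed period range.
assign_points <- function(points, tracts) {
  ord <- order(tracts$tract_id)
  ids <- tracts$tract_id[ord]
  polys <- tracts$geometry[ord]
  assigned <- character(nrow(points))
  for (k in seq_len(nrow(points))) {
    pt <- c(points$x[k], points$y[k])
    hit <- NA_character_
    for (j in seq_along(ids)) {
      if (point_in_polygon(pt, polys[[j]])) {
        hit <- ids[j]
        break
      }
    }
    if (is.na(hit)) {
      abort(
        sprintf(
          "Point (%g, %g) lies outside every tract polygon.", pt[1], pt[2]
        ),
        class = "hurdlemap_assignment_error"
      )
    }
    assigned[k] <- hit
  }
  counted <- dplyr::count(
    tibble::tibble(tract_id = assigned, period = as.integer(points$period)),
    .data$tract_id, .data$period,
    name = "count"
  )
  grid <- tidyr::expand_grid(
    tract_id = tracts$tract_id,
    period = seq_len(max(counted$period))
  )
  out <- dplyr::left_join(grid, counted, by = c("tract_id", "period"))
  out$count[is.na(out$count)] <- 0
  out$count <- as.numeric(out$count)
  out
}

#' Fit the model and persist the posterior
#'
#' Fits [fit_hurdle()] and writes the posterior store: one CSV of kept
#' draws per chain, the odds-ratio summary table (posterior mean OR with
#' 90% and 95% intervals and their unity flags), the diagnostics table,
#' and a JSON manifest.
#'
#' @param panel A [hurdle_panel()].
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the `hurdle_fit`.
#' @export
run_fit <- function(panel, config, out_dir) {
  dir.create(file.path(out_dir, "posterior"), recursive = TRUE, showWarnings = FALSE)
  fit <- fit_hurdle(
    panel,
    priors = config$priors, control = config$sampler,
    seed = derive_seed(config$seed, 2L),
    response = config$response, fixed = config$fixed,
    estimate_alpha = config$estimate_alpha
  )
  for (k in seq_along(fit$chains)) {
    readr::write_csv(
      tibble::as_tibble(fit$chains[[k]]),
      file.path(out_dir, "posterior", sprintf("chain_%d.csv", k))
    )
  }
  readr::write_csv(
    or_summary(fit),
    file.path(out_dir, "or_summary.csv")
  )
  readr::write_csv(fit$diagnostics, file.path(out_dir, "diagnostics.csv"))
  jsonlite::write_json(
    list(
      seed = fit$seed,
      chains = fit$control$chains,
      iter = fit$control$iter,
      warmup = fit$control$warmup,
      thin = fit$control$thin,
      response = fit$response,
      estimate_alpha = fit$estimate_alpha,
      n_tracts = panel$n_tracts,
      n_periods = panel$n_periods,
      design_columns = fit$design_columns,
      max_core_rhat = max_core_rhat(fit)
    ),
    file.path(out_dir, "posterior", "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(fit)
}

# Table-3-style summary: OR with 95% and 90% equal-tailed intervals and
# unity flags for both parts.
or_summary <- function(fit) {
  t95 <- tidy(fit, level = 0.95)
  t90 <- tidy(fit, level = 0.90)
  dplyr::bind_cols(
    t95[c("part", "term", "estimate")],
    tibble::tibble(
      ci95_low = t95$conf.low, ci95_high = t95$conf.high,
      sig95 = !t95$contains_one,
      ci90_low = t90$conf.low, ci90_high = t90$conf.high,
      sig90 = !t90$contains_one
    )
  )
}

#' Reload a persisted posterior
#'
#' @param out_dir Directory previously written by [run_fit()].
#' @return A list with `chains` (draw matrices) and the manifest fields.
#' @export
read_posterior <- function(out_dir) {
  man <- jsonlite::fromJSON(file.path(out_dir, "posterior", "manifest.json"))
  files <- sort(list.files(
    file.path(out_dir, "posterior"),
    pattern = "^chain_\\d+\\.csv$", full.names = TRUE
  ))
  chains <- lapply(files, function(f) {
    as.matrix(readr::read_csv(f, show_col_types = FALSE))
  })
  c(list(chains = chains), man)
}

#' Compute and export the risk surface from a persisted posterior
#'
#' @param posterior_dir Directory written by [run_fit()].
#' @param geometry_geojson Tract geometry file.
#' @param out_dir Output directory for the layers.
#' @param config A [run_config()] (cut-offs and map part).
#' @return Invisibly, the [risk_surface()] tibble.
#' @export
run_map <- function(posterior_dir, geometry_geojson, out_dir, config) {
  post <- read_posterior(posterior_dir)
  tracts <- read_geojson(geometry_geojson)
  m <- do.call(rbind, post$chains)
  n <- post$n_tracts
  eta <- m[, paste0("eta[", seq_len(n), "]"), drop = FALSE]
  s <- m[, paste0("S[", seq_len(n), "]"), drop = FALSE]
  logrr <- eta + s
  if (config$map_part == "poisson" && isTRUE(post$estimate_alpha)) {
    logrr <- logrr * m[, "alpha"]
  }
  rr <- exp(logrr)
  colnames(rr) <- tracts$tract_id[seq_len(n)]
  prp <- exceedance_prob(rr)
  qs <- apply(rr, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  surface <- tibble::tibble(
    tract_id = colnames(rr),
    rr_mean = unname(colMeans(rr)),
    rr_low = unname(qs[1, ]),
    rr_high = unname(qs[2, ]),
    prp = unname(prp),
    hotspot_label = classify_hotspots(unname(prp), config$hi_cutoff, config$lo_cutoff)
  )
  class(surface) <- c("risk_surface", class(surface))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  export_layers(tracts, surface, file.path(out_dir, "risk"), png = config$png)
  invisible(surface)
}

#' Run the full pipeline
#'
#' Simulate -> covariate coding -> joint fit -> summary table -> risk
#' layers, writing every artefact class under `out_dir`: simulated data
#' (`data/`), the posterior store (`posterior/` + `or_summary.csv`), the
#' risk layers (`layers/`), a run manifest (`manifest.json`) and a plain
#' log (`log.txt`).  Rerunning with the same config and seed reproduces
#' every table and layer byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fit, surface and paths.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  note("stage simulate: %d tracts x %d periods", config$scenario$n_tracts,
       config$scenario$n_periods)
  sim <- stage("simulate", run_simulate(config, file.path(out_dir, "data")))

  note("stage fit: %d chains x %d iterations (+%d warmup)",
       config$sampler$chains, config$sampler$iter, config$sampler$warmup)
  fit <- stage("fit", run_fit(sim$panel, config, out_dir))

  note("stage map: part %s, cutoffs %g/%g", config$map_part,
       config$hi_cutoff, config$lo_cutoff)
  surface <- stage("map", {
    surf <- risk_surface(
      fit,
      part = config$map_part,
      hi_cutoff = config$hi_cutoff, lo_cutoff = config$lo_cutoff
    )
    dir.create(file.path(out_dir, "layers"), showWarnings = FALSE)
    export_layers(
      sim$panel$tracts, surf, file.path(out_dir, "layers", "risk"),
      png = config$png
    )
    surf
  })

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("hurdlemap")),
    n_tracts = sim$panel$n_tracts,
    n_periods = sim$panel$n_periods,
    n_observations = nrow(sim$panel$observations),
    max_core_rhat = max_core_rhat(fit),
    artefacts = c(
      "data/tracts.geojson", "data/covariates.csv", "data/panel.csv",
      "posterior", "or_summary.csv", "diagnostics.csv", "layers/risk.geojson",
      "layers/risk.csv", "manifest.json"
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  note("run complete")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(fit = fit, surface = surface, out_dir = out_dir))
}
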