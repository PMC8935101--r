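#' Posterior draws of the smoothed relative risk
#'
#' The smoothed relative risk of a tract is the model-unexplained residual
#' risk after covariate adjustment: by default `RR_i = exp(S_i + eta_i)`
#' per posterior draw, combining the spatially structured and unstructured
#' latent fields (time-aggregated; the temporal effect is excluded, and can
#' be folded in for period-specific maps).  For the Poisson part the shared
#' latents are scaled by the sharing parameter `alpha`.  Optionally the
#' (mean-centred) covariate contribution can be included for a full-risk
#' map.
#'
#' @param fit A [fit_hurdle()] result.
#' @param part Which part's latent scale to map: `"binomial"` (reporting
#'   probability, the default) or `"poisson"` (count intensity).
#' @param include_covariates Add the mean-centred fixed-effect contribution
#'   `(x_i - x_bar)'beta` to the log-risk.
#' @return A draws x tracts matrix of relative-risk draws, with tract ids
#'   as column names.
#' @export
smoothed_rr <- function(fit, part = c("binomial", "poisson"),
                        include_covariates = FALSE) {
  stopifnot(inherits(fit, "hurdle_fit"))
  part <- match.arg(part)
  m <- all_draws(fit)
  n <- fit$panel$n_tracts
  eta <- m[, paste0("eta[", seq_len(n), "]"), drop = FALSE]
  s <- m[, paste0("S[", seq_len(n), "]"), drop = FALSE]
  if (ncol(eta) != n || ncol(s) != n) {
    abort("Posterior is missing latent-field draws.",
      class = "hurdlemap_schema_error"
    )
  }
  logrr <- eta + s
  if (part == "poisson") {
    alpha <- if (fit$estimate_alpha) m[, "alpha"] else 1
    logrr <- logrr * alpha
  }
  if (include_covariates) {
    prefix <- if (part == "binomial") "bin_" else "pois_"
    X <- as.matrix(fit$panel$design[fit$design_columns])
    Xc <- sweep(X, 2, colMeans(X))
    betas <- m[, paste0(prefix, fit$design_columns), drop = FALSE]
    logrr <- logrr + betas %*% t(Xc)
  }
  out <- exp(logrr)
  colnames(out) <- fit$panel$tracts$tract_id
  out
}

#' Exceedance probabilities
#'
#' Per-tract posterior probability that the smoothed relative risk exceeds
#' 1 (strictly), estimated as the fraction of posterior draws above 1.
#'
#' @param rr_draws Draws x tracts matrix from [smoothed_rr()] (or any
#'   matrix of positive draws).
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @examples
#' exceedance_prob(matrix(c(0.5, 1.5, 2.0, 0.8), ncol = 1))  # 0.5
#' @export
exceedance_prob <- function(rr_draws) {
  rr_draws <- as.matrix(rr_draws)
  if (nrow(rr_draws) < 1 || ncol(rr_draws) < 1) {
    stop_invalid("`rr_draws` needs at least one draw per tract.")
  }
  colMeans(rr_draws > 1)
}

#' Hotspot classification by the 80/20 rule
#'
#' Applies the conventional exceedance-probability interpretation rule: a
#' tract is a hotspot when its exceedance probability is above the high
#' cut-off (default 80%), a coldspot below the low cut-off (default 20%),
#' and uncertain otherwise.  Values exactly on a cut-off are classed
#' uncertain.
#'
#' @param probs Exceedance probabilities in `[0, 1]`.
#' @param hi_cutoff,lo_cutoff Classification cut-offs.
#' @return Factor with levels `hotspot`, `coldspot`, `uncertain`.
#' @examples
#' classify_hotspots(c(0.85, 0.15, 0.80))
#' @export
classify_hotspots <- function(probs, hi_cutoff = 0.8, lo_cutoff = 0.2) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_invalid("`probs` must lie in [0, 1].")
  }
  if (lo_cutoff > hi_cutoff) stop_invalid("`lo_cutoff` must be <= `hi_cutoff`.")
  lab <- rep("uncertain", length(probs))
  lab[probs > hi_cutoff] <- "hotspot"
  lab[probs < lo_cutoff] <- "coldspot"
  factor(lab, levels = c("hotspot", "coldspot", "uncertain"))
}

#' Relative-risk surface summary
#'
#' Summarises the smoothed relative risk per tract — posterior mean,
#' equal-tailed interval, exceedance probability, and hotspot label.
#'
#' @inheritParams smoothed_rr
#' @param level Credible level of the RR interval.
#' @param hi_cutoff,lo_cutoff Hotspot cut-offs, see [classify_hotspots()].
#' @return A tibble of class `risk_surface` with columns `tract_id`,
#'   `rr_mean`, `rr_low`, `rr_high`, `prp`, `hotspot_label`.
#' @export
risk_surface <- function(fit, part = c("binomial", "poisson"),
                         level = 0.95, hi_cutoff = 0.8, lo_cutoff = 0.2,
                         include_covariates = FALSE) {
  rr <- smoothed_rr(fit, part, include_covariates)
  a <- (1 - level) / 2
  qs <- apply(rr, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  prp <- exceedance_prob(rr)
  out <- tibble::tibble(
    tract_id = colnames(rr),
    rr_mean = unname(colMeans(rr)),
    rr_low = unname(qs[1, ]),
    rr_high = unname(qs[2, ]),
    prp = unname(prp),
    hotspot_label = classify_hotspots(unname(prp), hi_cutoff, lo_cutoff)
  )
  class(out) <- c("risk_surface", class(out))
  out
}

#' Export map-ready risk layers
#'
#' Writes the risk surface joined to the tract geometry as a GeoJSON
#' FeatureCollection (properties: `tract_id`, `rr_mean`, `rr_low`,
#' `rr_high`, `prp`, `hotspot_label`) plus a CSV twin, and optionally a
#' rendered choropleth (RR and exceedance probability side by side).
#'
#' @param tracts Tract frame with a `geometry` list-column covering every
#'   tract in `surface`.
#' @param surface A [risk_surface()] tibble.
#' @param out_path Output path without extension; `.geojson`, `.csv` (and
#'   `.png` if requested) are appended.
#' @param png Also render the choropleth image.
#' @return Invisibly, the paths written.
#' @export
export_layers <- function(tracts, surface, out_path, png = FALSE) {
  missing_geo <- setdiff(surface$tract_id, tracts$tract_id)
  if (!"geometry" %in% names(tracts)) {
    abort("`tracts` has no geometry column.", class = "hurdlemap_schema_error")
  }
  if (length(missing_geo) > 0) {
    abort(
      paste0(
        "No geometry for tract(s): ", paste(head(missing_geo, 5), collapse = ", ")
      ),
      class = "hurdlemap_schema_error"
    )
  }
  props <- as.data.frame(surface)
  props$hotspot_label <- as.character(props$hotspot_label)
  geo <- tracts[match(surface$tract_id, tracts$tract_id), ]
  paths <- c(
    geojson = paste0(out_path, ".geojson"),
    csv = paste0(out_path, ".csv")
  )
  write_geojson(geo, paths[["geojson"]], properties = props)
  readr::write_csv(props, paths[["csv"]])
  if (png) {
    paths <- c(paths, png = paste0(out_path, ".png"))
    gg <- plot_risk_map(tracts, surface)
    ggplot2::ggsave(paths[["png"]], gg, width = 10, height = 5, dpi = 120)
  }
  invisible(paths)
}

#' Choropleth of relative risk and exceedance probability
#'
#' Draws the tract polygons twice — filled by posterior mean RR and by
#' exceedance probability — the conventional pair of disease-mapping
#' panels.
#'
#' @param tracts Tract frame with `geometry`.
#' @param surface A [risk_surface()].
#' @return A ggplot object.
#' @export
plot_risk_map <- function(tracts, surface) {
  geo <- tracts[match(surface$tract_id, tracts$tract_id), ]
  poly <- purrr::map2_dfr(geo$geometry, geo$tract_id, function(g, id) {
    tibble::tibble(x = g[, 1], y = g[, 2], tract_id = id)
  })
  long <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::left_join(poly, surface[c("tract_id", "rr_mean")], by = "tract_id"),
      metric = "relative risk", value = .data$rr_mean
    ),
    dplyr::mutate(
      dplyr::left_join(poly, surface[c("tract_id", "prp")], by = "tract_id"),
      metric = "Pr(RR > 1)", value = .data$prp
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y,
    group = .data$tract_id, fill = .data$value
  )) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_risk_map
#' @param object A `risk_surface`.
#' @param tracts Tract frame with geometry.
#' @param ... Unused.
#' @method autoplot risk_surface
#' @export
autoplot.risk_surface <- function(object, tracts, ...) {
  plot_risk_map(tracts, object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
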