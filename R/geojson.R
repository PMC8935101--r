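# Minimal RFC 7946 GeoJSON I/O for tract frames.  Geometries are Polygons
# (from the `geometry` list-column of open-ring vertex matrices) or Points
# (centroids) when no polygons are present.  Properties are taken from a
# data frame aligned with the tracts.

close_ring <- function(m) {
  if (nrow(m) < 3) stop_invalid("Polygon ring needs at least 3 vertices.")
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

#' Write a tract frame as GeoJSON
#'
#' @param tracts Tract frame; polygon geometry is taken from the
#'   `geometry` list-column when present, otherwise point geometry from
#'   `x`, `y`.
#' @param path Output file.
#' @param properties Data frame of per-tract properties (defaults to the
#'   non-geometry columns of `tracts`).
#' @param digits Significant digits written for numbers.
#' @return Invisibly, `path`.
#' @export
write_geojson <- function(tracts, path, properties = NULL, digits = 10) {
  if (is.null(properties)) {
    properties <- as.data.frame(
      tracts[setdiff(names(tracts), c("geometry"))]
    )
  }
  has_poly <- "geometry" %in% names(tracts)
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    geom <- if (has_poly) {
      ring <- close_ring(tracts$geometry[[i]])
      list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(k) {
          as.numeric(ring[k, ])
        }))
      )
    } else {
      list(type = "Point", coordinates = c(tracts$x[i], tracts$y[i]))
    }
    prop <- as.list(properties[i, , drop = FALSE])
    prop <- lapply(prop, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature", geometry = geom, properties = prop)
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = digits)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection into a tract frame
#'
#' Supports Polygon and Point features; polygon centroids populate `x`,
#' `y` (vertex mean) when the properties do not carry them.
#'
#' @param path GeoJSON file.
#' @return A tibble with the feature properties, a `geometry` list-column
#'   for polygons, and centroid columns `x`, `y`.
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    abort("Not a GeoJSON FeatureCollection.", class = "hurdlemap_schema_error")
  }
  rows <- lapply(doc$features, function(f) {
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    geom <- f$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], as.numeric))
      ring <- ring[-nrow(ring), , drop = FALSE] # reopen the ring
      props$geometry <- list(ring)
      if (is.null(props$x)) props$x <- mean(ring[, 1])
      if (is.null(props$y)) props$y <- mean(ring[, 2])
    } else if (identical(geom$type, "Point")) {
      props$x <- as.numeric(geom$coordinates[[1]])
      props$y <- as.numeric(geom$coordinates[[2]])
    } else {
      abort(paste0("Unsupported geometry type: ", geom$type),
        class = "hurdlemap_schema_error"
      )
    }
    tibble::as_tibble(props)
  })
  dplyr::bind_rows(rows)
}
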