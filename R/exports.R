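#' Export a gridded UD as ESRI-ASCII grid text
#'
#' @param ud a `grid_ud`.
#' @param path output path.
#' @export
write_esri_ascii <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ud$nx),
               sprintf("nrows %d", ud$ny),
               sprintf("xllcorner %.3f", ud$x0),
               sprintf("yllcorner %.3f", ud$y0),
               sprintf("cellsize %.3f", ud$cell),
               "NODATA_value -9999"), con)
  # ESRI rows run north to south
  for (j in rev(seq_len(ud$ny)))
    writeLines(paste(format(ud$z[, j], digits = 10, scientific = TRUE),
                     collapse = " "), con)
  invisible(path)
}

# square polygon rings (planar metres) for each connected component of a
# cell set; coordinates are cell corners
component_rings <- function(g, member_idx, component) {
  lapply(sort(unique(component)), function(k) {
    memb <- member_idx[component == k]
    ij <- arrayInd(memb, c(g$nx, g$ny))
    lapply(seq_len(nrow(ij)), function(r) {
      x <- g$x0 + (ij[r, 1] - 1) * g$cell
      y <- g$y0 + (ij[r, 2] - 1) * g$cell
      list(rbind(c(x, y), c(x + g$cell, y), c(x + g$cell, y + g$cell),
                 c(x, y + g$cell), c(x, y)))
    })
  })
}

#' Export isopleth polygons as GeoJSON
#'
#' Each connected component is a MultiPolygon of its cell squares, in planar
#' coordinates (metres) with the projection centre recorded in `properties`.
#'
#' @param iso an `isopleth_set` (from [isopleth()]).
#' @param ud the `grid_ud` it came from.
#' @param path output path.
#' @param properties named list merged into every feature's properties.
#' @export
write_isopleth_geojson <- function(iso, ud, path, properties = list()) {
  g <- ud_grid(ud)
  rings <- component_rings(g, iso$member_idx, iso$component)
  feats <- lapply(seq_along(rings), function(k) {
    props <- c(list(component = k, level = iso$level), properties)
    if (!is.null(ud$proj))
      props <- c(props, list(projection = sprintf(
        "laea +lon_0=%.6f +lat_0=%.6f +R=%.0f", ud$proj$lon0, ud$proj$lat0,
        ud$proj$R)))
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = rings[[k]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a mean route as GeoJSON LineString
#'
#' Coordinates are planar kilometres in the working projection; the
#' per-point variance array rides along in `properties`.
#'
#' @param route a `mean_route`.
#' @param path output path.
#' @export
write_route_geojson <- function(route, path) {
  feat <- list(type = "Feature",
               properties = list(direction = route$direction,
                                 route_variation_km = route$route_variation_km,
                                 per_point_variance_km2 = route$per_point_variance,
                                 units = "km (planar, equal-area projection)"),
               geometry = list(type = "LineString",
                               coordinates = lapply(seq_len(nrow(route$points)),
                                 function(r) route$points[r, ])))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
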