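# Planar equirectangular projection used throughout: one configurable
# reference latitude; 111.32 km per degree; longitude scaled by
# cos(ref_lat).  At the ~250 x 400 km extent of a regional invasion this
# is accurate to well under one 10 km grid cell.

#' Project geographic coordinates to planar km
#'
#' Equirectangular projection about a reference latitude:
#' `x = (lon - lon0) * 111.32 * cos(ref_lat)`, `y = (lat - lat0) * 111.32`.
#'
#' @param lat,lon decimal degrees.
#' @param origin `c(lat0, lon0)` mapped to (0, 0).
#' @param ref_lat reference latitude for the longitude scale (defaults to
#'   `origin[1]`).
#' @return A two-column matrix of `x`, `y` in km.
#' @export
project_km <- function(lat, lon, origin, ref_lat = origin[1]) {
  cbind(x = (lon - origin[2]) * 111.32 * cos(ref_lat * pi / 180),
        y = (lat - origin[1]) * 111.32)
}

#' Pairwise planar distances between registry sites
#'
#' @param reg a [site_registry()].
#' @param ref_lat reference latitude; defaults to the mean site latitude.
#' @return Symmetric matrix of distances in km, dimnames = site ids.
#' @export
site_distances <- function(reg, ref_lat = mean(reg$lat)) {
  xy <- project_km(reg$lat, reg$lon, origin = c(min(reg$lat), min(reg$lon)),
                   ref_lat = ref_lat)
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(reg$site_id, reg$site_id)
  d
}

#' Bearing from one site to another
#'
#' Planar bearing in degrees clockwise from north (0 = north, 90 = east),
#' computed in the package's equirectangular projection.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (from site 1 toward site 2).
#' @param ref_lat reference latitude.
#' @return Bearing(s) in `[0, 360)`.
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2, ref_lat = mean(c(lat1, lat2))) {
  dx <- (lon2 - lon1) * 111.32 * cos(ref_lat * pi / 180)
  dy <- (lat2 - lat1) * 111.32
  (atan2(dx, dy) * 180 / pi) %% 360
}
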