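#' Equirectangular projection between lon/lat and raster kilometres
#'
#' The cost-distance machinery works on square projected cells in km, while
#' date tables carry geographic coordinates.  These helpers implement an
#' equirectangular (plate carree) projection with a configurable standard
#' parallel `lat0`: `x = R * cos(lat0) * lon`, `y = R * lat` (angles in
#' radians, R = 6371 km).  Cells are truly square only near `lat0`; for
#' continental-scale work spanning many degrees of latitude, project your
#' raster and sites upstream with a proper GIS equal-distance projection and
#' feed the package projected coordinates directly — these helpers exist so
#' the synthetic fixtures and demos are self-contained.
#'
#' @param lon,lat geographic coordinates, decimal degrees.
#' @param x,y projected coordinates, km.
#' @param lat0 standard parallel, decimal degrees (default 30, roughly the
#'   latitude of the study corridor from the Fertile Crescent to India).
#' @return `project_lonlat`: matrix with columns `x`, `y` (km);
#'   `unproject_xy`: matrix with columns `lon`, `lat` (degrees).
#' @export
project_lonlat <- function(lon, lat, lat0 = 30) {
  k <- 6371 * pi / 180
  cbind(x = k * cos(lat0 * pi / 180) * lon, y = k * lat)
}

#' @rdname project_lonlat
#' @export
unproject_xy <- function(x, y, lat0 = 30) {
  k <- 6371 * pi / 180
  cbind(lon = x / (k * cos(lat0 * pi / 180)), lat = y / k)
}
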