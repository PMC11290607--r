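#' Great-circle distance on a spherical Earth
#'
#' Haversine formula on a sphere of mean Earth radius 6,371,008.8 m.
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectorised.
#' @param radius sphere radius in metres.
#' @return distance in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2, radius = 6371008.8) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Deterministic per-stage seed
#'
#' Derives a stage seed from the master seed and the stage name so stages
#' can be rerun independently yet reproducibly.
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 69069 + h * 101) %% 2147483629)
}

#' Point-in-polygon test
#'
#' @param pts two-column matrix of lon/lat points.
#' @param poly two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector, `TRUE` for points inside.
#' @export
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- matrix(as.numeric(poly), ncol = 2)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, pts)
}

#' Serialize a polygon ring as WKT
#' @param poly two-column matrix of vertices.
#' @return `POLYGON ((...))` string.
#' @export
polygon_to_wkt <- function(poly) {
  poly <- matrix(as.numeric(poly), ncol = 2)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.8g %.8g", poly[, 1], poly[, 2]), collapse = ", "))
}

#' Parse a WKT POLYGON ring
#' @param wkt `POLYGON ((...))` string (outer ring only).
#' @return two-column matrix of vertices (closing vertex dropped).
#' @export
wkt_to_polygon <- function(wkt) {
  inner <- sub(".*\\(\\(", "", sub("\\)\\).*", "", wkt))
  xy <- do.call(rbind, lapply(strsplit(trimws(
    strsplit(inner, ",")[[1]]), "\\s+"), as.numeric))
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  colnames(xy) <- c("lon", "lat")
  xy
}
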