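#' Per-species range-shift metrics
#'
#' Compares current and future binary range maps: relative area change (the
#' ratio of future to current suitable-cell counts), altitude difference
#' (future minus current mean elevation over suitable cells, m), centroid
#' difference (great-circle distance between the unweighted centroids of the
#' suitable cell centres, m, on a sphere of radius 6,371,008.8 m) and the
#' centroid latitude shift in degrees (future minus current). An empty
#' future range yields a ratio of 0 with the displacement metrics missing.
#'
#' @param current,future binary `raster_grid`s (aligned).
#' @param elevation elevation `raster_grid` (aligned), metres.
#' @param cos_lat_weight weight cell centres by `cos(lat)` when averaging
#'   (approximate area weighting); off by default.
#' @return one-row data.frame of the metrics.
#' @export
range_metrics <- function(current, future, elevation,
                          cos_lat_weight = FALSE) {
  check_aligned(current, future, elevation)
  pts <- grid_points(current)
  cur <- as.vector(current$values) > 0
  fut <- as.vector(future$values) > 0
  if (!any(cur)) stop("current range is empty")
  wts <- if (cos_lat_weight) cos(pts[, "lat"] * pi / 180) else
    rep(1, nrow(pts))
  centroid <- function(sel) c(
    lon = stats::weighted.mean(pts[sel, "lon"], wts[sel]),
    lat = stats::weighted.mean(pts[sel, "lat"], wts[sel]))
  elev <- as.vector(elevation$values)
  cc <- centroid(cur)
  if (!any(fut))
    return(data.frame(relative_area_change = 0,
                      altitude_difference = NA_real_,
                      centroid_difference = NA_real_,
                      centroid_latitude_shift = NA_real_,
                      n_current = sum(cur), n_future = 0L))
  cf <- centroid(fut)
  data.frame(
    relative_area_change = sum(fut) / sum(cur),
    altitude_difference = stats::weighted.mean(elev[fut], wts[fut]) -
      stats::weighted.mean(elev[cur], wts[cur]),
    centroid_difference = haversine_m(cc["lon"], cc["lat"],
                                      cf["lon"], cf["lat"]),
    centroid_latitude_shift = unname(cf["lat"] - cc["lat"]),
    n_current = sum(cur), n_future = sum(fut))
}

#' Gain/loss raster between two binary maps
#'
#' Byproduct map: +1 where habitat is gained, -1 where lost, 0 elsewhere.
#' @inheritParams range_metrics
#' @return a `raster_grid`.
#' @export
gain_loss_map <- function(current, future) {
  check_aligned(current, future)
  raster_grid((future$values > 0) - (current$values > 0),
              current$xll, current$yll, current$cellsize, name = "gain_loss")
}

#' Summarise range shifts across species
#'
#' Arithmetic mean and standard error (sd/sqrt(n)) of the latitude and
#' altitude shifts per scenario and period, with counts of species shifting
#' northward (positive latitude shift) and upward (positive altitude
#' shift). The SE is reported missing for single-species strata.
#'
#' @param shifts data.frame with columns `species`, `scenario`, `period`,
#'   `centroid_latitude_shift`, `altitude_difference`,
#'   `relative_area_change`.
#' @return data.frame, one row per scenario x period.
#' @export
summarise_shifts <- function(shifts) {
  if (nrow(shifts) < 1) stop("empty shift table")
  se <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else
    stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  strata <- split(shifts, list(shifts$scenario, shifts$period), drop = TRUE)
  do.call(rbind, lapply(strata, function(d) data.frame(
    scenario = d$scenario[1], period = d$period[1],
    n_species = nrow(d),
    mean_lat_shift = mean(d$centroid_latitude_shift, na.rm = TRUE),
    se_lat_shift = se(d$centroid_latitude_shift),
    n_northward = sum(d$centroid_latitude_shift > 0, na.rm = TRUE),
    mean_alt_shift = mean(d$altitude_difference, na.rm = TRUE),
    se_alt_shift = se(d$altitude_difference),
    n_upward = sum(d$altitude_difference > 0, na.rm = TRUE),
    mean_area_ratio = mean(d$relative_area_change, na.rm = TRUE),
    row.names = NULL)))
}
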