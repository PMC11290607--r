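#' Occurrence record set for one species
#'
#' @param species_id character id.
#' @param records data.frame with columns `lon`, `lat`, `year`,
#'   `uncertainty_m` and optionally `dirty` (provenance flag, `NA` for clean
#'   synthetic records).
#' @param meta list of provenance metadata (cleaning log etc.).
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(species_id, records, meta = list()) {
  need <- c("lon", "lat", "year", "uncertainty_m")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (!"dirty" %in% names(records)) records$dirty <- NA_character_
  structure(list(species_id = species_id, records = records, meta = meta),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d records\n",
              x$species_id, nrow(x$records)))
  if (length(x$meta$removed))
    cat("  cleaning removed:",
        paste(sprintf("%s=%d", names(x$meta$removed), x$meta$removed),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write / read occurrence CSV
#'
#' Column schema: `species, lon, lat, year, uncertainty_m`.
#' @param occ an `occurrence_set`.
#' @param path CSV path.
#' @export
write_occurrences <- function(occ, path) {
  df <- cbind(species = occ$species_id,
              occ$records[c("lon", "lat", "year", "uncertainty_m")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @return `read_occurrences`: a list of `occurrence_set`, one per species.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$species), function(d)
    occurrence_set(d$species[1],
                   d[c("lon", "lat", "year", "uncertainty_m")]))
}

#' Clean occurrence records
#'
#' Removes records collected before 1970, records outside the study area,
#' exact coordinate duplicates (coordinates compared after rounding to six
#' decimals, so sub-metre noise cannot defeat deduplication) and records
#' whose coordinate uncertainty exceeds the working resolution. The result
#' is order-independent: records are ranked by (year desc, uncertainty asc)
#' before duplicate resolution.
#'
#' @param occ an `occurrence_set`.
#' @param study_area two-column matrix of polygon vertices bounding the
#'   study area (lon/lat).
#' @param max_uncertainty_m maximum tolerated coordinate uncertainty,
#'   metres; default 10 km, roughly one grid cell.
#' @param min_year earliest accepted collection year.
#' @return a cleaned `occurrence_set`; `meta$removed` counts removals per
#'   rule and `meta$unmodellable` is `TRUE` when no record survives.
#' @export
clean_records <- function(occ, study_area, max_uncertainty_m = 10000,
                          min_year = 1970) {
  r <- occ$records
  if (nrow(r) == 0) stop("empty occurrence set")
  keep_year <- r$year >= min_year
  keep_area <- points_in_polygon(cbind(r$lon, r$lat), study_area)
  keep_unc <- r$uncertainty_m <= max_uncertainty_m
  r2 <- r[keep_year & keep_area & keep_unc, , drop = FALSE]
  # canonical order so the surviving duplicate does not depend on input order
  ord <- order(round(r2$lon, 6), round(r2$lat, 6),
               -r2$year, r2$uncertainty_m)
  r2 <- r2[ord, , drop = FALSE]
  dup <- duplicated(cbind(round(r2$lon, 6), round(r2$lat, 6)))
  out <- r2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  removed <- c(old_year = sum(!keep_year),
               outside = sum(!keep_area, na.rm = TRUE),
               uncertain = sum(!keep_unc),
               duplicate = sum(dup))
  occurrence_set(occ$species_id, out,
                 meta = c(occ$meta,
                          list(removed = removed,
                               unmodellable = nrow(out) == 0)))
}

#' Spatial thinning of occurrence records
#'
#' Greedy thinning: while any pair of records lies closer than the minimum
#' distance, the record with the most neighbours inside the radius is
#' removed (ties broken by a seeded random choice). The survivors satisfy
#' the pairwise minimum-distance guarantee exactly.
#'
#' @param occ an `occurrence_set`.
#' @param min_distance_cells minimum distance in grid-cell units.
#' @param cellsize_deg size of one grid cell in degrees; a cell is converted
#'   to metres along a meridian arc.
#' @param seed RNG seed for tie-breaking.
#' @return thinned `occurrence_set` (a subset of the input records).
#' @export
thin_spatially <- function(occ, min_distance_cells = 1, cellsize_deg = 0.1,
                           seed = 1) {
  if (min_distance_cells <= 0) stop("min_distance_cells must be positive")
  r <- occ$records
  n <- nrow(r)
  if (n < 2) return(occ)
  thr <- min_distance_cells * cellsize_deg * pi / 180 * 6371008.8
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <-
      haversine_m(r$lon[i], r$lat[i], r$lon[j], r$lat[j])
  }
  set.seed(seed)
  alive <- rep(TRUE, n)
  close <- d < thr
  diag(close) <- FALSE
  repeat {
    nb <- rowSums(close[alive, alive, drop = FALSE])
    if (!any(nb > 0)) break
    worst <- which(nb == max(nb))
    drop_local <- if (length(worst) > 1) sample(worst, 1) else worst
    alive[which(alive)[drop_local]] <- FALSE
  }
  out <- r[alive, , drop = FALSE]
  rownames(out) <- NULL
  occurrence_set(occ$species_id, out,
                 meta = c(occ$meta, list(thinned_out = sum(!alive))))
}

#' Buffered accessible area of a species
#'
#' Builds the minimum convex polygon (MCP) of the occurrences after removing
#' the fraction of points farthest from the arithmetic coordinate centroid,
#' then buffers it outwards by a distance weighted by the species' flight
#' period: `buffer_m = buffer_per_10months * flight_months / 10` (default
#' 100 km for a 10-month flyer, i.e. 10 km per flight month). The buffered
#' ring is the convex hull of geodesic circles drawn around every hull
#' vertex, which is exact for a convex core up to the bearing
#' discretisation.
#'
#' @param occ an `occurrence_set` (cleaned/thinned).
#' @param flight_months flight period length in months.
#' @param outlier_pct fraction of points dropped before hull construction
#'   (default 1\%); `ceiling(outlier_pct * n)` points are removed, none when
#'   `outlier_pct = 0`.
#' @param buffer_per_10months metres of buffer per 10 months of flight.
#' @param n_bearings arc discretisation of the vertex circles.
#' @return object of class `accessible_area` with `mcp` (hull vertices),
#'   `buffer_m` and `polygon` (buffered ring vertices).
#' @export
accessible_area <- function(occ, flight_months, outlier_pct = 0.01,
                            buffer_per_10months = 1e5, n_bearings = 72) {
  r <- occ$records
  n <- nrow(r)
  n_out <- if (outlier_pct > 0) ceiling(outlier_pct * n) else 0L
  if (n - n_out < 3) stop("fewer than 3 usable points for MCP")
  ctr <- c(mean(r$lon), mean(r$lat))
  dc <- haversine_m(r$lon, r$lat, ctr[1], ctr[2])
  keep <- rank(dc, ties.method = "first") <= n - n_out
  pts <- cbind(lon = r$lon[keep], lat = r$lat[keep])
  h <- grDevices::chull(pts)
  if (length(h) < 3) stop("retained points are collinear; MCP degenerate")
  mcp <- pts[h, , drop = FALSE]
  buffer_m <- buffer_per_10months * flight_months / 10
  bearings <- seq(0, 360, length.out = n_bearings + 1)[-(n_bearings + 1)]
  ring <- do.call(rbind, lapply(seq_len(nrow(mcp)), function(i)
    geosphere::destPoint(mcp[i, ], b = bearings, d = buffer_m)))
  ring <- rbind(ring, mcp)                 # numeric safety at vertices
  hb <- grDevices::chull(ring)
  structure(list(species_id = occ$species_id,
                 mcp = mcp, buffer_m = buffer_m,
                 polygon = ring[hb, , drop = FALSE]),
            class = "accessible_area")
}

#' @export
print.accessible_area <- function(x, ...) {
  cat(sprintf("accessible_area '%s': MCP %d vertices, buffer %.0f m\n",
              x$species_id, nrow(x$mcp), x$buffer_m))
  invisible(x)
}

#' Sample background points inside an accessible area
#'
#' Draws `2 * n_presences` points uniformly over the grid cells whose
#' centres fall inside the buffered accessible area, excluding cells that
#' already hold a presence. When fewer eligible cells than requested points
#' exist, cells are re-used (sampling with replacement) and a warning is
#' logged.
#'
#' @param area an `accessible_area`.
#' @param n_presences number of presence records (background = 2x).
#' @param grid reference `raster_grid`.
#' @param presence_cells linear cell indices already occupied by presences.
#' @param seed RNG seed.
#' @param ratio background-to-presence ratio.
#' @return data.frame `lon`, `lat`, `cell` of background points.
#' @export
sample_background <- function(area, n_presences, grid,
                              presence_cells = integer(0), seed = 1,
                              ratio = 2) {
  set.seed(seed)
  pts <- grid_points(grid)
  inside <- points_in_polygon(pts, area$polygon)
  eligible <- setdiff(which(inside), presence_cells)
  if (length(eligible) == 0) stop("buffered polygon contains no grid cell")
  n_bg <- ratio * n_presences
  replace <- length(eligible) < n_bg
  if (replace)
    warning(sprintf("only %d eligible cells for %d background points; %s",
                    length(eligible), n_bg, "sampling with replacement"))
  cells <- if (length(eligible) == 1)
    rep(eligible, n_bg)
  else
    sample(eligible, n_bg, replace = replace)
  data.frame(lon = pts[cells, "lon"], lat = pts[cells, "lat"], cell = cells)
}
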