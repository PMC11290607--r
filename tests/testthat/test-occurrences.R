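rect <- cbind(lon = c(-1, 1, 1, -1), lat = c(42, 42, 44, 44))

test_that("cleaning removes each violation class and is idempotent", {
  base <- data.frame(lon = seq(-0.9, 0.9, length.out = 15),
                     lat = seq(42.1, 43.9, length.out = 15),
                     year = 2000, uncertainty_m = 500)
  bad <- rbind(
    transform(base[1:2, ], year = c(1969, 1950)),           # too old
    transform(base[3:4, ], lon = c(5, -3)),                 # outside
    transform(base[5, ], uncertainty_m = 50000))            # too uncertain
  dup <- base[6, ]                                          # exact duplicate
  occ <- occurrence_set("t", rbind(base, bad, dup))
  cleaned <- clean_records(occ, rect, max_uncertainty_m = 10000)
  expect_equal(nrow(cleaned$records), 15)
  expect_equal(cleaned$meta$removed,
               c(old_year = 2, outside = 2, uncertain = 1, duplicate = 1))
  expect_true(all(cleaned$records$year >= 1970))
  # idempotence
  again <- clean_records(cleaned, rect)
  expect_equal(again$records, cleaned$records)
  # order independence
  shuffled <- occurrence_set("t", occ$records[sample(nrow(occ$records)), ])
  cl2 <- clean_records(shuffled, rect)
  o1 <- cleaned$records[order(cleaned$records$lon), c("lon", "lat", "year")]
  o2 <- cl2$records[order(cl2$records$lon), c("lon", "lat", "year")]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("a year-1969 record is removed and 1970 retained", {
  occ <- occurrence_set("t", data.frame(
    lon = c(0, 0.1, 0.2), lat = c(43, 43, 43.2),
    year = c(1969, 1970, 2001), uncertainty_m = 100))
  cleaned <- clean_records(occ, rect)
  expect_equal(sort(cleaned$records$year), c(1970, 2001))
})

test_that("species with no surviving records is flagged unmodellable", {
  occ <- occurrence_set("t", data.frame(lon = 0, lat = 43, year = 1950,
                                        uncertainty_m = 10))
  cleaned <- clean_records(occ, rect)
  expect_true(cleaned$meta$unmodellable)
  expect_equal(nrow(cleaned$records), 0)
})

test_that("thinning enforces the minimum distance (exhaustive pair scan)", {
  occ <- toy_occurrences(200, spread = 1.2, seed = 7)
  th <- thin_spatially(occ, min_distance_cells = 1, cellsize_deg = 0.1,
                       seed = 3)
  r <- th$records
  thr <- 0.1 * pi / 180 * 6371008.8
  # brute-force all pairs
  for (i in seq_len(nrow(r) - 1)) {
    d <- haversine_m(r$lon[i], r$lat[i], r$lon[-(1:i)], r$lat[-(1:i)])
    expect_true(all(d >= thr))
  }
  # output is a subset of the input
  key <- function(d) paste(d$lon, d$lat)
  expect_true(all(key(r) %in% key(occ$records)))
  # already-sparse input passes through unchanged
  sparse <- occurrence_set("s", data.frame(
    lon = c(0, 1, 2), lat = c(43, 43, 43), year = 2000, uncertainty_m = 10))
  expect_equal(thin_spatially(sparse, 1, 0.1)$records[1:2],
               sparse$records[1:2])
  # two close records collapse to one
  pair <- occurrence_set("p", data.frame(
    lon = c(0, 0.0005), lat = c(43, 43), year = 2000, uncertainty_m = 10))
  expect_equal(nrow(thin_spatially(pair, 1, 0.1)$records), 1)
})

test_that("accessible area: hull, outlier rule and flight-period buffer", {
  # unit square of points, no outlier removal: hull is the square
  sq <- occurrence_set("sq", data.frame(
    lon = c(0, 1, 1, 0, 0.5), lat = c(43, 43, 44, 44, 43.5),
    year = 2000, uncertainty_m = 10))
  aa <- accessible_area(sq, flight_months = 10, outlier_pct = 0)
  expect_equal(aa$buffer_m, 1e5)                  # 10-month flyer -> 100 km
  expect_equal(nrow(aa$mcp), 4)                   # interior point not a vertex
  expect_setequal(paste(aa$mcp[, 1], aa$mcp[, 2]),
                  c("0 43", "1 43", "1 44", "0 44"))
  expect_equal(accessible_area(sq, 4, outlier_pct = 0)$buffer_m, 4e4)
  # every input point falls inside the buffered polygon
  expect_true(all(points_in_polygon(
    cbind(sq$records$lon, sq$records$lat), aa$polygon)))
  # buffered polygon contains the MCP
  expect_true(all(points_in_polygon(aa$mcp, aa$polygon)))
  # 1% outlier rule removes exactly ceiling(0.01 n) farthest points
  occ <- toy_occurrences(150, spread = 0.5, seed = 13)
  far <- occ$records[1:2, ]
  far$lon <- far$lon + 10                          # gross outliers
  occ2 <- occurrence_set("o", rbind(occ$records, far))
  aa2 <- accessible_area(occ2, 5, outlier_pct = 0.02)  # ceil(.02*152) = 4
  expect_true(all(aa2$mcp[, "lon"] < 5))           # outliers excluded
  expect_error(accessible_area(occurrence_set("x", data.frame(
    lon = 0:1, lat = c(43, 43), year = 2000, uncertainty_m = 1)), 5),
    "3 usable")
})

test_that("MCP equals an independent gift-wrapping hull oracle", {
  occ <- toy_occurrences(80, spread = 0.9, seed = 17)
  aa <- accessible_area(occ, 5, outlier_pct = 0)
  pts <- cbind(occ$records$lon, occ$records$lat)
  # gift wrapping (Jarvis march) oracle
  wrap <- function(p) {
    start <- which.min(p[, 1])
    hull <- start; cur <- start
    repeat {
      cand <- setdiff(seq_len(nrow(p)), cur)
      nxt <- cand[1]
      for (k in cand[-1]) {
        cr <- (p[nxt, 1] - p[cur, 1]) * (p[k, 2] - p[cur, 2]) -
          (p[nxt, 2] - p[cur, 2]) * (p[k, 1] - p[cur, 1])
        if (cr < 0) nxt <- k
      }
      if (nxt == start) break
      hull <- c(hull, nxt); cur <- nxt
    }
    p[hull, , drop = FALSE]
  }
  shoelace <- function(p) {
    n <- nrow(p); j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  expect_equal(shoelace(aa$mcp), shoelace(wrap(pts)), tolerance = 1e-12)
})

test_that("background sampling doubles presences uniformly outside them", {
  w <- small_world()
  occ <- toy_occurrences(60, lon0 = -3.5, lat0 = 41.5, spread = 0.6,
                         seed = 23)
  aa <- accessible_area(occ, 6, outlier_pct = 0)
  pc <- cell_index(w$template, occ$records$lon, occ$records$lat)
  bg <- sample_background(aa, 50, w$template, presence_cells = pc, seed = 2)
  expect_equal(nrow(bg), 100)                     # 2 x presences
  expect_true(all(!bg$cell %in% pc))
  expect_true(all(points_in_polygon(cbind(bg$lon, bg$lat), aa$polygon)))
  # determinism
  expect_identical(bg, sample_background(aa, 50, w$template, pc, seed = 2))
  # chi-square uniformity over eligible cells across many draws
  pts <- grid_points(w$template)
  eligible <- setdiff(which(points_in_polygon(pts, aa$polygon)), pc)
  counts <- numeric(length(eligible))
  for (r in 1:40) {
    b <- sample_background(aa, 50, w$template, pc, seed = 100 + r)
    counts <- counts + tabulate(match(b$cell, eligible), length(eligible))
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # tiny polygon falls back to replacement with a warning
  tiny <- occurrence_set("t", data.frame(
    lon = c(-3.45, -3.44, -3.45), lat = c(41.55, 41.55, 41.54),
    year = 2000, uncertainty_m = 1))
  ta <- accessible_area(tiny, 1, outlier_pct = 0, buffer_per_10months = 1.2e5)
  expect_warning(sample_background(ta, 500, w$template, seed = 1),
                 "replacement")
})

test_that("occurrence CSV and WKT round-trips preserve data", {
  occ <- toy_occurrences(12, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- read_occurrences(f)[["toy"]]
  expect_equal(back$records[c("lon", "lat", "year")],
               occ$records[c("lon", "lat", "year")])
  poly <- cbind(lon = c(0, 2, 1), lat = c(40, 40, 42))
  expect_equal(unname(wkt_to_polygon(polygon_to_wkt(poly))), unname(poly))
})
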