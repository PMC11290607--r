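#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with edge reflection; the workhorse behind
#' the spatial autocorrelation of all synthetic fields.
#' @param mat numeric matrix.
#' @param sigma kernel standard deviation in cells; 0 returns `mat`.
#' @return smoothed matrix of the same dimension.
#' @keywords internal
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smat <- function(n) {
    S <- matrix(0, n, n)
    for (off in -r:r) {
      j <- seq_len(n) + off
      j <- ifelse(j < 1L, 2L - j, ifelse(j > n, 2L * n - j, j)) # reflect
      S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + k[off + r + 1L]
    }
    S
  }
  smat(nrow(mat)) %*% mat %*% t(smat(ncol(mat)))
}

#' Future climate scenario presets
#'
#' Named additive temperature / multiplicative precipitation presets. The
#' names follow the global circulation models commonly used for mid-century
#' projections; the numbers are package presets spanning a moderate-emission
#' span of warming, not downloaded model output.
#' @return named list; each element has `dtemp` (degrees C added to every
#'   monthly temperature) and `pfac` (factor multiplying every monthly
#'   precipitation) for the 2050 horizon. The 2070 horizon scales `dtemp` by
#'   1.4 and squares the precipitation anomaly.
#' @export
scenario_presets <- function() {
  list(
    "BCC-CSM1-1"     = list(dtemp = 2.0, pfac = 0.95),
    "MIROC-ESM-CHEM" = list(dtemp = 2.8, pfac = 0.90),
    "NorESM1-M"      = list(dtemp = 1.8, pfac = 1.00))
}

#' Generate a synthetic world
#'
#' Builds the full environmental input set of the pipeline: 12 monthly
#' minimum/maximum temperature and precipitation fields, elevation and a
#' water-body mask, all spatially autocorrelated (Gaussian-filtered noise)
#' and superimposed on a latitudinal temperature gradient with an
#' elevational lapse, plus named future scenario offsets. Regeneration with
#' the same seed is bit-identical.
#'
#' @param nrow,ncol grid dimensions (at least 10 x 10).
#' @param cellsize cell size in degrees (~0.1 deg is roughly the 10-km
#'   working resolution of the pipeline).
#' @param origin lower-left corner `c(lon, lat)` in degrees.
#' @param seed integer RNG seed.
#' @param t_south mean annual temperature at the southern edge at sea level,
#'   degrees C.
#' @param lat_gradient cooling per degree of latitude northwards, degrees C.
#' @param seasonal_amp amplitude of the annual temperature cycle, degrees C
#'   (July warmest).
#' @param lapse_rate temperature decrease per km of elevation, degrees C.
#' @param elev_max approximate maximum elevation, m.
#' @param prec_base mean monthly precipitation, mm.
#' @param prec_seasonal amplitude of the winter-wet precipitation cycle, mm.
#' @param noise_sd standard deviation of the (pre-smoothing) climate noise.
#' @param smooth_sigma Gaussian kernel width in cells.
#' @param water_frac fraction of cells flagged as water bodies.
#' @param scenarios named list of scenario presets; see [scenario_presets()].
#' @return object of class `synthetic_world`.
#' @export
generate_world <- function(nrow = 60, ncol = 60, cellsize = 0.1,
                           origin = c(-5, 40), seed = 1,
                           t_south = 16, lat_gradient = 1.5,
                           seasonal_amp = 8, lapse_rate = 6.5,
                           elev_max = 1200, prec_base = 60,
                           prec_seasonal = 25, noise_sd = 2,
                           smooth_sigma = 3, water_frac = 0.15,
                           scenarios = scenario_presets()) {
  if (nrow < 10 || ncol < 10) stop("grid must be at least 10 x 10")
  if (cellsize <= 0) stop("cellsize must be positive")
  set.seed(seed)
  template <- raster_grid(matrix(NA_real_, nrow, ncol),
                          origin[1], origin[2], cellsize, name = "template")
  lat <- grid_coords(template)$lat                     # north -> south
  latmat <- matrix(lat, nrow, ncol)                    # per-row latitude

  elevation <- gauss_smooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                            smooth_sigma)
  elevation <- (elevation - min(elevation)) / diff(range(elevation))
  elevation <- elev_max * elevation

  water_field <- gauss_smooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                              smooth_sigma)
  water_mask <- water_field >= stats::quantile(water_field, 1 - water_frac)

  base_t <- t_south - lat_gradient * (latmat - origin[2]) -
    lapse_rate * elevation / 1000
  tnoise <- gauss_smooth(matrix(stats::rnorm(nrow * ncol, sd = noise_sd),
                                nrow, ncol), smooth_sigma)
  drange <- pmax(8 + gauss_smooth(
    matrix(stats::rnorm(nrow * ncol, sd = noise_sd), nrow, ncol),
    smooth_sigma), 1)

  tmin <- tmax <- prec <- vector("list", 12)
  for (m in 1:12) {
    cyc <- seasonal_amp * cos(2 * pi * (m - 7) / 12)   # peak in July
    tmean_m <- base_t + cyc + tnoise
    tmin[[m]] <- tmean_m - drange / 2
    tmax[[m]] <- tmean_m + drange / 2
    pcyc <- prec_seasonal * cos(2 * pi * (m - 1) / 12) # winter-wet
    pn <- gauss_smooth(matrix(stats::rnorm(nrow * ncol, sd = 6 * noise_sd),
                              nrow, ncol), smooth_sigma)
    prec[[m]] <- pmax(prec_base + pcyc + pn, 0)
  }

  structure(
    list(template = template, tmin = tmin, tmax = tmax, prec = prec,
         elevation = elevation, water_mask = water_mask,
         scenarios = scenarios, seed = seed,
         params = list(t_south = t_south, lat_gradient = lat_gradient,
                       seasonal_amp = seasonal_amp, lapse_rate = lapse_rate,
                       smooth_sigma = smooth_sigma)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d x %d cells at %.3g deg, seed %d\n",
              nrow(x$template$values), ncol(x$template$values),
              x$template$cellsize, x$seed))
  cat("  scenarios:", paste(names(x$scenarios), collapse = ", "), "\n")
  invisible(x)
}

#' Monthly climate of a world under a scenario
#'
#' Future temperature fields are current plus the scenario's additive offset;
#' future precipitation is current times its multiplicative factor. Horizon
#' "2070" amplifies the 2050 anomaly (offset x 1.4; factor squared).
#' Elevation and water bodies are held constant.
#' @param world a `synthetic_world`.
#' @param scenario `NULL`/"current" or a name in `world$scenarios`.
#' @param period "current", "2050" or "2070".
#' @return list with `tmin`, `tmax`, `prec` (12 matrices each).
#' @export
world_climate <- function(world, scenario = NULL, period = "current") {
  if (is.null(scenario) || identical(scenario, "current") ||
      identical(period, "current"))
    return(list(tmin = world$tmin, tmax = world$tmax, prec = world$prec))
  sc <- world$scenarios[[scenario]]
  if (is.null(sc)) stop("unknown scenario: ", scenario)
  amp <- switch(period, "2050" = 1, "2070" = 1.4,
                stop("unknown period: ", period))
  dtemp <- sc$dtemp * amp
  pfac <- sc$pfac^amp
  list(tmin = lapply(world$tmin, `+`, dtemp),
       tmax = lapply(world$tmax, `+`, dtemp),
       prec = lapply(world$prec, `*`, pfac))
}

#' Predictor stack of a synthetic world
#'
#' Derives the seven working predictors (water bodies, elevation, Emberger's
#' pluviometric quotient, bio7, bio8, bio10, bio15) from the world's monthly
#' climate under a scenario/period.
#' @inheritParams world_climate
#' @param full include the whole candidate bioclim set (for the
#'   multicollinearity filter) instead of only the seven working predictors.
#' @return a `predictor_stack`.
#' @export
world_predictors <- function(world, scenario = NULL, period = "current",
                             full = FALSE) {
  cl <- world_climate(world, scenario, period)
  bc <- bioclim(cl$tmin, cl$tmax, cl$prec)
  tpl <- world$template
  as_g <- function(v, nm) raster_grid(v, tpl$xll, tpl$yll, tpl$cellsize, nm)
  eq <- emberger_q(as_g(bc$bio5, "bio5"), as_g(bc$bio6, "bio6"),
                   as_g(bc$bio12, "bio12"))
  layers <- c(
    list(water = as_g(world$water_mask + 0, "water"),
         elevation = as_g(world$elevation, "elevation"),
         embergerQ = eq),
    if (full) lapply(stats::setNames(nm = setdiff(names(bc),
                                                  c("bio7", "bio8",
                                                    "bio10", "bio15"))),
               function(nm) as_g(bc[[nm]], nm)),
    list(bio7 = as_g(bc$bio7, "bio7"), bio8 = as_g(bc$bio8, "bio8"),
         bio10 = as_g(bc$bio10, "bio10"), bio15 = as_g(bc$bio15, "bio15")))
  predictor_stack(layers,
                  scenario = if (is.null(scenario)) "current" else scenario,
                  period = period)
}

#' Define a species with known logistic suitability
#'
#' @param species_id character id.
#' @param coefficients named numeric vector of logit-scale weights; names are
#'   predictor layer names, optionally suffixed `"^2"` for a squared term
#'   (e.g. `c("(Intercept)" = 2, bio10 = 1.2, "bio10^2" = -0.03)`).
#' @param n_presences number of presence records to draw (>= 1).
#' @param flight_months length of the adult flight period, months (1-12).
#' @param lentic,lotic habitat flags; at least one must be `TRUE`.
#' @return object of class `true_species`.
#' @export
true_species <- function(species_id, coefficients, n_presences,
                         flight_months, lentic = TRUE, lotic = FALSE) {
  if (n_presences < 1) stop("n_presences must be >= 1")
  if (!lentic && !lotic) stop("at least one habitat flag must be set")
  if (flight_months < 1 || flight_months > 12)
    stop("flight_months must lie in 1..12")
  structure(list(species_id = species_id, coefficients = coefficients,
                 n_presences = n_presences, flight_months = flight_months,
                 lentic = lentic, lotic = lotic),
            class = "true_species")
}

#' True suitability of a species on a predictor stack
#'
#' Evaluates the species' logistic suitability function cell by cell.
#' @param sp a `true_species`.
#' @param stack a `predictor_stack` containing every predictor the species'
#'   coefficients name.
#' @return a `raster_grid` of suitabilities in (0, 1).
#' @export
true_suitability <- function(sp, stack) {
  vals <- stack_values(stack)
  eta <- rep(0, nrow(vals))
  for (nm in names(sp$coefficients)) {
    b <- sp$coefficients[[nm]]
    if (nm == "(Intercept)") { eta <- eta + b; next }
    base <- sub("\\^2$", "", nm)
    if (!base %in% names(vals))
      stop("predictor '", base, "' missing from stack")
    x <- vals[[base]]
    eta <- eta + b * if (grepl("\\^2$", nm)) x^2 else x
  }
  g <- stack$grid
  raster_grid(matrix(stats::plogis(eta), nrow(g$values), ncol(g$values)),
              g$xll, g$yll, g$cellsize,
              name = paste0("true_suit_", sp$species_id))
}

#' Generate a pool of synthetic species
#'
#' Each species gets a quadratic thermal niche on the mean temperature of the
#' warmest quarter (bio10) — an optimum drawn inside the world's central
#' temperature span with a tolerance of a few degrees — plus a mild aridity
#' (Emberger quotient) preference, random habitat flags and a flight period.
#' Because every niche tracks an isotherm, warming displaces all true ranges
#' polewards, which is the known ground truth the downstream stages must
#' recover.
#' @param world a `synthetic_world`.
#' @param n_species number of species.
#' @param seed RNG seed.
#' @param n_presences integer range to draw per-species record counts from.
#' @return list of `true_species`.
#' @export
make_species_pool <- function(world, n_species, seed = 1,
                              n_presences = c(150, 300)) {
  set.seed(seed)
  stk <- world_predictors(world)
  b10 <- as.vector(stk$layers$bio10$values)
  eq <- as.vector(stk$layers$embergerQ$values)
  qs <- stats::quantile(b10, c(0.25, 0.85))
  steep <- 4                       # near-deterministic occupancy at band edge
  lapply(seq_len(n_species), function(i) {
    opt <- stats::runif(1, qs[1], qs[2])
    tol <- stats::runif(1, 0.8, 1.6)
    bq <- stats::rnorm(1, 0, 0.8) / max(stats::sd(eq), 1e-9)
    co <- c("(Intercept)" = steep * (1 - opt^2 / tol^2) - bq * mean(eq),
            bio10 = steep * 2 * opt / tol^2,
            "bio10^2" = -steep / tol^2,
            embergerQ = bq)
    lentic <- stats::runif(1) < 0.6
    lotic <- stats::runif(1) < 0.6 || !lentic
    true_species(sprintf("sp%02d", i), co,
                 n_presences = sample(n_presences[1]:n_presences[2], 1),
                 flight_months = sample(2:10, 1),
                 lentic = lentic, lotic = lotic)
  })
}

#' Sample occurrence records for a species
#'
#' Presence cells are drawn without replacement with probability proportional
#' to the species' true suitability; coordinates are jittered uniformly
#' within the cell. A configurable fraction of "dirty" records (pre-1970
#' year, exact duplicate, excessive coordinate uncertainty, outside the study
#' area) is appended to exercise the cleaning stage; their row indices are
#' recorded in the `dirty` column.
#' @param world a `synthetic_world`.
#' @param sp a `true_species`.
#' @param seed RNG seed.
#' @param dirty_fraction fraction (of `n_presences`) of corrupted records to
#'   append.
#' @param uniform if `TRUE`, ignore suitability and sample cells uniformly
#'   (used for calibration checks).
#' @return an `occurrence_set` with
#'   `n_presences + round(dirty_fraction * n_presences)` records.
#' @export
sample_occurrences <- function(world, sp, seed = 1, dirty_fraction = 0,
                               uniform = FALSE) {
  set.seed(seed)
  stk <- world_predictors(world)
  suit <- as.vector(true_suitability(sp, stk)$values)
  ncell <- length(suit)
  if (sp$n_presences > ncell)
    stop("n_presences exceeds the number of grid cells")
  prob <- if (uniform) rep(1, ncell) else suit
  cells <- sample.int(ncell, sp$n_presences, replace = FALSE, prob = prob)
  pts <- grid_points(world$template)[cells, , drop = FALSE]
  cs <- world$template$cellsize
  rec <- data.frame(
    lon = pts[, "lon"] + stats::runif(length(cells), -cs / 2, cs / 2),
    lat = pts[, "lat"] + stats::runif(length(cells), -cs / 2, cs / 2),
    year = sample(1975:2015, length(cells), replace = TRUE),
    uncertainty_m = stats::runif(length(cells), 50, 5000),
    dirty = NA_character_)
  n_dirty <- round(dirty_fraction * sp$n_presences)
  if (n_dirty > 0) {
    kinds <- rep(c("old_year", "duplicate", "uncertain", "outside"),
                 length.out = n_dirty)
    src <- sample.int(nrow(rec), n_dirty, replace = TRUE)
    bad <- rec[src, ]
    bad$dirty <- kinds
    # every non-duplicate kind gets fresh coordinates so that exactly one
    # cleaning rule fires per injected record
    fresh <- kinds != "duplicate"
    ext_lon <- world$template$xll +
      c(0, ncol(world$template$values) * cs)
    ext_lat <- world$template$yll +
      c(0, nrow(world$template$values) * cs)
    bad$lon[fresh] <- stats::runif(sum(fresh), ext_lon[1], ext_lon[2])
    bad$lat[fresh] <- stats::runif(sum(fresh), ext_lat[1], ext_lat[2])
    old <- kinds == "old_year"
    bad$year[old] <- sample(1900:1969, sum(old), replace = TRUE)
    unc <- kinds == "uncertain"
    bad$uncertainty_m[unc] <- stats::runif(sum(unc), 2e4, 5e4)
    out <- kinds == "outside"
    bad$lon[out] <- ext_lon[1] - stats::runif(sum(out), 2, 10)
    rec <- rbind(rec, bad)
  }
  rownames(rec) <- NULL
  occurrence_set(sp$species_id, rec)
}

#' Simulate a phylogeny with traits of known signal
#'
#' A pure-birth (Yule) tree with `n_tips` tips; continuous traits are then
#' simulated under Brownian motion on the lambda-transformed tree: the
#' off-diagonal entries of the Brownian covariance are scaled by
#' `lambda_signal`, the diagonal is untouched, so `lambda_signal = 1` is
#' plain Brownian motion and `lambda_signal = 0` gives phylogeny-free
#' independent tips.
#' @param n_tips number of tips (>= 4).
#' @param birth_rate speciation rate of the Yule process.
#' @param lambda_signal Pagel's lambda used for simulation, in [0, 1].
#' @param seed RNG seed.
#' @param n_traits number of independent trait columns.
#' @param rate Brownian variance per unit branch length.
#' @param tip_prefix label prefix, matched to species ids downstream.
#' @return object of class `simulated_phylogeny` with elements `tree`
#'   (an `ape::phylo`), `traits` (tips x traits matrix),
#'   `generating_lambda`, `brownian_rate`.
#' @export
simulate_phylogeny_and_traits <- function(n_tips, birth_rate = 1,
                                          lambda_signal = 1, seed = 1,
                                          n_traits = 1, rate = 1,
                                          tip_prefix = "sp") {
  if (n_tips < 4) stop("need at least 4 tips")
  if (lambda_signal < 0 || lambda_signal > 1)
    stop("lambda_signal must lie in [0, 1]")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("%s%02d", tip_prefix, seq_len(n_tips))
  V <- rate * lambda_cov(ape::vcv(tree), lambda_signal)
  L <- chol(V + diag(1e-10, n_tips))
  Z <- matrix(stats::rnorm(n_tips * n_traits), n_tips, n_traits)
  traits <- crossprod(L, Z)
  dimnames(traits) <- list(tree$tip.label,
                           paste0("trait", seq_len(n_traits)))
  structure(list(tree = tree, traits = traits,
                 generating_lambda = lambda_signal, brownian_rate = rate),
            class = "simulated_phylogeny")
}

#' Assemble a synthetic trait table
#'
#' Maps Brownian trait columns onto the measurement scales of the functional
#' trait schema (body, abdomen and wing lengths in mm, abdomen colour in RGB)
#' and joins the habitat flags and flight period of the species pool.
#' @param sim a `simulated_phylogeny` with at least 6 trait columns.
#' @param pool species pool from [make_species_pool()]; ids must match tips.
#' @return data.frame in the schema expected by [gower_grouped()].
#' @export
synth_trait_table <- function(sim, pool) {
  ids <- vapply(pool, `[[`, "", "species_id")
  if (!setequal(ids, rownames(sim$traits)))
    stop("species pool and simulated tips do not match")
  tr <- sim$traits[ids, , drop = FALSE]
  if (ncol(tr) < 6) stop("need at least 6 simulated trait columns")
  rescale <- function(x, lo, hi) {
    r <- range(x)
    if (diff(r) == 0) return(rep((lo + hi) / 2, length(x)))
    lo + (x - r[1]) / diff(r) * (hi - lo)
  }
  body <- rescale(tr[, 1], 25, 85)
  data.frame(
    species = ids,
    body_size = body,
    abdomen_length = body * 0.7 + rescale(tr[, 2], -4, 4),
    wing_length = body * 0.55 + rescale(tr[, 3], -5, 5),
    col_r = round(rescale(tr[, 4], 0, 255)),
    col_g = round(rescale(tr[, 5], 0, 255)),
    col_b = round(rescale(tr[, 6], 0, 255)),
    lentic = vapply(pool, `[[`, TRUE, "lentic"),
    lotic = vapply(pool, `[[`, TRUE, "lotic"),
    flight_months = vapply(pool, function(p) as.numeric(p$flight_months), 1),
    row.names = NULL)
}
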