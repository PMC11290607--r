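#' Bioclimatic variables from monthly climate
#'
#' Computes the subset of the classical bioclimatic variables the pipeline
#' uses from 12 monthly minimum temperature, maximum temperature and
#' precipitation fields. Per cell: monthly mean temperature is
#' `(tmin + tmax) / 2`; quarters are the 12 wrap-around 3-month windows;
#' the wettest quarter maximises the precipitation sum and the warmest
#' quarter the mean temperature (ties resolved to the earliest window).
#'
#' \itemize{
#'   \item bio1: annual mean temperature
#'   \item bio4: temperature seasonality (100 x SD of monthly means)
#'   \item bio5: max temperature of warmest month (max monthly tmax)
#'   \item bio6: min temperature of coldest month (min monthly tmin)
#'   \item bio7: temperature annual range (bio5 - bio6)
#'   \item bio8: mean temperature of wettest quarter
#'   \item bio10: mean temperature of warmest quarter
#'   \item bio12: annual precipitation
#'   \item bio15: precipitation seasonality,
#'     `100 * sd(monthly prec) / (1 + bio12/12)` (the +1 guards arid cells)
#' }
#'
#' @param tmin,tmax,prec lists of 12 numeric matrices (deg C, deg C, mm).
#' @return named list of matrices.
#' @export
bioclim <- function(tmin, tmax, prec) {
  if (length(tmin) != 12 || length(tmax) != 12 || length(prec) != 12)
    stop("need 12 monthly fields of each input")
  dm <- dim(tmin[[1]])
  arr <- function(l) array(unlist(l), c(dm, 12))
  tn <- arr(tmin); tx <- arr(tmax); pr <- arr(prec)
  if (any(tx < tn)) stop("tmax < tmin in some cell/month")
  tm <- (tn + tx) / 2
  ncell <- prod(dm)
  dim(tn) <- dim(tx) <- dim(pr) <- dim(tm) <- c(ncell, 12)

  windows <- lapply(1:12, function(m) ((m - 2):m) %% 12 + 1)  # centred on m
  qprec <- matrix(vapply(windows, function(w)
    rowSums(pr[, w, drop = FALSE]), numeric(ncell)), ncell, 12)
  qtemp <- matrix(vapply(windows, function(w)
    rowMeans(tm[, w, drop = FALSE]), numeric(ncell)), ncell, 12)
  wet <- max.col(qprec, ties.method = "first")
  warm <- max.col(qtemp, ties.method = "first")

  sd_row <- function(x) sqrt(rowSums((x - rowMeans(x))^2) / (ncol(x) - 1))
  bio12 <- rowSums(pr)
  out <- list(
    bio1 = rowMeans(tm),
    bio4 = 100 * sd_row(tm),
    bio5 = apply(tx, 1, max),
    bio6 = apply(tn, 1, min),
    bio8 = qtemp[cbind(seq_len(ncell), wet)],
    bio10 = qtemp[cbind(seq_len(ncell), warm)],
    bio12 = bio12,
    bio15 = 100 * sd_row(pr) / (1 + bio12 / 12))
  out$bio7 <- out$bio5 - out$bio6
  out <- out[c("bio1", "bio4", "bio5", "bio6", "bio7", "bio8",
               "bio10", "bio12", "bio15")]
  lapply(out, function(v) { dim(v) <- dm; v })
}

#' Emberger's pluviometric quotient
#'
#' `Q = 2000 P / ((Tmax + Tmin)(Tmax - Tmin))` with P the annual
#' precipitation (bio12, mm) and Tmax/Tmin the extreme monthly temperatures
#' (bio5/bio6) expressed in kelvin. Cells with `Tmax = Tmin` (zero
#' denominator) are masked and their count reported in a message.
#'
#' @param bio5,bio6,bio12 aligned `raster_grid` layers.
#' @return a `raster_grid` named `embergerQ`.
#' @export
emberger_q <- function(bio5, bio6, bio12) {
  check_aligned(bio5, bio6, bio12)
  tx <- bio5$values + 273.15
  tn <- bio6$values + 273.15
  den <- (tx + tn) * (tx - tn)
  q <- 2000 * bio12$values / den
  bad <- den == 0
  if (any(bad, na.rm = TRUE)) {
    q[bad] <- NA_real_
    message(sum(bad, na.rm = TRUE),
            " cell(s) masked in embergerQ (Tmax = Tmin)")
  }
  raster_grid(q, bio5$xll, bio5$yll, bio5$cellsize, name = "embergerQ")
}

#' Filter collinear predictors
#'
#' Two-step multicollinearity filter on a sample matrix of cell values.
#' Step 1: hierarchical clustering (average linkage) on the distance
#' `1 - |Pearson r|`, cut at `1 - r_max`; one representative kept per
#' cluster — by default the member with the lowest mean absolute correlation
#' against all other variables. Step 2: iteratively drop the variable with
#' the highest variance inflation factor until all VIF are at or below
#' `vif_max`. Keep-list variables are forced through both steps, so a named
#' predictor set can be imposed while the remaining candidates are still
#' filtered against it. Constant variables are excluded up front with a
#' warning (their correlation is undefined).
#'
#' @param samples data.frame/matrix of predictor samples (rows = cells).
#' @param r_max maximum tolerated absolute pairwise correlation.
#' @param vif_max maximum tolerated variance inflation factor.
#' @param keep character vector of variable names retained unconditionally
#'   (forced through the cluster step and never dropped by the VIF step).
#' @return list with `retained` (names), `log` (data.frame of decisions)
#'   and `vif` (named vector of final VIFs).
#' @export
filter_collinear <- function(samples, r_max = 0.5, vif_max = 3,
                             keep = character(0)) {
  x <- as.data.frame(samples)
  if (ncol(x) < 2) stop("need at least 2 variables")
  log <- data.frame(variable = character(0), action = character(0),
                    detail = character(0))
  note <- function(v, a, d) rbind(log, data.frame(variable = v, action = a,
                                                  detail = d))
  const <- vapply(x, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    warning("constant variable(s) excluded: ",
            paste(names(x)[const], collapse = ", "))
    for (v in names(x)[const]) log <- note(v, "excluded", "constant")
    x <- x[!const]
  }
  cm <- abs(stats::cor(x))
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  cl <- stats::cutree(hc, h = 1 - r_max)
  retained <- character(0)
  for (k in unique(cl)) {
    members <- names(cl)[cl == k]
    forced <- intersect(keep, members)
    keep_here <- if (length(forced)) forced else {
      meanr <- vapply(members, function(v)
        mean(cm[v, setdiff(colnames(cm), v)]), 1)
      members[which.min(meanr)]
    }
    retained <- c(retained, keep_here)
    for (v in setdiff(members, keep_here))
      log <- note(v, "dropped_cluster",
                  sprintf("|r| cluster represented by %s",
                          paste(keep_here, collapse = "/")))
  }
  # step 2: iterative VIF
  vifs <- function(vars) {
    r <- stats::cor(x[vars])
    ri <- tryCatch(solve(r), error = function(e) NULL)
    if (is.null(ri)) stats::setNames(rep(Inf, length(vars)), vars)
    else stats::setNames(diag(ri), vars)
  }
  repeat {
    if (length(retained) < 2) break
    v <- vifs(retained)
    if (max(v) <= vif_max) break
    cand <- setdiff(names(v)[order(-v)], keep)   # keep-list is never dropped
    if (!length(cand)) break
    drop_v <- cand[1]
    log <- note(drop_v, "dropped_vif", sprintf("VIF = %.3g", v[drop_v]))
    retained <- setdiff(retained, drop_v)
  }
  final_vif <- if (length(retained) >= 2) vifs(retained) else
    stats::setNames(rep(1, length(retained)), retained)
  list(retained = retained, log = log, vif = final_vif)
}
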