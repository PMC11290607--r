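#' Assemble a presence-background modelling dataset
#'
#' Joins presence and background predictor rows, labels them 1/0 and assigns
#' a stratified 75/25 train/test split (seeded). The background is expected
#' to double the presences.
#'
#' @param presence_env data.frame of predictor values at presence cells.
#' @param background_env data.frame of predictor values at background cells.
#' @param species_id species identifier.
#' @param seed RNG seed for the split.
#' @param train_frac training fraction (default 0.75).
#' @return object of class `sdm_data` with elements `env`, `label`,
#'   `train` (logical), `species_id`, `predictors`.
#' @export
make_sdm_data <- function(presence_env, background_env, species_id,
                          seed = 1, train_frac = 0.75) {
  if (!identical(names(presence_env), names(background_env)))
    stop("presence and background predictor columns differ")
  env <- rbind(presence_env, background_env)
  label <- c(rep(1L, nrow(presence_env)), rep(0L, nrow(background_env)))
  ok <- stats::complete.cases(env)
  env <- env[ok, , drop = FALSE]; label <- label[ok]
  set.seed(seed)
  train <- logical(length(label))
  for (cl in c(0L, 1L)) {
    idx <- which(label == cl)
    train[sample(idx, round(train_frac * length(idx)))] <- TRUE
  }
  structure(list(env = env, label = label, train = train,
                 species_id = species_id, predictors = names(env)),
            class = "sdm_data")
}

# ---- learners ---------------------------------------------------------------

maxent_features <- function(env, center = NULL, scale = NULL) {
  x <- as.matrix(env)
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  feats <- cbind(z, z^2)
  colnames(feats) <- c(colnames(z), paste0(colnames(z), "^2"))
  if (ncol(z) >= 2) {
    cmb <- utils::combn(ncol(z), 2)
    prod <- z[, cmb[1, ], drop = FALSE] * z[, cmb[2, ], drop = FALSE]
    colnames(prod) <- paste(colnames(z)[cmb[1, ]], colnames(z)[cmb[2, ]],
                            sep = ":")
    feats <- cbind(feats, prod)
  }
  list(x = feats, center = center, scale = scale)
}

fit_one_learner <- function(type, env, label, seed) {
  set.seed(seed)
  if (type == "additive_smooth") {
    terms <- vapply(names(env), function(v) {
      k <- min(5L, length(unique(env[[v]])) - 1L)
      if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v
    }, "")
    dat <- cbind(env, .y = label)
    fit <- mgcv::gam(stats::as.formula(
      paste(".y ~", paste(terms, collapse = " + "))),
      family = stats::binomial(), data = dat, method = "REML")
    structure(list(type = type, fit = fit, predictors = names(env)),
              class = "fs_learner")
  } else if (type == "maxent_style") {
    mf <- maxent_features(env)
    foldid <- sample(rep_len(1:4, length(label)))
    cv <- glmnet::cv.glmnet(mf$x, label, family = "binomial", alpha = 1,
                            foldid = foldid, nlambda = 50)
    structure(list(type = type, fit = cv$glmnet.fit, lambda = cv$lambda.min,
                   center = mf$center, scale = mf$scale,
                   predictors = names(env)),
              class = "fs_learner")
  } else if (type == "boosted_trees") {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(env), label = label)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.01, max_depth = 3,
                    subsample = 0.7, colsample_bytree = 0.8, nthread = 1),
      data = dtrain, nrounds = 1000, verbose = 0)
    structure(list(type = type, fit = fit, predictors = names(env)),
              class = "fs_learner")
  } else stop("unknown learner type: ", type)
}

#' Predict habitat suitability from a fitted learner
#'
#' @param learner an `fs_learner` or `fs_ensemble`.
#' @param newdata data.frame containing the learner's predictors.
#' @return numeric suitabilities in [0, 1].
#' @export
predict_suitability <- function(learner, newdata) {
  newdata <- newdata[learner$predictors]
  if (inherits(learner, "fs_ensemble")) {
    p <- vapply(learner$members, predict_suitability, numeric(nrow(newdata)),
                newdata = newdata)
    return(rowMeans(p))
  }
  switch(learner$type,
    additive_smooth = as.numeric(
      mgcv::predict.gam(learner$fit, newdata, type = "response")),
    maxent_style = {
      mf <- maxent_features(newdata, learner$center, learner$scale)
      as.numeric(stats::predict(learner$fit, newx = mf$x,
                                s = learner$lambda, type = "response"))
    },
    boosted_trees = as.numeric(
      stats::predict(learner$fit, as.matrix(newdata))))
}

#' Fit the three suitability learners and their ensemble
#'
#' Fits a generalised additive model with smooth terms, a regularized
#' log-linear presence-background classifier with linear, quadratic and
#' product features (maximum-entropy style) and stochastic gradient-boosted
#' trees on the training split, plus their unweighted-mean ensemble, and
#' scores each candidate on the held-out test split with AUC and the
#' continuous Boyce index. Predictors that are constant on the training
#' split are dropped for this species with a message.
#'
#' @param data an `sdm_data`.
#' @param seed RNG seed governing all stochastic elements.
#' @param min_presences minimum presences required to model the species.
#' @return object of class `sdm_model_set`: `learners` (named list including
#'   `ensemble`), `evaluation` (data.frame learner/auc/boyce), `best_learner`
#'   (highest test AUC).
#' @export
fit_learners <- function(data, seed = 1, min_presences = 30) {
  n_pres <- sum(data$label == 1L)
  if (n_pres < min_presences)
    stop(sprintf("only %d presences (< %d); species not modellable",
                 n_pres, min_presences))
  tr <- data$train
  env_tr <- data$env[tr, , drop = FALSE]
  const <- vapply(env_tr, function(v) length(unique(v)) < 2, TRUE)
  if (any(const)) {
    message("dropping constant predictor(s) for ", data$species_id, ": ",
            paste(names(env_tr)[const], collapse = ", "))
    data$env <- data$env[!const]
    env_tr <- env_tr[!const]
    data$predictors <- names(data$env)
  }
  types <- c("additive_smooth", "maxent_style", "boosted_trees")
  learners <- lapply(seq_along(types), function(i)
    fit_one_learner(types[i], env_tr, data$label[tr], seed + i))
  names(learners) <- types
  learners$ensemble <- structure(
    list(members = learners[types], predictors = data$predictors),
    class = c("fs_ensemble", "fs_learner"))
  env_te <- data$env[!tr, , drop = FALSE]
  lab_te <- data$label[!tr]
  ev <- do.call(rbind, lapply(names(learners), function(nm) {
    p <- predict_suitability(learners[[nm]], env_te)
    data.frame(learner = nm,
               auc = auc(p, lab_te),
               boyce = tryCatch(
                 boyce_index(p[lab_te == 1], p[lab_te == 0]),
                 error = function(e) NA_real_))
  }))
  best <- ev$learner[which.max(ev$auc)]
  structure(list(learners = learners, evaluation = ev, best_learner = best,
                 species_id = data$species_id),
            class = "sdm_model_set")
}

#' @export
print.sdm_model_set <- function(x, ...) {
  cat(sprintf("sdm_model_set '%s' (best: %s)\n", x$species_id,
              x$best_learner))
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly drawn presence outscores
#' a randomly drawn background point, ties counting one half.
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Continuous Boyce index
#'
#' Moving windows slide across the suitability range; per window the fraction
#' of presences inside (P) is divided by the fraction of background inside
#' (E), and the index is the Spearman rank correlation between P/E and the
#' window centre. Windows with `E = 0` are dropped. Ranges from -1 to 1;
#' values above zero indicate predictions consistent with the presence data.
#'
#' @param pres suitabilities at test presences.
#' @param bg suitabilities at background points.
#' @param n_windows number of window centres (default 101).
#' @param window_width width of each window; default one tenth of the
#'   combined suitability range.
#' @return Boyce index in [-1, 1].
#' @export
boyce_index <- function(pres, bg, n_windows = 101, window_width = NULL) {
  if (!length(pres) || !length(bg)) stop("both vectors must be non-empty")
  rng <- range(c(pres, bg))
  if (diff(rng) == 0) stop("degenerate suitability range")
  if (is.null(window_width)) window_width <- diff(rng) / 10
  centers <- seq(rng[1], rng[2], length.out = n_windows)
  h <- window_width / 2
  P <- vapply(centers, function(cc)
    mean(pres >= cc - h & pres <= cc + h), 1)
  E <- vapply(centers, function(cc)
    mean(bg >= cc - h & bg <= cc + h), 1)
  ok <- E > 0
  if (sum(ok) < 3) stop("fewer than 3 usable windows")
  stats::cor(P[ok] / E[ok], centers[ok], method = "spearman")
}

#' Threshold maximising sensitivity plus specificity
#'
#' Scans every observed score as a candidate threshold and returns the one
#' maximising sensitivity (fraction of presences at or above) plus
#' specificity (fraction of background below); ties resolved to the smallest
#' threshold.
#' @param pres scores at presences.
#' @param bg scores at background points.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
select_threshold <- function(pres, bg) {
  if (!length(pres) || !length(bg)) stop("both classes required")
  cand <- sort(unique(c(pres, bg)))
  sp <- sort(pres); sb <- sort(bg)
  sens <- 1 - (findInterval(cand, sp, left.open = TRUE) / length(sp))
  spec <- findInterval(cand, sb, left.open = TRUE) / length(sb)
  i <- which.max(sens + spec)           # which.max takes the first maximum
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i])
}

#' Apply quality gates and refit the best learner on all occurrences
#'
#' Flags the species as low quality when the best test AUC falls below
#' `auc_min` or its Boyce index below `boyce_min`; the best-performing
#' method (the ensemble is a candidate) is then refitted on 100% of the
#' occurrences and the binarisation threshold selected on the full-data
#' scores.
#'
#' @param data the `sdm_data` used for fitting.
#' @param model_set an `sdm_model_set`.
#' @param auc_min,boyce_min quality gates.
#' @param seed RNG seed for the refit.
#' @return object of class `sdm_final`: `learner` (refitted), `threshold`,
#'   `flagged`, `best_learner`, `evaluation`.
#' @export
evaluate_and_finalize <- function(data, model_set, auc_min = 0.7,
                                  boyce_min = 0.4, seed = 1) {
  ev <- model_set$evaluation
  best <- model_set$best_learner
  row <- ev[ev$learner == best, ]
  flagged <- row$auc < auc_min || is.na(row$boyce) || row$boyce < boyce_min
  env <- data$env[model_set$learners[[best]]$predictors]
  learner <- if (best == "ensemble") {
    types <- c("additive_smooth", "maxent_style", "boosted_trees")
    members <- lapply(seq_along(types), function(i)
      fit_one_learner(types[i], env, data$label, seed + i))
    names(members) <- types
    structure(list(members = members, predictors = names(env)),
              class = c("fs_ensemble", "fs_learner"))
  } else {
    fit_one_learner(best, env, data$label, seed)
  }
  p <- predict_suitability(learner, env)
  thr <- select_threshold(p[data$label == 1], p[data$label == 0])
  structure(list(learner = learner, threshold = thr$threshold,
                 flagged = flagged, best_learner = best,
                 evaluation = ev, species_id = data$species_id),
            class = "sdm_final")
}

#' Project a final model onto a predictor stack
#'
#' Predicts suitability for every cell of the stack and binarises it: a cell
#' is suitable when its suitability reaches the threshold and its centre
#' lies inside the buffered accessible area. Future stacks carry their own
#' climate layers while elevation and water bodies are held constant by
#' construction of the stack.
#'
#' @param final an `sdm_final` (or any object with `learner` + `threshold`).
#' @param stack a `predictor_stack` containing the model's predictors.
#' @param area an `accessible_area`, or `NULL` to skip the spatial clamp.
#' @return list with `suitability` and `binary` (`raster_grid`s).
#' @export
project_sdm <- function(final, stack, area = NULL) {
  missing <- setdiff(final$learner$predictors, names(stack$layers))
  if (length(missing))
    stop("predictor(s) missing from stack: ", paste(missing, collapse = ", "))
  vals <- stack_values(stack)
  suit <- predict_suitability(final$learner, vals)
  g <- stack$grid
  inside <- if (is.null(area)) TRUE else
    points_in_polygon(grid_points(g), area$polygon)
  bin <- (suit >= final$threshold) & inside
  list(
    suitability = raster_grid(matrix(suit, nrow(g$values)), g$xll, g$yll,
                              g$cellsize,
                              name = paste0("suit_", final$species_id)),
    binary = raster_grid(matrix(bin, nrow(g$values)), g$xll, g$yll,
                         g$cellsize,
                         name = paste0("range_", final$species_id)))
}
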