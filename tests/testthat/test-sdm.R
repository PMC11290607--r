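test_that("AUC matches the O(n^2) pairwise oracle and tie conventions", {
  expect_equal(auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.4, 10), rep(0:1, 5)), 0.5)
  set.seed(3)
  scores <- sample(round(runif(200), 2))   # rounding forces ties
  labels <- rbinom(200, 1, 0.5)
  expect_equal(auc(scores, labels), auc_bruteforce(scores, labels),
               tolerance = 1e-12)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("threshold selection equals an exhaustive scan", {
  set.seed(4)
  pres <- runif(80, 0.3, 1); bg <- runif(160, 0, 0.7)
  got <- select_threshold(pres, bg)
  cand <- sort(unique(c(pres, bg)))
  ss <- vapply(cand, function(t) mean(pres >= t) + mean(bg < t), 1)
  expect_equal(got$threshold, cand[which.max(ss)])
  expect_equal(got$sensitivity + got$specificity, max(ss))
  # perfectly separated scores attain sens + spec = 2
  sep <- select_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(sep$sensitivity + sep$specificity, 2)
  # single presence above all background
  one <- select_threshold(0.95, runif(50, 0, 0.9))
  expect_equal(one$threshold, 0.95)
  expect_equal(one$sensitivity, 1)
})

test_that("Boyce index behaves at its construction extremes", {
  set.seed(5)
  # rank-preserving model: presence density proportional to suitability
  pres <- sqrt(runif(500)); bg <- runif(1000)
  expect_gte(boyce_index(pres, bg), 0.9)
  # deterministic strictly decreasing P/E profile: exactly -1
  n <- 2000
  pres_dec <- 1 - sqrt(1 - (seq_len(n) - 0.5) / n)   # density 2(1 - x)
  bg_grid <- seq(0, 1, length.out = 4000)
  expect_equal(boyce_index(pres_dec, bg_grid, n_windows = 5,
                           window_width = 0.3), -1)
  expect_error(boyce_index(numeric(0), bg), "non-empty")
  expect_error(boyce_index(rep(0.5, 5), rep(0.5, 9)), "degenerate")
})

test_that("null Boyce index concentrates near zero", {
  # evaluated at window width = range/30; the wide default windows smooth
  # P/E so strongly that a null Spearman over ~10 effective windows is
  # much more variable (see the methods vignette)
  set.seed(6)
  vals <- replicate(200, {
    pool <- runif(1500)
    boyce_index(sample(pool, 500), pool, window_width = 1 / 30)
  })
  expect_gte(mean(abs(vals) <= 0.35), 0.95)
})

test_that("stratified split and dataset invariants hold", {
  set.seed(7)
  pres <- data.frame(a = rnorm(100), b = rnorm(100))
  bg <- data.frame(a = rnorm(200), b = rnorm(200))
  d <- make_sdm_data(pres, bg, "sp", seed = 1)
  expect_equal(sum(d$label == 0), 2 * sum(d$label == 1))
  expect_equal(sum(d$train[d$label == 1]), 75)
  expect_equal(sum(d$train[d$label == 0]), 150)
  d2 <- make_sdm_data(pres, bg, "sp", seed = 1)
  expect_identical(d$train, d2$train)
})

test_that("learners separate a linearly separable species perfectly", {
  set.seed(8)
  pres <- data.frame(x = rnorm(90, 3), z = rnorm(90))
  bg <- data.frame(x = rnorm(180, -3), z = rnorm(180))
  d <- make_sdm_data(pres, bg, "sep", seed = 2)
  ms <- fit_learners(d, seed = 2)
  expect_true(all(ms$evaluation$auc == 1))
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(9)
  n <- 120
  env <- data.frame(x = rnorm(3 * n), z = rnorm(3 * n))
  d <- make_sdm_data(env[1:n, ], env[(n + 1):(3 * n), ], "null", seed = 3)
  ms <- fit_learners(d, seed = 3)
  expect_true(all(abs(ms$evaluation$auc - 0.5) < 0.12))
})

test_that("ensemble suitability is the pointwise mean of its members", {
  set.seed(10)
  pres <- data.frame(x = rnorm(80, 1), z = rnorm(80))
  bg <- data.frame(x = rnorm(160), z = rnorm(160))
  d <- make_sdm_data(pres, bg, "m", seed = 4)
  ms <- fit_learners(d, seed = 4)
  nd <- data.frame(x = rnorm(50), z = rnorm(50))
  p_members <- vapply(ms$learners[c("additive_smooth", "maxent_style",
                                    "boosted_trees")],
                      predict_suitability, numeric(50), newdata = nd)
  expect_equal(predict_suitability(ms$learners$ensemble, nd),
               rowMeans(p_members), tolerance = 1e-12)
})

test_that("quality gates flag exactly the low-quality combinations", {
  fake_ms <- function(auc, boyce) {
    ev <- data.frame(learner = "boosted_trees", auc = auc, boyce = boyce)
    set.seed(1)
    pres <- data.frame(x = rnorm(40, 2)); bg <- data.frame(x = rnorm(80))
    d <- make_sdm_data(pres, bg, "g", seed = 1)
    ms <- fit_learners(d, seed = 1, min_presences = 10)
    ms$evaluation <- ev
    ms$best_learner <- "boosted_trees"
    list(d = d, ms = ms)
  }
  f1 <- fake_ms(0.69, 0.8)
  expect_true(evaluate_and_finalize(f1$d, f1$ms)$flagged)
  f2 <- fake_ms(0.9, 0.39)
  expect_true(evaluate_and_finalize(f2$d, f2$ms)$flagged)
  f3 <- fake_ms(0.9, 0.8)
  expect_false(evaluate_and_finalize(f3$d, f3$ms)$flagged)
})

test_that("projection is consistent, clamps to the area and honours t*", {
  w <- small_world()
  stk <- world_predictors(w)
  sp <- midband_species(w, n_presences = 250)
  occ <- sample_occurrences(w, sp, seed = 5)
  occ <- thin_spatially(clean_records(occ, study_rect(w)), 1,
                        w$template$cellsize, seed = 5)
  aa <- accessible_area(occ, sp$flight_months, outlier_pct = 0.01)
  pc <- cell_index(w$template, occ$records$lon, occ$records$lat)
  bg <- sample_background(aa, length(pc), w$template, pc, seed = 5)
  d <- make_sdm_data(stack_values(stk, pc), stack_values(stk, bg$cell),
                     "spMid", seed = 5)
  ms <- fit_learners(d, seed = 5)
  fin <- evaluate_and_finalize(d, ms, seed = 5)
  pr <- project_sdm(fin, stk, aa)
  # projecting onto the training stack reproduces training-cell suitabilities
  expect_equal(as.vector(pr$suitability$values)[pc],
               predict_suitability(fin$learner, stack_values(stk, pc)),
               tolerance = 1e-10)
  # binary = suitability >= t* AND inside the accessible area
  inside <- points_in_polygon(grid_points(w$template), aa$polygon)
  expect_equal(as.vector(pr$binary$values),
               (as.vector(pr$suitability$values) >= fin$threshold) & inside)
  # t* = 0 makes the binary map the accessible-area mask
  fin0 <- fin; fin0$threshold <- 0
  expect_equal(as.vector(project_sdm(fin0, stk, aa)$binary$values), inside)
  # missing predictor raises a schema error
  stk2 <- predictor_stack(stk$layers[1:2])
  expect_error(project_sdm(fin, stk2), "missing from stack")
})

test_that("a known logistic species is recovered on held-out cells", {
  w <- small_world()
  stk <- world_predictors(w)
  sp <- midband_species(w, n_presences = 300)
  ts <- as.vector(true_suitability(sp, stk)$values)
  occ <- sample_occurrences(w, sp, seed = 6)
  occ <- thin_spatially(clean_records(occ, study_rect(w)), 1,
                        w$template$cellsize, seed = 6)
  aa <- accessible_area(occ, sp$flight_months)
  pc <- cell_index(w$template, occ$records$lon, occ$records$lat)
  bg <- sample_background(aa, length(pc), w$template, pc, seed = 6)
  d <- make_sdm_data(stack_values(stk, pc), stack_values(stk, bg$cell),
                     "spMid", seed = 6)
  ms <- fit_learners(d, seed = 6)
  fin <- evaluate_and_finalize(d, ms, seed = 6)
  test_cells <- c(pc, bg$cell)[!d$train]
  p <- predict_suitability(fin$learner, d$env[!d$train, ])
  expect_gte(stats::cor(p, ts[test_cells], method = "spearman"), 0.9)
})

test_that("warming contracts a cold-adapted species' warm edge", {
  w <- small_world()
  stk <- world_predictors(w)
  sp <- midband_species(w, n_presences = 250)
  occ <- sample_occurrences(w, sp, seed = 7)
  occ <- thin_spatially(clean_records(occ, study_rect(w)), 1,
                        w$template$cellsize, seed = 7)
  aa <- accessible_area(occ, sp$flight_months)
  pc <- cell_index(w$template, occ$records$lon, occ$records$lat)
  bg <- sample_background(aa, length(pc), w$template, pc, seed = 7)
  d <- make_sdm_data(stack_values(stk, pc), stack_values(stk, bg$cell),
                     "spMid", seed = 7)
  fin <- evaluate_and_finalize(d, fit_learners(d, seed = 7), seed = 7)
  cur <- project_sdm(fin, stk, aa)$binary$values
  fut <- project_sdm(fin, world_predictors(w, "BCC-CSM1-1", "2050"),
                     aa)$binary$values
  # strictly fewer suitable cells in the warm (southern) third of the range
  south <- 21:30
  expect_lt(sum(fut[south, ]), sum(cur[south, ]))
})
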