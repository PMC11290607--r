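bm_tree <- function(n, seed) {
  set.seed(seed)
  ape::rphylo(n, 1, 0)
}

bm_trait <- function(tree, seed, lambda = 1) {
  set.seed(seed)
  V <- lambda_cov(ape::vcv(tree), lambda)
  n <- nrow(V)
  stats::setNames(as.numeric(crossprod(chol(V + diag(1e-10, n)),
                                       stats::rnorm(n))),
                  tree$tip.label)
}

test_that("lambda estimation recovers simulated signal levels", {
  tree <- bm_tree(60, 1)
  est1 <- vapply(1:12, function(i)
    pagel_lambda(tree, bm_trait(tree, i, lambda = 1))$estimate, 1)
  expect_gt(mean(est1), 0.85)
  est0 <- vapply(1:12, function(i)
    pagel_lambda(tree, bm_trait(tree, 100 + i, lambda = 0))$estimate, 1)
  expect_lt(mean(est0), 0.15)
  # shuffling destroys the signal of a BM trait
  set.seed(2)
  x <- bm_trait(tree, 55, lambda = 1)
  shuf <- vapply(1:12, function(i) {
    xs <- stats::setNames(sample(x), names(x))
    pagel_lambda(tree, xs)$estimate
  }, 1)
  expect_lt(mean(shuf), 0.15)
})

test_that("lambda optimum dominates the endpoints and the LRT is sane", {
  tree <- bm_tree(40, 3)
  x <- bm_trait(tree, 7, lambda = 0.7)
  r <- pagel_lambda(tree, x)
  V <- ape::vcv(tree)
  ll_at <- function(l) facetshift:::bm_profile_loglik(lambda_cov(V, l), x)$loglik
  expect_gte(r$loglik, ll_at(0) - 1e-8)
  expect_gte(r$loglik, ll_at(1) - 1e-8)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_error(pagel_lambda(tree, rep(1, 40)), "constant")
})

test_that("star phylogeny yields a flat likelihood flag", {
  star <- ape::stree(10, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- paste0("t", 1:10)
  set.seed(4)
  x <- stats::setNames(rnorm(10), star$tip.label)
  r <- pagel_lambda(star, x)
  expect_true(r$flat_likelihood)
})

test_that("lambda and K agree with the reference phytools implementation", {
  skip_if_not_installed("phytools")
  tree <- bm_tree(40, 5)
  x <- bm_trait(tree, 9, lambda = 0.8)
  ours <- pagel_lambda(tree, x)
  ref <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  expect_equal(ours$estimate, ref$lambda, tolerance = 0.01)
  expect_equal(ours$p_value, ref$P, tolerance = 0.02)
  ok <- blomberg_k(tree, x, n_permutations = 50, seed = 1)
  refk <- phytools::phylosig(tree, x, method = "K")
  expect_equal(ok$estimate, as.numeric(refk), tolerance = 1e-6)
})

test_that("K is near 1 under Brownian motion and errors on constants", {
  tree <- bm_tree(50, 6)
  ks <- vapply(1:15, function(i)
    blomberg_k(tree, bm_trait(tree, 200 + i), n_permutations = 10,
               seed = i)$estimate, 1)
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.2)
  expect_error(blomberg_k(tree, rep(2, 50)), "constant")
})

test_that("K permutation p-values are uniform under the null", {
  tree <- bm_tree(30, 7)
  set.seed(8)
  ps <- vapply(1:100, function(i) {
    x <- stats::setNames(rnorm(30), tree$tip.label)
    blomberg_k(tree, x, n_permutations = 199, seed = i)$p_value
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ancestral reconstruction matches closed-form GLS at the root", {
  # two tips, equal branches, values 0 and 2: root estimate 1 by symmetry
  t2 <- load_tree("(A:1,B:1);")
  a2 <- ancestral_reconstruction(t2, c(A = 0, B = 2))
  expect_equal(a2$estimate[1], 1)
  # arbitrary 6-tip tree: root equals (1'V^-1 x)/(1'V^-1 1) by inversion
  tree <- bm_tree(6, 9)
  x <- bm_trait(tree, 10)
  anc <- ancestral_reconstruction(tree, x)
  V <- ape::vcv(tree)
  Vi <- solve(V)
  mu <- sum(Vi %*% x) / sum(Vi)
  expect_equal(anc$estimate[anc$node == 7], mu, tolerance = 1e-10)
  # constant trait: every internal state equals that constant
  xc <- stats::setNames(rep(3.5, 6), tree$tip.label)
  expect_equal(ancestral_reconstruction(tree, xc)$estimate, rep(3.5, 5),
               tolerance = 1e-10)
})

test_that("ancestral states agree with the reference ML implementation", {
  tree <- bm_tree(12, 11)
  x <- bm_trait(tree, 12)
  ours <- ancestral_reconstruction(tree, x)
  ref <- ape::ace(x, tree, method = "REML")$ace
  expect_equal(ours$estimate, unname(ref), tolerance = 1e-4)
  txt <- export_ancestral_text(tree, x, ours)
  expect_length(txt, 12 + nrow(ours))
})

test_that("PGLS with identity-like covariance equals ordinary least squares", {
  star <- ape::stree(25, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- paste0("t", 1:25)
  set.seed(13)
  X <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  y <- stats::setNames(1 + 2 * X$x1 - 0.5 * X$x2 + rnorm(25, sd = 0.3),
                       star$tip.label)
  fit <- pgls(star, y, X, family = "lambda", fixed_param = 0)
  ols <- stats::lm(y ~ x1 + x2, data = X)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$std_error,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(fit$coefficients$p_value,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)
})

test_that("kappa = 0 equals GLS under the all-branches-equal covariance", {
  tree <- bm_tree(20, 14)
  set.seed(15)
  X <- data.frame(x = rnorm(20))
  y <- stats::setNames(rnorm(20), tree$tip.label)
  fit <- pgls(tree, y, X, family = "kappa", fixed_param = 0)
  t1 <- tree; t1$edge.length <- rep(1, nrow(t1$edge))
  V <- ape::vcv(t1)
  Xm <- cbind(1, X$x)
  beta <- solve(t(Xm) %*% solve(V) %*% Xm, t(Xm) %*% solve(V) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-8)
})

test_that("PGLS matches nlme::gls under a fixed Brownian correlation", {
  skip_if_not_installed("nlme")
  tree <- bm_tree(30, 16)
  set.seed(17)
  X <- data.frame(x = rnorm(30))
  y <- stats::setNames(2 + 0.8 * X$x + bm_trait(tree, 18) * 0.5,
                       tree$tip.label)
  fit <- pgls(tree, y, X, family = "lambda", fixed_param = 1)
  d <- data.frame(y = y, x = X$x, sp = tree$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tree, form = ~sp))
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ref)),
               tolerance = 1e-6)
})

test_that("singular designs are rejected naming the collinear columns", {
  tree <- bm_tree(15, 19)
  set.seed(20)
  X <- data.frame(a = rnorm(15))
  X$b <- 2 * X$a
  y <- stats::setNames(rnorm(15), tree$tip.label)
  expect_error(pgls(tree, y, X), "collinear.*b")
})

test_that("known slopes are recovered with nominal CI coverage", {
  tree <- bm_tree(40, 21)
  cover <- 0
  nrep <- 40
  for (i in seq_len(nrep)) {
    set.seed(400 + i)
    x <- rnorm(40)
    y <- stats::setNames(2 * x + bm_trait(tree, 500 + i), tree$tip.label)
    fit <- pgls(tree, y, data.frame(x = x), family = "lambda")
    co <- fit$coefficients[fit$coefficients$term == "x", ]
    tcrit <- stats::qt(0.975, fit$df_residual)
    if (abs(co$estimate - 2) <= tcrit * co$std_error) cover <- cover + 1
  }
  expect_gte(cover / nrep, 0.85)
})

test_that("the comparative suite runs per stratum and logs small subsets", {
  tree <- bm_tree(12, 22)
  tree$tip.label <- sprintf("sp%02d", 1:12)
  set.seed(23)
  shifts <- expand.grid(species = tree$tip.label,
                        scenario = c("A", "B"), period = "2050",
                        stringsAsFactors = FALSE)
  shifts$relative_area_change <- runif(nrow(shifts), 0.4, 1.6)
  shifts$altitude_difference <- rnorm(nrow(shifts), 30, 20)
  shifts$centroid_difference <- runif(nrow(shifts), 1e4, 3e5)
  traits <- data.frame(species = tree$tip.label,
                       body_size = runif(12, 30, 80),
                       flight_months = sample(2:10, 12, TRUE),
                       lentic = runif(12) < 0.6, lotic = runif(12) < 0.6)
  traits$lotic[!traits$lentic] <- TRUE
  out <- run_comparative_suite(
    shifts, traits, tree, responses = "relative_area_change",
    subsets = list(all = NULL, tiny = tree$tip.label[1:2]),
    n_permutations = 49, seed = 1)
  expect_equal(nrow(out$signal), 2)              # 2 scenarios x all
  expect_true(any(grepl("skipped", out$log)))    # tiny subset skipped
  expect_true(all(c("estimate", "std_error", "t_value", "p_value")
                  %in% names(out$pgls)))
  expect_equal(sort(unique(out$pgls$scenario)), c("A", "B"))
  # pruning consistency: suite on a pruned tree equals direct analysis
  sub <- tree$tip.label[1:8]
  out_sub <- run_comparative_suite(
    shifts[shifts$species %in% sub & shifts$scenario == "A", ],
    traits, tree, responses = "relative_area_change",
    n_permutations = 49, seed = 1)
  ptree <- ape::keep.tip(tree, sub)
  out_dir <- run_comparative_suite(
    shifts[shifts$species %in% sub & shifts$scenario == "A", ],
    traits, ptree, responses = "relative_area_change",
    n_permutations = 49, seed = 1)
  expect_equal(out_sub$signal$lambda, out_dir$signal$lambda,
               tolerance = 1e-8)
})
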