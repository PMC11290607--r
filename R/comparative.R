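#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Scales the off-diagonal entries of a Brownian covariance matrix by
#' `lambda`, leaving the diagonal untouched: `lambda = 1` is Brownian
#' motion, `lambda = 0` a star phylogeny.
#' @param V covariance matrix (e.g. `ape::vcv(tree)`).
#' @param lambda scalar in `[0, lambda_max]`.
#' @return transformed matrix.
#' @export
lambda_cov <- function(V, lambda) {
  out <- lambda * V
  diag(out) <- diag(V)
  out
}

#' Largest lambda keeping the transformed covariance positive definite
#'
#' Computed from the pairwise bound `sqrt(Vii Vjj) / Vij`; for an
#' ultrametric tree this is at least 1. Estimation routines additionally
#' cap the search at 1, where the transform retains its interpretation
#' (the profiled likelihood can diverge spuriously as the covariance
#' approaches singularity just beyond the Brownian case).
#' @param V Brownian covariance matrix.
#' @return upper bound for the lambda search.
#' @export
lambda_upper_bound <- function(V) {
  off <- V; diag(off) <- 0
  mx <- max(off)
  if (mx <= 0) return(1)
  d <- sqrt(diag(V))
  min(outer(d, d)[off > 0] / off[off > 0])
}

# profiled BM log-likelihood of trait x under covariance structure V
# (rate and root mean profiled out analytically)
bm_profile_loglik <- function(V, x) {
  n <- length(x)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf))
  z <- backsolve(L, x, transpose = TRUE)
  o <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  q <- sum((z - mu * o)^2)
  if (q <= 0) return(list(loglik = Inf, mu = mu, rate = 0))
  sig2 <- q / n
  logdet <- 2 * sum(log(diag(L)))
  list(loglik = -0.5 * (n * log(2 * pi * sig2) + logdet + n),
       mu = mu, rate = sig2)
}

#' Phylogenetic signal: Pagel's lambda
#'
#' Maximises the Brownian-motion likelihood of the trait over the lambda
#' transform of the tree's covariance (rate and root mean profiled out),
#' and tests the estimate against `lambda = 0` with a likelihood-ratio test
#' on one degree of freedom. On a star phylogeny the likelihood is flat in
#' lambda and the result carries a `flat_likelihood` flag.
#'
#' @param tree ultrametric-ish `ape::phylo` with at least 4 tips.
#' @param x named trait vector covering the tips.
#' @param grid_n coarse grid size before local refinement.
#' @return object of class `signal_result` with `statistic = "lambda"`,
#'   `estimate`, `loglik`, `loglik0`, `p_value`, `flat_likelihood`.
#' @export
pagel_lambda <- function(tree, x, grid_n = 21) {
  x <- align_trait(tree, x)
  if (length(x) < 4) stop("need at least 4 tips")
  if (stats::sd(x) == 0) stop("trait is constant across tips")
  V <- ape::vcv(tree)
  ub <- min(1, lambda_upper_bound(V))
  f <- function(l) bm_profile_loglik(lambda_cov(V, l), x)$loglik
  grid <- seq(0, ub, length.out = grid_n)
  ll <- vapply(grid, f, 1)
  flat <- diff(range(ll[is.finite(ll)])) < 1e-8
  if (flat) {
    est <- 0
    llhat <- ll[1]
  } else {
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= ll[i]) {
      est <- opt$maximum; llhat <- opt$objective
    } else {
      est <- grid[i]; llhat <- ll[i]
    }
  }
  ll0 <- f(0)
  lr <- max(0, 2 * (llhat - ll0))
  structure(list(statistic = "lambda", estimate = est, loglik = llhat,
                 loglik0 = ll0, lr = lr,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 flat_likelihood = flat, n = length(x)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (n = %d)%s\n", x$statistic, x$estimate,
              x$p_value, x$n,
              if (isTRUE(x$flat_likelihood)) " [flat likelihood]" else ""))
  invisible(x)
}

#' Phylogenetic signal: Blomberg's K
#'
#' K is the ratio of the observed mean-squared-error ratio
#' `MSE0/MSE` (deviation from the phylogenetically corrected mean over the
#' GLS rate) to its Brownian-motion expectation
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`; K is about 1 under Brownian motion.
#' Significance comes from a seeded permutation test that shuffles tip
#' values and asks how often the permuted `MSE0/MSE` reaches the observed
#' one.
#'
#' @param tree `ape::phylo` with at least 4 tips.
#' @param x named trait vector.
#' @param n_permutations permutations for the p-value (default 1000).
#' @param seed RNG seed.
#' @return `signal_result` with `statistic = "K"`.
#' @export
blomberg_k <- function(tree, x, n_permutations = 1000, seed = 1) {
  x <- align_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips")
  if (stats::sd(x) == 0) stop("trait is constant across tips")
  C <- ape::vcv(tree)
  Ci <- solve(C)
  w <- Ci %*% rep(1, n)
  sw <- sum(w)
  ratio_of <- function(X) {           # X: n x m matrix of trait columns
    abar <- as.numeric(crossprod(w, X)) / sw
    mse0 <- colSums(X^2) - 2 * abar * colSums(X) + n * abar^2
    mse <- colSums(X * (Ci %*% X)) - abar^2 * sw
    mse0 / mse
  }
  obs <- ratio_of(matrix(x, ncol = 1))
  expected <- (sum(diag(C)) - n / sw) / (n - 1)
  K <- as.numeric(obs / expected)
  set.seed(seed)
  perms <- vapply(seq_len(n_permutations), function(i) sample(x),
                  numeric(n))
  pr <- ratio_of(perms)
  p <- (1 + sum(pr >= as.numeric(obs))) / (n_permutations + 1)
  structure(list(statistic = "K", estimate = K, p_value = p,
                 n_permutations = n_permutations, n = n,
                 observed_ratio = as.numeric(obs),
                 expected_ratio = expected),
            class = "signal_result")
}

# node-by-edge root-path incidence over all nodes (tips + internal)
node_edge_incidence <- function(tree) {
  ntot <- max(tree$edge)
  N <- matrix(FALSE, ntot, nrow(tree$edge))
  child_edge <- match(seq_len(ntot), tree$edge[, 2])
  for (k in seq_len(ntot)) {
    node <- k
    while (!is.na(child_edge[node])) {
      e <- child_edge[node]
      N[k, e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  N
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS prediction of internal-node states given the tip data: the root
#' estimate is the phylogenetically corrected (GLS) mean and every other
#' node is the conditional Brownian expectation given the tips. Variances
#' are the conditional Brownian variances scaled by the ML rate.
#'
#' @param tree `ape::phylo`.
#' @param x named trait vector over the tips.
#' @return data.frame with `node` (ape numbering), `estimate`, `variance`;
#'   internal nodes only, root first.
#' @export
ancestral_reconstruction <- function(tree, x) {
  x <- align_trait(tree, x)
  ntip <- length(tree$tip.label)
  N <- node_edge_incidence(tree)
  Cfull <- (N %*% (tree$edge.length * t(N)))
  tips <- seq_len(ntip)
  internal <- (ntip + 1L):max(tree$edge)
  Ct <- Cfull[tips, tips]
  Ci <- solve(Ct)
  one <- rep(1, ntip)
  mu <- as.numeric(crossprod(one, Ci %*% x) / crossprod(one, Ci %*% one))
  rate <- as.numeric(crossprod(x - mu, Ci %*% (x - mu))) / ntip
  Cnt <- Cfull[internal, tips, drop = FALSE]
  est <- mu + as.numeric(Cnt %*% (Ci %*% (x - mu)))
  vr <- rate * (diag(Cfull)[internal] -
                  rowSums((Cnt %*% Ci) * Cnt))
  data.frame(node = internal, estimate = est, variance = pmax(vr, 0))
}

#' Plain-text rendering of ancestral states
#'
#' ASCII export of a tree with tip values and internal-node reconstructions,
#' one node per line in preorder.
#' @param tree `ape::phylo`.
#' @param x named tip trait vector.
#' @param anc output of [ancestral_reconstruction()]; recomputed if `NULL`.
#' @return character vector of lines (invisibly printable with `cat`).
#' @export
export_ancestral_text <- function(tree, x, anc = NULL) {
  x <- align_trait(tree, x)
  if (is.null(anc)) anc <- ancestral_reconstruction(tree, x)
  dep <- node_depths(tree)
  ntip <- length(tree$tip.label)
  vals <- c(x, stats::setNames(anc$estimate, anc$node))
  lab <- c(tree$tip.label, paste0("node", anc$node))
  nodes <- c(seq_len(ntip), anc$node)
  ord <- order(dep[nodes])
  sprintf("%s%-14s depth %8.4f  state %10.4f",
          strrep("  ", pmin(12, round(dep[nodes][ord] /
                                        max(dep) * 6))),
          lab[ord], dep[nodes][ord], vals[ord])
}

align_trait <- function(tree, x) {
  if (!is.null(names(x))) {
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing))
      stop("trait missing for tips: ", paste(missing, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != length(tree$tip.label)) {
    stop("trait length does not match number of tips")
  }
  as.numeric(x)
}

# covariance under one branch-length transform family
transform_cov <- function(tree, family, param, V = NULL) {
  switch(family,
    lambda = {
      if (is.null(V)) V <- ape::vcv(tree)
      lambda_cov(V, param)
    },
    kappa = {
      tr <- tree
      tr$edge.length <- tree$edge.length^param
      ape::vcv(tr)
    },
    delta = {
      if (is.null(V)) V <- ape::vcv(tree)
      V^param
    },
    stop("unknown transform family: ", family))
}

transform_bounds <- function(family, tree) {
  switch(family,
    lambda = c(0, min(1, lambda_upper_bound(ape::vcv(tree)))),
    kappa = c(0, 3),
    delta = c(0, 3))
}

#' Phylogenetic generalised least squares
#'
#' GLS regression with residual covariance from a branch-length transform of
#' the phylogeny (lambda, kappa or delta family). The transform parameter is
#' profiled by maximum likelihood on a coarse grid of 51 points followed by
#' local refinement. Coefficient standard errors use the residual variance
#' on `n - p` degrees of freedom, with two-sided t-tests.
#'
#' @param tree `ape::phylo` covering all modelled species.
#' @param y named response vector.
#' @param X data.frame/matrix of predictors (intercept added automatically).
#' @param family transform family: `"lambda"`, `"kappa"` or `"delta"`.
#' @param fixed_param fix the transform parameter instead of profiling.
#' @return object of class `pgls_fit`: `coefficients` table, `family`,
#'   `param`, `loglik`, `sigma2`, `df_residual`.
#' @export
pgls <- function(tree, y, X, family = c("lambda", "kappa", "delta"),
                 fixed_param = NULL) {
  family <- match.arg(family)
  y <- align_trait(tree, y)
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("predictor rows must match response length")
  Xm <- cbind("(Intercept)" = 1, as.matrix(X))
  qr_x <- qr(Xm)
  if (qr_x$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qr_x$pivot[(qr_x$rank + 1):ncol(Xm)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- length(y); p <- ncol(Xm)
  V0 <- ape::vcv(tree)
  fit_at <- function(param) {
    V <- transform_cov(tree, family, param, V = V0)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(list(loglik = -Inf))
    yt <- backsolve(L, y, transpose = TRUE)
    Xt <- backsolve(L, Xm, transpose = TRUE)
    fit <- stats::lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    logdet <- 2 * sum(log(diag(L)))
    list(loglik = -0.5 * (n * log(2 * pi * rss / n) + logdet + n),
         beta = fit$coefficients, rss = rss, Xt = Xt, param = param)
  }
  if (is.null(fixed_param)) {
    b <- transform_bounds(family, tree)
    grid <- seq(b[1], b[2], length.out = 51)
    ll <- vapply(grid, function(p1) fit_at(p1)$loglik, 1)
    i <- which.max(ll)
    opt <- stats::optimize(function(p1) fit_at(p1)$loglik,
                           c(grid[max(1, i - 1)], grid[min(51, i + 1)]),
                           maximum = TRUE, tol = 1e-6)
    param <- if (opt$objective > ll[i]) opt$maximum else grid[i]
  } else param <- fixed_param
  f <- fit_at(param)
  if (!is.finite(f$loglik)) stop("covariance not positive definite at fit")
  sigma2 <- f$rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(f$Xt)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- f$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coef <- data.frame(term = colnames(Xm), estimate = unname(f$beta),
                     std_error = se, t_value = tval, p_value = pval,
                     row.names = NULL)
  structure(list(coefficients = coef, family = family, param = param,
                 loglik = f$loglik, sigma2 = sigma2, df_residual = n - p,
                 n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s = %.3g, logLik = %.3f, n = %d)\n",
              x$family, x$param, x$loglik, x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit PGLS under all transform families and keep the best
#'
#' Profiles lambda, kappa and delta separately and returns the fit with the
#' highest maximised likelihood.
#' @inheritParams pgls
#' @return the winning `pgls_fit` (with the family recorded).
#' @export
pgls_best_transform <- function(tree, y, X) {
  fits <- lapply(c("lambda", "kappa", "delta"), function(fam)
    tryCatch(pgls(tree, y, X, family = fam), error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("no transform family produced a valid fit")
  fits[[which.max(vapply(fits, `[[`, 1, "loglik"))]]
}

#' Run the full comparative analysis bundle
#'
#' For every response x scenario x period stratum and every species subset
#' (the whole assemblage and, e.g., each suborder with its pruned tree),
#' estimates Pagel's lambda and Blomberg's K on the response, reconstructs
#' ancestral states, and fits PGLS of the response on body size, flight
#' season and the two habitat indicators, choosing the branch transform by
#' maximum likelihood. Strata with fewer than 4 species are skipped with a
#' log entry.
#'
#' @param shifts tidy range-shift table (`species`, `scenario`, `period`,
#'   metric columns).
#' @param traits trait table as from [synth_trait_table()].
#' @param tree phylogeny covering the species.
#' @param responses response column names in `shifts`.
#' @param subsets named list of species-id vectors (`NULL` = all species).
#' @param n_permutations permutations for K.
#' @param seed RNG seed.
#' @return list with `signal` (tidy lambda/K table), `pgls` (tidy
#'   coefficient table), `ancestral` (per-stratum root estimates) and
#'   `log` (skipped strata).
#' @export
run_comparative_suite <- function(shifts, traits, tree,
                                  responses = c("relative_area_change",
                                                "altitude_difference",
                                                "centroid_difference"),
                                  subsets = list(all = NULL),
                                  n_permutations = 199, seed = 1) {
  signal <- pgls_tab <- anc_tab <- NULL
  log <- character(0)
  strata <- unique(shifts[c("scenario", "period")])
  for (si in seq_len(nrow(strata))) {
    sc <- strata$scenario[si]; pd <- strata$period[si]
    sub_shift <- shifts[shifts$scenario == sc & shifts$period == pd, ]
    for (sub_nm in names(subsets)) {
      ids <- subsets[[sub_nm]]
      d <- if (is.null(ids)) sub_shift else
        sub_shift[sub_shift$species %in% ids, ]
      d <- merge(d, traits, by = "species")
      for (resp in responses) {
        ok <- stats::complete.cases(d[c(resp, "body_size",
                                        "flight_months", "lentic", "lotic")])
        dd <- d[ok, ]
        if (nrow(dd) < 4) {
          log <- c(log, sprintf("skipped (<4 species): %s/%s/%s/%s",
                                sub_nm, sc, pd, resp))
          next
        }
        al <- align_tree_to_species(tree, dd$species)
        dd <- dd[dd$species %in% al$tree$tip.label, ]
        yv <- stats::setNames(dd[[resp]], dd$species)
        lam <- pagel_lambda(al$tree, yv)
        kk <- blomberg_k(al$tree, yv, n_permutations = n_permutations,
                         seed = stage_seed(seed, paste(sub_nm, sc, pd, resp)))
        signal <- rbind(signal, data.frame(
          subset = sub_nm, scenario = sc, period = pd, response = resp,
          lambda = lam$estimate, lambda_p = lam$p_value,
          K = kk$estimate, K_p = kk$p_value, n = lam$n))
        anc <- ancestral_reconstruction(al$tree, yv)
        anc_tab <- rbind(anc_tab, data.frame(
          subset = sub_nm, scenario = sc, period = pd, response = resp,
          root_estimate = anc$estimate[1]))
        Xd <- data.frame(body_length = dd$body_size,
                         flight_season = dd$flight_months,
                         habitat_lentic = dd$lentic + 0,
                         habitat_lotic = dd$lotic + 0)
        rownames(Xd) <- dd$species
        fit <- tryCatch(
          pgls_best_transform(al$tree, yv, Xd[al$tree$tip.label, ]),
          error = function(e) e)
        if (inherits(fit, "error")) {
          log <- c(log, sprintf("pgls failed (%s/%s/%s/%s): %s",
                                sub_nm, sc, pd, resp, conditionMessage(fit)))
          next
        }
        co <- fit$coefficients
        pgls_tab <- rbind(pgls_tab, cbind(
          co, subset = sub_nm, scenario = sc, period = pd, response = resp,
          transform = fit$family, transform_param = fit$param))
      }
    }
  }
  list(signal = signal, pgls = pgls_tab, ancestral = anc_tab, log = log)
}
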