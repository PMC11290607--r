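# Shared fixtures, built in code at test time.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(nrow = 30, ncol = 30,
                                                 seed = 42)
    cache
  }
})

# a species whose optimum sits mid-domain, so its niche is identifiable
midband_species <- function(world, n_presences = 300, tol = 1.2) {
  stk <- world_predictors(world)
  opt <- stats::median(stk$layers$bio10$values)
  true_species("spMid",
               c("(Intercept)" = 4 * (1 - opt^2 / tol^2),
                 bio10 = 4 * 2 * opt / tol^2, "bio10^2" = -4 / tol^2),
               n_presences = n_presences, flight_months = 6)
}

study_rect <- function(world) {
  g <- world$template
  ext <- c(g$xll, g$yll, g$xll + ncol(g$values) * g$cellsize,
           g$yll + nrow(g$values) * g$cellsize)
  cbind(lon = ext[c(1, 3, 3, 1)], lat = ext[c(2, 2, 4, 4)])
}

# small deterministic occurrence table around a point
toy_occurrences <- function(n = 20, lon0 = 0, lat0 = 43, spread = 0.5,
                            seed = 99) {
  set.seed(seed)
  occurrence_set("toy", data.frame(
    lon = lon0 + stats::runif(n, -spread, spread),
    lat = lat0 + stats::runif(n, -spread, spread),
    year = sample(1980:2010, n, replace = TRUE),
    uncertainty_m = stats::runif(n, 100, 2000)))
}

# brute-force Faith-style alpha: per-branch descendant scan
alpha_bruteforce <- function(tree, present_tips) {
  if (!length(present_tips)) return(0)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    desc <- descendant_tips(tree, tree$edge[e, 2])
    if (any(desc %in% present_tips)) total <- total + tree$edge.length[e]
  }
  total
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# O(n^2) pairwise AUC oracle with half-credit ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# scalar per-cell reference implementation of the bioclim set
bioclim_scalar <- function(tmin, tmax, prec) {
  tm <- (tmin + tmax) / 2
  qs <- lapply(1:12, function(m) ((m - 2):m) %% 12 + 1)
  qprec <- vapply(qs, function(w) sum(prec[w]), 1)
  qtemp <- vapply(qs, function(w) mean(tm[w]), 1)
  b12 <- sum(prec)
  c(bio1 = mean(tm), bio4 = 100 * stats::sd(tm),
    bio5 = max(tmax), bio6 = min(tmin), bio7 = max(tmax) - min(tmin),
    bio8 = qtemp[which.max(qprec)], bio10 = qtemp[which.max(qtemp)],
    bio12 = b12, bio15 = 100 * stats::sd(prec) / (1 + b12 / 12))
}

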