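#' Stack per-species binary range maps into a community matrix
#'
#' @param binary_maps named list (by species) of logical/0-1 `raster_grid`s
#'   on a shared grid.
#' @param scenario,period provenance tags.
#' @return object of class `community_stack`: `comm` (cells x species
#'   logical matrix in grid cell order), `species`, `grid`, tags.
#' @export
stack_maps <- function(binary_maps, scenario = "current",
                       period = "current") {
  if (is.null(names(binary_maps))) stop("binary_maps must be named by species")
  do.call(check_aligned, unname(binary_maps))
  comm <- vapply(binary_maps, function(g) as.vector(g$values) > 0,
                 logical(length(binary_maps[[1]]$values)))
  structure(list(comm = comm, species = names(binary_maps),
                 grid = binary_maps[[1]], scenario = scenario,
                 period = period),
            class = "community_stack")
}

#' Edge-by-tip incidence of a tree
#'
#' `B[e, t]` is `TRUE` when tip `t` descends from edge `e`, i.e. edge `e`
#' lies on the root path of tip `t`.
#' @param tree an `ape::phylo`.
#' @return logical matrix (edges x tips), tip columns named.
#' @export
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  B <- matrix(FALSE, nrow(tree$edge), ntip,
              dimnames = list(NULL, tree$tip.label))
  child_edge <- match(seq_len(max(tree$edge)), tree$edge[, 2])
  for (t in seq_len(ntip)) {
    node <- t
    while (!is.na(child_edge[node])) {
      e <- child_edge[node]
      B[e, t] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  B
}

#' Tree-based alpha diversity of communities
#'
#' Without a tree, alpha is the species count per cell (taxonomic facet).
#' With a tree, alpha is Faith-style diversity: the summed branch length of
#' the minimal subtree connecting the cell's species to the root (root path
#' included, so a single-species cell scores its root-to-tip distance).
#'
#' @param comm logical matrix (cells x species) or a `community_stack`.
#' @param tree `NULL` or an `ape::phylo` whose tips cover the species.
#' @return numeric vector of per-cell alpha values (0 for empty cells).
#' @export
alpha_diversity <- function(comm, tree = NULL) {
  if (inherits(comm, "community_stack")) comm <- comm$comm
  if (is.null(tree)) return(rowSums(comm))
  if (!all(colnames(comm) %in% tree$tip.label))
    stop("community species missing from tree")
  B <- edge_tip_incidence(tree)[, colnames(comm), drop = FALSE]
  present_edge <- tcrossprod(comm + 0, B + 0) > 0   # cells x edges
  as.numeric(present_edge %*% tree$edge.length)
}

#' Temporal beta diversity with replacement/richness decomposition
#'
#' Compares a cell's present and future communities on a tree. With `a` the
#' branch length shared by both communities' root-spanning subtrees, `b` the
#' length unique to the present and `c` unique to the future:
#' `beta_total = (b+c)/(a+b+c)`, `beta_repl = 2 min(b,c)/(a+b+c)`,
#' `beta_rich = |b-c|/(a+b+c)`, so that total = replacement + richness.
#' Without a tree the species sets act on an implicit unit star tree and
#' `a`, `b`, `c` reduce to species counts. Two empty communities give all
#' zeros.
#'
#' @param present,future logical vectors (named by species when `tree` is
#'   given) or character vectors of species names.
#' @param tree `NULL` (taxonomic) or an `ape::phylo`.
#' @return named numeric vector `c(total =, repl =, rich =)`.
#' @export
beta_temporal <- function(present, future, tree = NULL) {
  as_set <- function(x, universe) {
    if (is.character(x)) return(universe %in% x)
    x
  }
  if (is.null(tree)) {
    uni <- unique(c(
      if (is.character(present)) present else names(present),
      if (is.character(future)) future else names(future)))
    p <- as_set(present, uni); f <- as_set(future, uni)
    a <- sum(p & f); b <- sum(p & !f); cc <- sum(!p & f)
  } else {
    uni <- tree$tip.label
    p <- as_set(present, uni); f <- as_set(future, uni)
    B <- edge_tip_incidence(tree)
    if (is.character(present)) {
      ep <- B[, uni %in% present, drop = FALSE]
      ef <- B[, uni %in% future, drop = FALSE]
    } else {
      ep <- B[, p, drop = FALSE]; ef <- B[, f, drop = FALSE]
    }
    in_p <- rowSums(ep) > 0; in_f <- rowSums(ef) > 0
    len <- tree$edge.length
    a <- sum(len[in_p & in_f]); b <- sum(len[in_p & !in_f])
    cc <- sum(len[!in_p & in_f])
  }
  tot <- a + b + cc
  if (tot == 0) return(c(total = 0, repl = 0, rich = 0))
  c(total = (b + cc) / tot, repl = 2 * min(b, cc) / tot,
    rich = abs(b - cc) / tot)
}

beta_temporal_stack <- function(comm_p, comm_f, tree = NULL) {
  if (is.null(tree)) {
    ep <- comm_p; ef <- comm_f
    len <- rep(1, ncol(comm_p))
  } else {
    B <- edge_tip_incidence(tree)[, colnames(comm_p), drop = FALSE]
    ep <- tcrossprod(comm_p + 0, B + 0) > 0
    ef <- tcrossprod(comm_f + 0, B + 0) > 0
    len <- tree$edge.length
  }
  a <- (ep & ef) %*% len
  b <- (ep & !ef) %*% len
  cc <- (!ep & ef) %*% len
  tot <- a + b + cc
  safe <- function(x) ifelse(tot == 0, 0, x / tot)
  list(total = as.numeric(safe(b + cc)),
       repl = as.numeric(safe(2 * pmin(b, cc))),
       rich = as.numeric(safe(abs(b - cc))))
}

#' Alpha and beta maps for every diversity facet
#'
#' For each facet (TD = taxonomic, FD = functional, PD = phylogenetic),
#' computes per-cell alpha for both periods, the alpha change (future minus
#' present) and the three temporal beta components. Species missing from a
#' facet's tree are excluded from that facet and reported.
#'
#' @param present,future `community_stack`s on the same grid with the same
#'   species.
#' @param trees list with optional elements `FD` and `PD` (`ape::phylo`);
#'   TD always uses the implicit unit star tree.
#' @return nested list: per facet, `alpha_present`, `alpha_future`,
#'   `alpha_delta`, `beta_total`, `beta_repl`, `beta_rich` as
#'   `raster_grid`s; plus `excluded` (per-facet species lists).
#' @export
facet_maps <- function(present, future, trees = list()) {
  stopifnot(inherits(present, "community_stack"),
            inherits(future, "community_stack"))
  check_aligned(present$grid, future$grid)
  if (!identical(present$species, future$species))
    stop("present and future stacks hold different species")
  g <- present$grid
  as_g <- function(v, nm)
    raster_grid(matrix(v, nrow(g$values)), g$xll, g$yll, g$cellsize, nm)
  facets <- c("TD", if (!is.null(trees$FD)) "FD", if (!is.null(trees$PD)) "PD")
  excluded <- list()
  out <- list()
  for (fc in facets) {
    tree <- NULL
    comm_p <- present$comm; comm_f <- future$comm
    if (fc != "TD") {
      al <- align_tree_to_species(trees[[fc]], present$species)
      tree <- al$tree
      excluded[[fc]] <- al$missing
      keep <- colnames(comm_p) %in% tree$tip.label
      comm_p <- comm_p[, keep, drop = FALSE]
      comm_f <- comm_f[, keep, drop = FALSE]
    }
    ap <- alpha_diversity(comm_p, tree)
    af <- alpha_diversity(comm_f, tree)
    bt <- beta_temporal_stack(comm_p, comm_f, tree)
    out[[fc]] <- list(
      alpha_present = as_g(ap, paste0("alpha_", fc, "_present")),
      alpha_future = as_g(af, paste0("alpha_", fc, "_future")),
      alpha_delta = as_g(af - ap, paste0("alpha_", fc, "_delta")),
      beta_total = as_g(bt$total, paste0("beta_total_", fc)),
      beta_repl = as_g(bt$repl, paste0("beta_repl_", fc)),
      beta_rich = as_g(bt$rich, paste0("beta_rich_", fc)))
  }
  out$excluded <- excluded
  out
}
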