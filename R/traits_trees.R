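#' Default trait grouping for the grouped Gower dissimilarity
#'
#' Group 1: body, abdomen and wing lengths; group 2: habitat (lentic/lotic
#' flags); group 3: flight season; group 4: abdomen pigmentation (RGB).
#' Every group contributes equally to the final dissimilarity.
#' @return named list of character vectors of trait names.
#' @export
default_trait_groups <- function() {
  list(morphology = c("body_size", "abdomen_length", "wing_length"),
       habitat = "habitat",
       flight = "flight_months",
       pigmentation = "rgb")
}

#' Group-balanced Gower dissimilarity
#'
#' Mixed-type trait dissimilarity in which traits are first averaged within
#' their group and groups then contribute equally to the final matrix, so
#' that a group holding many correlated traits (e.g. three body measures)
#' cannot dominate. Per trait: continuous traits use the range-normalised
#' absolute difference; the habitat trait is the mean mismatch of the lentic
#' and lotic flags; pigmentation is the Euclidean RGB distance in the unit
#' cube divided by sqrt(3). Traits with zero range are dropped with a
#' warning.
#'
#' @param traits data.frame with columns `species`, `body_size`,
#'   `abdomen_length`, `wing_length`, `col_r`, `col_g`, `col_b`, `lentic`,
#'   `lotic`, `flight_months`.
#' @param groups named list mapping group names to trait names
#'   (`"habitat"` and `"rgb"` are composite traits); see
#'   [default_trait_groups()].
#' @return symmetric dissimilarity matrix in [0, 1] with species
#'   row/colnames and zero diagonal.
#' @export
gower_grouped <- function(traits, groups = default_trait_groups()) {
  sp <- traits$species
  n <- length(sp)
  if (anyDuplicated(sp)) stop("duplicate species in trait table")
  if (anyNA(traits)) stop("trait table contains missing values")
  cont_d <- function(x) {
    r <- diff(range(x))
    if (r == 0) return(NULL)
    abs(outer(x, x, "-")) / r
  }
  trait_d <- function(nm) {
    if (nm == "habitat") {
      m <- (abs(outer(traits$lentic + 0, traits$lentic + 0, "-")) +
              abs(outer(traits$lotic + 0, traits$lotic + 0, "-"))) / 2
      return(m)
    }
    if (nm == "rgb") {
      rgb <- as.matrix(traits[c("col_r", "col_g", "col_b")]) / 255
      d2 <- outer(rowSums(rgb^2), rowSums(rgb^2), "+") - 2 * tcrossprod(rgb)
      return(sqrt(pmax(d2, 0)) / sqrt(3))
    }
    cont_d(traits[[nm]])
  }
  gmats <- lapply(names(groups), function(g) {
    ms <- lapply(groups[[g]], trait_d)
    dropped <- vapply(ms, is.null, TRUE)
    if (any(dropped))
      warning("constant trait(s) dropped in group '", g, "': ",
              paste(groups[[g]][dropped], collapse = ", "))
    ms <- ms[!dropped]
    if (!length(ms)) return(NULL)
    Reduce(`+`, ms) / length(ms)
  })
  gmats <- gmats[!vapply(gmats, is.null, TRUE)]
  if (!length(gmats)) stop("no usable trait groups")
  d <- Reduce(`+`, gmats) / length(gmats)
  dimnames(d) <- list(sp, sp)
  diag(d) <- 0
  d
}

#' Functional dendrogram from a dissimilarity matrix
#'
#' Agglomerative hierarchical clustering (UPGMA by default) converted to a
#' rooted tree whose cophenetic distances equal the merge heights: two tips
#' merging at height h sit at depth h/2 below their common node.
#' @param d symmetric dissimilarity matrix with species dimnames.
#' @param linkage `hclust` linkage method; `"average"` (UPGMA) default.
#' @return an `ape::phylo` tree (class attribute `facet = "functional"`).
#' @export
build_dendrogram <- function(d, linkage = "average") {
  if (nrow(d) < 2) stop("need at least 2 species")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  tree <- ape::as.phylo(hc)
  attr(tree, "facet") <- "functional"
  tree
}

#' Load and validate a phylogenetic tree
#'
#' Parses Newick text (or a file), validates tip uniqueness, branch-length
#' presence and non-negativity, and optionally checks ultrametricity.
#' @param newick a Newick string or path to a Newick file.
#' @param ultrametric_tol if non-`NULL`, maximum allowed spread of
#'   root-to-tip distances.
#' @return an `ape::phylo`.
#' @export
load_tree <- function(newick, ultrametric_tol = NULL) {
  tree <- if (file.exists(newick)) ape::read.tree(newick)
  else ape::read.tree(text = newick)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!is.null(ultrametric_tol)) {
    dep <- node_depths(tree)[seq_along(tree$tip.label)]
    if (diff(range(dep)) > ultrametric_tol)
      stop("tree is not ultrametric within tolerance")
  }
  tree
}

#' Align a tree with a species set
#'
#' Prunes tree tips absent from the community and reports community species
#' missing from the tree (these must be excluded from tree-based facets).
#' @param tree an `ape::phylo`.
#' @param species character vector of community species.
#' @return list with `tree` (pruned), `missing` (species not in the tree),
#'   `pruned` (tips removed).
#' @export
align_tree_to_species <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  extra <- setdiff(tree$tip.label, species)
  keep <- intersect(tree$tip.label, species)
  if (length(keep) < 2) stop("fewer than 2 shared species between tree and data")
  if (length(extra))
    message("pruned ", length(extra), " tree tip(s) absent from community")
  if (length(missing))
    message("species missing from tree (excluded from this facet): ",
            paste(missing, collapse = ", "))
  list(tree = ape::keep.tip(tree, keep), missing = missing, pruned = extra)
}

#' Root-to-node depths of a tree
#' @param tree an `ape::phylo` with branch lengths.
#' @return numeric vector over all nodes (tips first, ape numbering).
#' @export
node_depths <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  dep <- numeric(max(tr$edge))
  for (i in rev(seq_len(nrow(tr$edge))))   # root-to-tip sweep
    dep[tr$edge[i, 2]] <- dep[tr$edge[i, 1]] + tr$edge.length[i]
  dep
}
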