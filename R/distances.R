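#' Taxonomic distances between species
#'
#' The unit taxonomic metric: `d_ij = 1` for distinct species, 0 on the
#' diagonal. Already unit-scaled.
#'
#' @param species character vector of unique species identifiers.
#' @return a `dist_matrix` with provenance `"taxonomic"`.
#' @export
taxonomic_distances <- function(species) {
  species <- as.character(species)
  if (anyDuplicated(species)) abort("duplicate species identifiers")
  n <- length(species)
  m <- matrix(1, n, n) - diag(n)
  dist_matrix(m, labels = species, provenance = "taxonomic")
}

#' Functional distances between species from a trait table
#'
#' Traits are standardized (mean 0, SD 1), rotated by PCA to remove the
#' dominance of correlated trait blocks, and Euclidean distances are computed
#' over the retained axes. With all axes retained (the default) the rotation
#' is distance-preserving, so the result equals the Euclidean distance on the
#' standardized traits. The matrix is then divided by its maximum so the
#' largest off-diagonal distance is 1.
#'
#' @param traits validated trait table (`species` column + numeric traits;
#'   fuzzy-coded shares and 0/1 traits are used as numeric columns).
#' @param axes number of PCA axes to keep (default `NULL`: all axes).
#' @param group_weight if `TRUE`, each fuzzy-coded column is downweighted by
#'   `1/sqrt(group size)` after standardization so a many-column category
#'   counts like one trait. Off by default.
#' @return a `dist_matrix` with provenance `"functional"`.
#' @export
functional_distances <- function(traits, axes = NULL, group_weight = FALSE) {
  traits <- validate_traits(traits, fuzzy_groups = attr(traits, "fuzzy_groups"))
  sp <- traits$species
  if (length(sp) < 2L) abort("need at least two species")
  m <- as.matrix(traits[, setdiff(names(traits), "species"), drop = FALSE])
  rownames(m) <- sp
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste("dropping zero-variance trait columns:",
               paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) == 0L) abort("no informative trait columns")
  }
  z <- scale(m)
  if (group_weight) {
    fg <- attr(traits, "fuzzy_groups")
    for (g in names(fg)) {
      colsg <- intersect(fg[[g]], colnames(z))
      z[, colsg] <- z[, colsg] / sqrt(length(colsg))
    }
  }
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(if (is.null(axes)) ncol(pc$x) else axes, ncol(pc$x))
  d <- as.matrix(dist(pc$x[, seq_len(k), drop = FALSE]))
  rescale_unit(dist_matrix(d, labels = sp, provenance = "functional"))
}

#' Prepare a phylogeny: resolve polytomies and Grafen-ultrametrize
#'
#' Polytomies are resolved at random into dichotomies with zero-length
#' inserted branches (seeded, reproducible), then every node is assigned the
#' Grafen height `((t_v - 1)/(t_root - 1))^rho` where `t_v` counts the tips
#' descended from the node; branch lengths are the height differences. The
#' result is a binary ultrametric tree with root-to-tip height 1. Because the
#' heights depend only on tip counts and inserted branches have zero length,
#' the cophenetic distances do not depend on how polytomies were resolved.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param rho Grafen exponent (default 1).
#' @param seed seed for the random polytomy resolution.
#' @param species optional species set the tree must cover.
#' @return the prepared `phylo` tree, with attributes `rho` and `seed`.
#' @export
prepare_tree <- function(tree, rho = 1, seed = 1L, species = NULL) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo object")
  # a basal polytomy (single internal node) still counts as rooted here
  if (!ape::is.rooted(tree) && tree$Nnode > 1L) abort("tree must be rooted")
  if (!is.null(species)) {
    miss <- setdiff(species, tree$tip.label)
    if (length(miss)) abort(paste("tips missing from tree:",
                                  paste(head(miss, 5), collapse = ", ")))
  }
  if (rho <= 0) abort("`rho` must be positive")
  # Grafen heights are assigned on the original topology, then polytomies
  # are resolved with zero-length inserted branches: this is the order under
  # which the cophenetic distances do not depend on the random resolution.
  tr <- ape::compute.brlen(tree, method = "Grafen", power = rho)
  tr <- with_seed_or_global(seed, ape::multi2di(tr, random = TRUE))
  attr(tr, "rho") <- rho
  attr(tr, "seed") <- seed
  tr
}

#' Cophenetic phylogenetic distances, unit-scaled
#'
#' Sums of branch lengths along tip-to-tip paths on a prepared (binary,
#' ultrametric, height-1) tree, divided by the maximum distance so the most
#' distant pair is at 1 (pairs whose most recent common ancestor is the root
#' sit at cophenetic distance 2 before scaling).
#'
#' @param tree a prepared tree (see [prepare_tree()]).
#' @return a `dist_matrix` with provenance `"phylogenetic"`, tips sorted by
#'   label order of the tree.
#' @export
phylogenetic_distances <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo object")
  d <- cophenetic(tree)
  ord <- tree$tip.label
  d <- d[ord, ord]
  rescale_unit(dist_matrix(d, labels = ord, provenance = "phylogenetic"))
}

# Independent ultrametricity check: variance of root-to-tip path lengths.
root_to_tip_depths <- function(tree) {
  nt <- ape::Ntip(tree)
  ape::node.depth.edgelength(tree)[seq_len(nt)]
}
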