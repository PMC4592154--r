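#' Rao quadratic entropy of one community
#'
#' For a presence-absence community of `S` species, the quadratic entropy is
#' `Q = sum_ij p_i p_j d_ij` with uniform weights `p_i = 1/S`: the expected
#' distance between two individuals drawn at random (with replacement across
#' species) from the community. With unit taxonomic distances this is
#' `(S - 1)/S`, and its Jost equivalent number `1/(1 - Q)` is exactly the
#' species richness `S`. `literal_sum = TRUE` instead returns the unweighted
#' sum `sum_ij d_ij` over present species, for comparison only (it grows with
#' `S^2` and the equivalent number is not defined for it).
#'
#' @param present logical/0-1 vector over the species of `d`, or a character
#'   vector of present species names.
#' @param d species `dist_matrix`, unit-scaled.
#' @param corrected return the Jost equivalent number `1/(1 - Q)` instead of
#'   raw `Q`.
#' @param literal_sum return the unweighted double sum (overrides
#'   `corrected`).
#' @return a single number.
#' @export
rao_alpha <- function(present, d, corrected = FALSE, literal_sum = FALSE) {
  idx <- presence_index(present, d)
  if (!length(idx)) abort("empty community")
  sub <- d[idx, idx, drop = FALSE]
  if (literal_sum) return(sum(sub))
  q <- sum(sub) / length(idx)^2
  if (corrected) 1 / (1 - q) else q
}

#' Rao gamma diversity of two pooled communities
#'
#' [rao_alpha()] applied to the union of the two presence vectors.
#'
#' @param present_k,present_l presence vectors (or species-name vectors) for
#'   the two communities.
#' @inheritParams rao_alpha
#' @return a single number.
#' @export
rao_gamma <- function(present_k, present_l, d, corrected = FALSE) {
  u <- union(presence_index(present_k, d), presence_index(present_l, d))
  if (!length(u)) abort("empty pooled community")
  pres <- logical(nrow(d))
  pres[u] <- TRUE
  rao_alpha(pres, d, corrected = corrected)
}

#' Pairwise Rao beta dissimilarity with Jost correction
#'
#' `beta = (gamma_c - alpha_bar_c) / gamma_c` where `gamma_c` is the Jost
#' equivalent number of the pooled pair and `alpha_bar_c` the mean of the two
#' Jost-corrected alphas (correction applied before averaging). Bounded in
#' `[0, 1]`; 0 for identical communities.
#'
#' @inheritParams rao_gamma
#' @return the beta dissimilarity.
#' @export
rao_beta_pairwise <- function(present_k, present_l, d) {
  g <- rao_gamma(present_k, present_l, d, corrected = TRUE)
  a_k <- rao_alpha(present_k, d, corrected = TRUE)
  a_l <- rao_alpha(present_l, d, corrected = TRUE)
  b <- (g - (a_k + a_l) / 2) / g
  min(max(b, 0), 1)
}

#' All-pairs Rao beta matrix of a community table
#'
#' @param comm validated community tibble (`site` column + binary species
#'   columns).
#' @param d species `dist_matrix` whose labels cover the community's species.
#' @return a site x site `dist_matrix` with provenance `"beta"`.
#' @export
rao_beta_matrix <- function(comm, d) {
  m <- community_matrix(comm)
  d <- align_distances(d, colnames(m))
  n <- nrow(m)
  if (any(rowSums(m) == 0)) abort("empty site rows are not allowed")
  pres <- lapply(seq_len(n), function(i) which(m[i, ] > 0))
  # cache per-site corrected alphas and raw within-site distance sums
  subsum <- vapply(pres, function(ix) sum(d[ix, ix]), numeric(1))
  s <- lengths(pres)
  a_corr <- 1 / (1 - subsum / s^2)
  b <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    pi_ <- pres[[i]]
    for (j in (i + 1):n) {
      u <- union(pi_, pres[[j]])
      qg <- sum(d[u, u]) / length(u)^2
      g <- 1 / (1 - qg)
      bij <- (g - (a_corr[i] + a_corr[j]) / 2) / g
      b[i, j] <- b[j, i] <- min(max(bij, 0), 1)
    }
  }
  dist_matrix(b, labels = comm$site, provenance = "beta")
}

#' Alpha diversity table for one facet
#'
#' Per-site species richness, raw Rao `Q` and Jost equivalent number.
#'
#' @inheritParams rao_beta_matrix
#' @param facet label recorded in the output (`"TD"`, `"PD"`, `"FD"`, ...).
#' @return a tibble with columns `site`, `facet`, `richness`, `Q`,
#'   `equivalent`.
#' @export
rao_alpha_table <- function(comm, d, facet = attr(d, "provenance")) {
  m <- community_matrix(comm)
  d <- align_distances(d, colnames(m))
  q <- as.numeric(apply(m, 1, function(row) rao_alpha(row > 0, d)))
  tibble::tibble(site = comm$site, facet = facet,
                 richness = as.integer(rowSums(m)),
                 Q = as.numeric(q), equivalent = 1 / (1 - q))
}

#' Alpha/beta Rao partition of a community for one distance facet
#'
#' Bundles the per-site alpha table and the pairwise beta matrix.
#'
#' @inheritParams rao_alpha_table
#' @return an object of class `rao_partition` with elements `alpha` (tibble)
#'   and `beta` (`dist_matrix`), plus the facet tag.
#' @export
rao_partition <- function(comm, d, facet = attr(d, "provenance")) {
  structure(list(alpha = rao_alpha_table(comm, d, facet),
                 beta = rao_beta_matrix(comm, d),
                 facet = facet),
            class = "rao_partition")
}

#' @export
print.rao_partition <- function(x, ...) {
  cat("Rao diversity partition (", x$facet, ")\n", sep = "")
  cat("  sites:", nrow(x$alpha), "\n")
  cat("  mean alpha equivalent:", round(mean(x$alpha$equivalent), 3), "\n")
  cat("  mean pairwise beta:  ",
      round(mean(x$beta[upper.tri(x$beta)]), 3), "\n")
  invisible(x)
}

#' Multi-community additive Rao decomposition
#'
#' Utility decomposition over all communities at once: pooled gamma
#' (equivalent number over the union with uniform weights), mean corrected
#' alpha, and the proportional beta `(gamma - alpha_bar)/gamma`. The pipeline
#' itself uses only the pairwise beta; this summary is exposed for
#' exploration.
#'
#' @inheritParams rao_beta_matrix
#' @return a tibble with one row: `gamma`, `alpha_bar`, `beta_prop`.
#' @export
rao_decompose <- function(comm, d) {
  m <- community_matrix(comm)
  d <- align_distances(d, colnames(m))
  pooled <- colSums(m) > 0
  g <- rao_alpha(pooled, d, corrected = TRUE)
  a <- mean(apply(m, 1, function(r) rao_alpha(r > 0, d, corrected = TRUE)))
  tibble::tibble(gamma = g, alpha_bar = a, beta_prop = (g - a) / g)
}

# Resolve a presence specification to integer indices into d's labels.
presence_index <- function(present, d) {
  if (is.character(present)) {
    idx <- match(present, rownames(d))
    if (anyNA(idx)) abort("species not found in distance matrix")
    return(sort(unique(idx)))
  }
  if (length(present) != nrow(d))
    abort("presence vector length must match the distance matrix")
  which(as.logical(present))
}

# Reorder/subset a species distance matrix to a species vector.
align_distances <- function(d, species) {
  if (is.null(rownames(d))) {
    if (nrow(d) != length(species)) abort("unlabelled distance matrix of wrong size")
    dimnames(d) <- list(species, species)
    return(d)
  }
  miss <- setdiff(species, rownames(d))
  if (length(miss)) abort(paste("species missing from distance matrix:",
                                paste(head(miss, 5), collapse = ", ")))
  out <- d[species, species]
  attr(out, "provenance") <- attr(d, "provenance")
  class(out) <- class(d)
  out
}
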