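#' PCNM spatial eigenfunctions from site coordinates
#'
#' Principal coordinates of neighbour matrices: (1) pairwise geographic
#' distances; (2) truncation threshold `t` = the longest edge of the minimum
#' spanning tree (the smallest distance keeping all sites connected);
#' (3) distances beyond `t` replaced by `4 t`; (4) principal coordinate
#' analysis of the truncated matrix; (5) eigenvectors with positive
#' eigenvalues retained, scaled by the square root of their eigenvalue.
#' The eigenfunctions are centred mutually orthogonal waves ordered from
#' broad to fine spatial scale; Moran's I (with the binary connectivity
#' implied by `t`) is recorded per eigenfunction so that the
#' positive-autocorrelation subset can be selected.
#'
#' @param sites site table with `x`, `y` (and optional `site`) columns, or a
#'   two-column coordinate matrix; lon/lat tables (see [validate_sites()])
#'   use great-circle distances.
#' @param truncation optional threshold overriding the MST rule.
#' @return an object of class `pcnm_basis`: `vectors` (tibble `site` +
#'   `PCNM1..k`), `values` (eigenvalues), `threshold`, `moran` (per-function
#'   Moran's I) and `positive_moran` (logical filter).
#' @export
pcnm_basis <- function(sites, truncation = NULL) {
  if (is.matrix(sites)) {
    sites <- tibble::tibble(site = as.character(seq_len(nrow(sites))),
                            x = sites[, 1], y = sites[, 2])
  }
  if (!"site" %in% names(sites))
    sites <- dplyr::mutate(sites, site = as.character(dplyr::row_number()))
  n <- nrow(sites)
  if (n < 3L) abort("need at least 3 sites")
  dgeo <- geographic_distances(validate_sites(sites,
                                              lonlat = isTRUE(attr(sites, "lonlat"))))
  if (max(dgeo) == 0) abort("all sites are collocated")
  t_thr <- if (is.null(truncation)) max(vegan::spantree(as.dist(dgeo))$dist)
           else truncation
  dtrunc <- unclass(dgeo)
  dtrunc[dtrunc > t_thr] <- 4 * t_thr
  eig <- eigen(double_center(dtrunc), symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  if (!any(keep)) abort("no positive eigenvalues")
  vals <- eig$values[keep]
  vecs <- sweep(eig$vectors[, keep, drop = FALSE], 2, sqrt(vals), `*`)
  colnames(vecs) <- paste0("PCNM", seq_len(ncol(vecs)))
  w <- (unclass(dgeo) <= t_thr) + 0
  diag(w) <- 0
  mor <- apply(vecs, 2, function(v) morans_i(v, w))
  structure(list(vectors = dplyr::bind_cols(tibble::tibble(site = sites$site),
                                            tibble::as_tibble(vecs)),
                 values = vals, threshold = t_thr, moran = mor,
                 positive_moran = mor > -1 / (n - 1)),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat("PCNM basis:", length(x$values), "positive-eigenvalue eigenfunctions (",
      sum(x$positive_moran), "with positive Moran's I ), threshold =",
      signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Extract PCNM eigenfunctions as a predictor tibble
#'
#' @param basis a [pcnm_basis()] object.
#' @param positive_moran keep only eigenfunctions whose Moran's I exceeds the
#'   null expectation `-1/(n-1)` (the broad-scale, positively autocorrelated
#'   waves used as spatial predictors).
#' @return tibble of `site` + eigenfunction columns.
#' @export
pcnm_scores <- function(basis, positive_moran = TRUE) {
  v <- basis$vectors
  if (positive_moran) {
    keep <- c(TRUE, basis$positive_moran)
    v <- v[, keep, drop = FALSE]
  }
  v
}

#' Moran's I spatial autocorrelation coefficient
#'
#' `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W` the sum of weights. Expectation under no autocorrelation is
#' `-1/(n-1)`.
#'
#' @param x numeric values, one per site.
#' @param w non-negative spatial weight matrix, zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(x, w) {
  n <- length(x)
  if (n < 3L) abort("need at least 3 values")
  if (!is.matrix(w) || any(dim(w) != n)) abort("weight matrix of wrong size")
  if (any(w < 0) || any(diag(w) != 0)) abort("weights must be non-negative with zero diagonal")
  W <- sum(w)
  if (W == 0) abort("all-zero weights")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) abort("constant values")
  (n / W) * drop(crossprod(z, w %*% z)) / ss
}

#' Moran's I correlogram with permutation tests
#'
#' Splits the inter-site distances into classes (equal width by default),
#' computes Moran's I with binary membership weights per class, and attaches
#' a two-sided permutation p-value from random relabelling of the values
#' across sites. Empty classes are merged into their left neighbour with a
#' warning.
#'
#' @param x numeric site values.
#' @param sites site table (or coordinate matrix) as in [pcnm_basis()].
#' @param n_classes number of distance classes (default: Sturges' rule on the
#'   number of site pairs).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a tibble of class `moran_correlogram`: `class`, `lower`, `upper`,
#'   `n_pairs`, `moran_i`, `p_value`.
#' @export
morans_correlogram <- function(x, sites, n_classes = NULL, n_perm = 999,
                               seed = NULL) {
  if (is.matrix(sites)) sites <- tibble::tibble(site = as.character(seq_len(nrow(sites))),
                                                x = sites[, 1], y = sites[, 2])
  dgeo <- unclass(geographic_distances(validate_sites(sites,
                                                      lonlat = isTRUE(attr(sites, "lonlat")))))
  n <- length(x)
  if (is.null(n_classes))
    n_classes <- max(2L, ceiling(log2(n * (n - 1) / 2) + 1))
  brks <- seq(0, max(dgeo), length.out = n_classes + 1)
  res <- vector("list", n_classes)
  perms <- with_seed_or_global(seed,
    replicate(n_perm, sample.int(n), simplify = FALSE))
  lower <- brks[-length(brks)]
  upper <- brks[-1]
  i <- 1L
  out <- list()
  while (i <= n_classes) {
    lo <- lower[i]; up <- upper[i]
    w <- (dgeo > lo & dgeo <= up) + 0
    diag(w) <- 0
    j <- i
    while (sum(w) == 0 && j < n_classes) {
      warn("empty distance class merged with neighbour")
      j <- j + 1L
      up <- upper[j]
      w <- (dgeo > lo & dgeo <= up) + 0
      diag(w) <- 0
    }
    i_obs <- morans_i(x, w)
    e_i <- -1 / (n - 1)
    i_perm <- vapply(perms, function(p) morans_i(x[p], w), numeric(1))
    p <- (sum(abs(i_perm - e_i) >= abs(i_obs - e_i) - 1e-12) + 1) / (n_perm + 1)
    out[[length(out) + 1L]] <- tibble::tibble(
      class = length(out) + 1L, lower = lo, upper = up,
      n_pairs = sum(w) / 2, moran_i = i_obs, p_value = p)
    i <- j + 1L
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("moran_correlogram", class(res))
  res
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with a one-sided
#' permutation test permuting the rows and columns of the second matrix
#' jointly.
#'
#' @param d1,d2 conformable symmetric matrices (>= 4 objects).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a tibble: `statistic` (Mantel r), `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4L || any(dim(d2) != n)) abort("need conformable matrices with >= 4 objects")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0) abort("zero variance in a distance triangle")
  r_obs <- cor(v1, d2[lt])
  r_perm <- with_seed_or_global(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(v1, d2[p, p][lt])
  }, numeric(1)))
  tibble::tibble(statistic = r_obs,
                 p_value = perm_pvalue(r_perm, r_obs),
                 n_perm = n_perm)
}

#' Mantel correlogram (distance-class Mantel statistics)
#'
#' For each geographic distance class, correlates membership in the class
#' with the response dissimilarities (a standard multivariate correlogram):
#' the statistic is the Mantel r between the response matrix and the binary
#' within-class contrast, sign-flipped so positive values mean sites in the
#' class are more similar than average.
#'
#' @param d response `dist_matrix` (e.g. a Rao beta matrix).
#' @param sites site table or coordinate matrix.
#' @inheritParams morans_correlogram
#' @return tibble of class `mantel_correlogram`: per class bounds, `mantel_r`
#'   and permutation `p_value`.
#' @export
mantel_correlogram <- function(d, sites, n_classes = NULL, n_perm = 999,
                               seed = NULL) {
  if (is.matrix(sites) && !is.data.frame(sites))
    sites <- tibble::tibble(site = as.character(seq_len(nrow(sites))),
                            x = sites[, 1], y = sites[, 2])
  dgeo <- unclass(geographic_distances(validate_sites(sites,
                                                      lonlat = isTRUE(attr(sites, "lonlat")))))
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n_classes))
    n_classes <- max(2L, ceiling(log2(n * (n - 1) / 2) + 1))
  brks <- seq(0, max(dgeo), length.out = n_classes + 1)
  lt <- lower.tri(d)
  v <- d[lt]
  perms <- with_seed_or_global(seed,
    replicate(n_perm, sample.int(n), simplify = FALSE))
  out <- list()
  for (i in seq_len(n_classes)) {
    inclass <- (dgeo > brks[i] & dgeo <= brks[i + 1])[lt]
    if (!any(inclass) || all(inclass)) next
    m <- inclass + 0
    r_obs <- -cor(v, m)
    r_perm <- vapply(perms, function(p) -cor(d[p, p][lt], m), numeric(1))
    p <- (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
    out[[length(out) + 1L]] <- tibble::tibble(
      class = length(out) + 1L, lower = brks[i], upper = brks[i + 1],
      n_pairs = sum(inclass), mantel_r = r_obs, p_value = p)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("mantel_correlogram", class(res))
  res
}

# Gower double-centering of a squared-distance transform: -0.5 * (I-11'/n) D^2 (I-11'/n)
double_center <- function(d) {
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  a - outer(rm_, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) + mean(a)
}
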