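# Shared fixtures and independent oracles used across test files.

# Balanced 4-tip binary tree: ((A,B),(C,D)); with Grafen heights the two
# cherries sit at height 1/3 and the root at 1.
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# Brute-force Rao Q: explicit double loop over species pairs, p_i = 1/S.
rao_oracle <- function(pres, d) {
  ix <- which(pres > 0)
  s <- length(ix)
  tot <- 0
  for (i in ix) for (j in ix) tot <- tot + d[i, j]
  tot / s^2
}

# Brute-force pairwise beta from corrected alphas/gamma.
beta_oracle <- function(pk, pl, d) {
  corr <- function(p) 1 / (1 - rao_oracle(p, d))
  u <- as.numeric(pk | pl)
  g <- corr(u)
  (g - (corr(pk) + corr(pl)) / 2) / g
}

# Random unit-scaled species distance matrix.
random_dist <- function(n_sp, seed) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n_sp * 3), n_sp)
    d <- as.matrix(dist(pts))
    d <- d / max(d)
    dimnames(d) <- list(paste0("sp", 1:n_sp), paste0("sp", 1:n_sp))
    dist_matrix(d, provenance = "functional")
  })
}

# Random community tibble with no empty sites/species.
random_community <- function(n_sites, n_sp, seed, p = 0.5) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(rbinom(n_sites * n_sp, 1, p), n_sites)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    colnames(m) <- paste0("sp", 1:n_sp)
    dplyr::bind_cols(tibble::tibble(site = paste0("s", 1:n_sites)),
                     tibble::as_tibble(m))
  })
}

# Dense-eigendecomposition PCNM oracle: full PCoA of the truncated matrix.
pcnm_oracle <- function(xy, t_thr) {
  d <- as.matrix(dist(xy))
  d[d > t_thr] <- 4 * t_thr
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  list(values = e$values[keep],
       vectors = sweep(e$vectors[, keep, drop = FALSE], 2,
                       sqrt(e$values[keep]), `*`))
}
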