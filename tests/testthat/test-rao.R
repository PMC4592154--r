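test_that("alpha Rao handles the degenerate closed forms", {
  d <- taxonomic_distances(paste0("sp", 1:4))
  one <- c(1, 0, 0, 0)
  expect_equal(rao_alpha(one, d), 0)
  expect_equal(rao_alpha(one, d, corrected = TRUE), 1)
  # S = 4 taxonomic: Q = (S-1)/S, equivalent number = S
  all4 <- rep(1, 4)
  expect_equal(rao_alpha(all4, d), 0.75)
  expect_equal(rao_alpha(all4, d, corrected = TRUE), 4)
  # two species at functional distance zero
  dz <- dist_matrix(matrix(0, 2, 2), labels = c("a", "b"),
                    provenance = "functional")
  expect_warning(dz2 <- rescale_unit(dz), "unscaled")
  expect_equal(rao_alpha(c(1, 1), dz2), 0)
  expect_equal(rao_alpha(c(1, 1), dz2, corrected = TRUE), 1)
  expect_error(rao_alpha(c(0, 0, 0, 0), d), "empty")
  # literal unweighted sum grows as S(S-1) for unit distances
  expect_equal(rao_alpha(all4, d, literal_sum = TRUE), 12)
})

test_that("corrected taxonomic alpha equals species richness for S = 1..50", {
  d <- taxonomic_distances(paste0("sp", 1:50))
  for (s in 1:50) {
    pres <- c(rep(1, s), rep(0, 50 - s))
    expect_equal(rao_alpha(pres, d, corrected = TRUE), s, tolerance = 1e-12)
  }
})

test_that("alpha and beta match the brute-force double-loop oracle", {
  for (rep_i in 1:25) {
    n_sp <- sample(5:30, 1)
    d <- random_dist(n_sp, seed = 1000 + rep_i)
    withr::with_seed(rep_i, {
      pk <- rbinom(n_sp, 1, 0.5); pk[sample(n_sp, 1)] <- 1
      pl <- rbinom(n_sp, 1, 0.5); pl[sample(n_sp, 1)] <- 1
    })
    expect_equal(rao_alpha(pk, d), rao_oracle(pk, d), tolerance = 1e-12)
    expect_equal(rao_beta_pairwise(pk, pl, d),
                 max(0, beta_oracle(pk == 1, pl == 1, d)), tolerance = 1e-12)
  }
})

test_that("gamma pools the union of the two communities", {
  d <- taxonomic_distances(paste0("sp", 1:6))
  k <- c(1, 1, 0, 0, 0, 0)
  expect_equal(rao_gamma(k, k, d, corrected = TRUE),
               rao_alpha(k, d, corrected = TRUE))
  # disjoint 2 + 2 species -> corrected gamma = 4
  l <- c(0, 0, 1, 1, 0, 0)
  expect_equal(rao_gamma(k, l, d, corrected = TRUE), 4, tolerance = 1e-12)
  # nested: union equals the larger community
  big <- c(1, 1, 1, 1, 0, 0)
  expect_equal(rao_gamma(k, big, d), rao_alpha(big, d))
})

test_that("pairwise beta reproduces the closed-form taxonomic cases", {
  d <- taxonomic_distances(paste0("sp", 1:8))
  k <- c(1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(rao_beta_pairwise(k, k, d), 0)
  # disjoint equal-size communities: gamma = 2S, alpha-bar = S, beta = 1/2
  for (s in 1:4) {
    a <- c(rep(1, s), rep(0, 8 - s))
    b <- c(rep(0, s), rep(1, s), rep(0, 8 - 2 * s))
    expect_equal(rao_beta_pairwise(a, b, d), 0.5, tolerance = 1e-12)
  }
  # {a,b} vs {a,b,c,d}: gamma = 4, alpha-bar = 3, beta = 1/4
  ab <- c(1, 1, 0, 0, 0, 0, 0, 0)
  abcd <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(rao_beta_pairwise(ab, abcd, d), 0.25, tolerance = 1e-12)
})

test_that("beta is symmetric and invariant to species relabelling", {
  d <- random_dist(12, seed = 77)
  withr::with_seed(42, {
    pk <- rbinom(12, 1, 0.5); pk[1] <- 1
    pl <- rbinom(12, 1, 0.5); pl[2] <- 1
    perm <- sample(12)
  })
  expect_equal(rao_beta_pairwise(pk, pl, d), rao_beta_pairwise(pl, pk, d))
  dp <- dist_matrix(unclass(d)[perm, perm], provenance = "functional")
  expect_equal(rao_beta_pairwise(pk[perm], pl[perm], dp),
               rao_beta_pairwise(pk, pl, d), tolerance = 1e-12)
})

test_that("the beta matrix agrees with per-pair computation and permutes with sites", {
  comm <- random_community(5, 10, seed = 6)
  d <- random_dist(10, seed = 60)
  b <- rao_beta_matrix(comm, d)
  m <- as.matrix(comm[, -1])
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(b[i, j], rao_beta_pairwise(m[i, ], m[j, ], d),
                 tolerance = 1e-12)
  }
  expect_true(all(diag(b) == 0))
  expect_identical(attr(b, "provenance"), "beta")
  # permuting site rows permutes the matrix consistently
  ord <- c(3, 1, 5, 2, 4)
  b2 <- rao_beta_matrix(comm[ord, ], d)
  expect_equal(unclass(b2), unclass(b)[ord, ord], tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical sites give an all-zero matrix
  same <- comm; for (i in 2:5) same[i, -1] <- same[1, -1]
  expect_equal(max(rao_beta_matrix(same, d)), 0)
})

test_that("unit-bounded distances make functional/phylogenetic Q at most taxonomic Q", {
  dtax <- taxonomic_distances(paste0("sp", 1:15))
  dfun <- random_dist(15, seed = 5)
  for (i in 1:20) {
    pres <- withr::with_seed(200 + i, {p <- rbinom(15, 1, 0.5); p[1] <- 1; p})
    expect_lte(rao_alpha(pres, dfun), rao_alpha(pres, dtax) + 1e-12)
  }
})

test_that("multi-community decomposition is coherent with its parts", {
  comm <- random_community(6, 12, seed = 14)
  d <- random_dist(12, seed = 15)
  dec <- rao_decompose(comm, d)
  expect_gte(dec$gamma + 1e-12, dec$alpha_bar)
  expect_gte(dec$beta_prop, 0)
  expect_lte(dec$beta_prop, 1)
})

test_that("alpha tables carry facet tags and Jost equivalents", {
  comm <- random_community(4, 8, seed = 21)
  d <- taxonomic_distances(paste0("sp", 1:8))
  tab <- rao_alpha_table(comm, d, facet = "TD")
  expect_identical(tab$facet, rep("TD", 4))
  expect_equal(tab$equivalent, tab$richness, tolerance = 1e-12)
  part <- rao_partition(comm, d, facet = "TD")
  expect_s3_class(tidy(part), "tbl_df")
  expect_equal(glance(part)$n_sites, 4L)
})
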