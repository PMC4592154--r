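test_that("PCNM basis matches the dense-eigendecomposition oracle and vegan", {
  withr::with_seed(10, xy <- matrix(runif(60), 30))
  basis <- pcnm_basis(xy)
  oracle <- pcnm_oracle(xy, basis$threshold)
  expect_equal(basis$values, oracle$values, tolerance = 1e-8)
  v <- as.matrix(basis$vectors[, -1])
  for (i in seq_along(basis$values)) {
    expect_equal(abs(cor(v[, i], oracle$vectors[, i])), 1, tolerance = 1e-6)
  }
  # vegan as an independent cross-check: same count, eigenvalues, spaces
  pv <- vegan::pcnm(dist(xy))
  pos <- pv$values > max(pv$values) * 1e-10
  expect_equal(length(basis$values), sum(pos))
  expect_equal(basis$values, pv$values[pos], tolerance = 1e-8)
})

test_that("PCNM eigenfunctions are centred and mutually orthogonal", {
  withr::with_seed(3, xy <- matrix(runif(50), 25))
  v <- as.matrix(pcnm_basis(xy)$vectors[, -1])
  expect_lt(max(abs(colMeans(v))), 1e-8)
  g <- crossprod(v)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("the first transect eigenfunction is a broad-scale sine wave", {
  n <- 10
  basis <- pcnm_basis(cbind(1:n, 0))
  expect_equal(basis$threshold, 1)
  v1 <- basis$vectors$PCNM1
  # the construction yields exactly sin(2*pi*i/(n+1)) on the regular transect
  expect_gt(abs(cor(v1, sin(2 * pi * (1:n) / (n + 1)))), 0.97)
  # oracle agreement on eigenvector count for the transect
  oracle <- pcnm_oracle(cbind(1:n, 0), 1)
  expect_identical(length(basis$values), length(oracle$values))
})

test_that("MST truncation is the minimax connection distance", {
  withr::with_seed(8, xy <- matrix(runif(40), 20))
  basis <- pcnm_basis(xy)
  d <- as.matrix(dist(xy))
  connected_at <- function(thr) {
    adj <- d <= thr
    diag(adj) <- FALSE
    reach <- logical(nrow(d)); reach[1] <- TRUE
    repeat {
      new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
      if (identical(new, reach)) break
      reach <- new
    }
    all(reach)
  }
  expect_true(connected_at(basis$threshold))
  below <- max(d[d < basis$threshold - 1e-12])
  expect_false(connected_at(below))
})

test_that("Moran's I matches hand evaluation and its null expectation", {
  # perfect alternation on a 4-cycle
  w4 <- matrix(0, 4, 4)
  w4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  w4 <- w4 + t(w4)
  expect_equal(morans_i(c(1, -1, 1, -1), w4), -1)
  # linear gradient with nearest-neighbour weights is positively autocorrelated
  n <- 12
  wnn <- matrix(0, n, n)
  wnn[cbind(1:(n - 1), 2:n)] <- 1
  wnn <- wnn + t(wnn)
  expect_gt(morans_i(1:n, wnn), 0)
  # Monte-Carlo mean of I under permutation is about -1/(n-1)
  x <- withr::with_seed(2, rnorm(n))
  sims <- withr::with_seed(3,
    replicate(3000, morans_i(sample(x), wnn)))
  expect_lt(abs(mean(sims) - (-1 / (n - 1))), 0.015)
  expect_error(morans_i(rep(1, n), wnn), "constant")
  expect_error(morans_i(1:n, wnn * 0), "all-zero")
})

test_that("Moran correlogram flags short-range structure in a gradient", {
  withr::with_seed(21, {
    xy <- matrix(runif(80), 40)
    x <- xy[, 1] * 3 + rnorm(40, sd = 0.3)
  })
  cg <- morans_correlogram(x, xy, n_classes = 5, n_perm = 999, seed = 9)
  expect_s3_class(cg, "moran_correlogram")
  expect_gt(cg$moran_i[1], 0)
  expect_lt(cg$p_value[1], 0.05)
  expect_true(all(cg$p_value >= 1 / 1000 & cg$p_value <= 1))
  expect_equal(cg$lower[1], 0)
})

test_that("Moran correlogram type-I error is near nominal on white noise", {
  rejections <- 0L
  classes <- 0L
  for (i in 1:30) {
    withr::with_seed(400 + i, {
      xy <- matrix(runif(60), 30)
      x <- rnorm(30)
    })
    cg <- morans_correlogram(x, xy, n_classes = 4, n_perm = 199,
                             seed = 500 + i)
    rejections <- rejections + sum(cg$p_value < 0.05)
    classes <- classes + nrow(cg)
  }
  expect_lt(rejections / classes, 0.15)
})

test_that("Mantel statistic equals direct Pearson on the triangles", {
  d1 <- as.matrix(dist(matrix(withr::with_seed(1, rnorm(8)), 4)))
  d2 <- as.matrix(dist(matrix(withr::with_seed(2, rnorm(8)), 4)))
  mt <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, cor(d1[lower.tri(d1)], d2[lower.tri(d2)]),
               tolerance = 1e-12)
  # identity: r = 1 and minimal p
  self <- mantel_test(d1, d1, n_perm = 99, seed = 2)
  expect_equal(self$statistic, 1)
  expect_true(all(mt$p_value >= 1 / 100 & mt$p_value <= 1))
  # invariance under joint relabelling of both matrices
  perm <- c(3, 1, 4, 2)
  mt2 <- mantel_test(d1[perm, perm], d2[perm, perm], n_perm = 99, seed = 1)
  expect_equal(mt2$statistic, mt$statistic, tolerance = 1e-12)
  # vegan cross-check of the statistic
  expect_equal(mt$statistic,
               unname(vegan::mantel(as.dist(d1), as.dist(d2),
                                    permutations = 5)$statistic),
               tolerance = 1e-10)
})

test_that("Mantel test keeps its nominal size under independence", {
  hits <- 0L
  for (i in 1:60) {
    withr::with_seed(700 + i, {
      d1 <- as.matrix(dist(matrix(rnorm(24), 12)))
      d2 <- as.matrix(dist(matrix(rnorm(24), 12)))
    })
    p <- mantel_test(d1, d2, n_perm = 99, seed = 800 + i)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_lt(hits / 60, 0.15)
})
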