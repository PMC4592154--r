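test_that("PCoA recovers planar configurations and the equilateral spectrum", {
  withr::with_seed(4, pts <- matrix(rnorm(16), 8))
  d <- as.matrix(dist(pts))
  ax <- pcoa_axes(dist_matrix(d, labels = paste0("s", 1:8), provenance = "beta"),
                  criterion = "fixed", k = 2)
  rec <- as.matrix(dist(as.matrix(ax$points[, -1])))
  expect_equal(rec, d, tolerance = 1e-8, ignore_attr = TRUE)
  # 3-object equilateral matrix: two equal positive eigenvalues of 1/2
  eq <- matrix(1, 3, 3) - diag(3)
  e <- pcoa_axes(dist_matrix(eq, labels = letters[1:3], provenance = "beta"),
                 criterion = "all_positive")
  expect_equal(sort(e$eig[e$eig > 1e-10]), c(0.5, 0.5), tolerance = 1e-10)
  # spectral conservation: positive eigenvalue sum = squared coordinate sum
  expect_equal(sum(e$eig[e$eig > 0]),
               sum(as.matrix(e$all_points[, -1])^2), tolerance = 1e-8)
  expect_error(pcoa_axes(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("broken-stick retention keeps leading dominant axes only", {
  withr::with_seed(9, {
    base <- matrix(rnorm(40), 20, 2) %*% diag(c(5, 3))
    noise <- matrix(rnorm(20 * 6, sd = 0.1), 20)
  })
  d <- as.matrix(dist(cbind(base, noise)))
  ax <- pcoa_axes(dist_matrix(d, labels = paste0("s", 1:20), provenance = "beta"))
  expect_gte(ax$retained, 1)
  expect_lte(ax$retained, 3)
})

test_that("RDA R2 and Ezekiel adjustment match closed forms and vegan", {
  # exact linear response -> R2 = 1
  withr::with_seed(12, x <- matrix(rnorm(40), 20))
  y_exact <- x %*% matrix(c(1, 2, -1, 0.5), 2)
  expect_equal(rda_fit(y_exact, x)$r2, 1, tolerance = 1e-12)
  # Ezekiel: R2 = 0.5, n = 11, p = 2 -> 0.375
  expect_equal(1 - (1 - 0.5) * (11 - 1) / (11 - 2 - 1), 0.375)
  withr::with_seed(13, {
    y <- matrix(rnorm(11 * 2), 11)
    xx <- matrix(rnorm(11 * 2), 11)
  })
  f <- rda_fit(y, xx)
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * 10 / 8, tolerance = 1e-12)
  # univariate: R2 equals the squared Pearson correlation
  withr::with_seed(14, {
    x1 <- rnorm(30)
    y1 <- 2 * x1 + rnorm(30)
  })
  expect_equal(rda_fit(cbind(y1), cbind(x1))$r2, cor(x1, y1)^2,
               tolerance = 1e-12)
  # vegan cross-check on a multivariate fit
  withr::with_seed(15, {
    ym <- matrix(rnorm(25 * 3), 25)
    xm <- matrix(rnorm(25 * 2), 25)
  })
  fm <- rda_fit(ym, xm)
  vr <- vegan::RsquareAdj(vegan::rda(ym ~ xm))
  expect_equal(fm$r2, vr$r.squared, tolerance = 1e-10)
  expect_equal(fm$adj_r2, vr$adj.r.squared, tolerance = 1e-10)
  # constrained + residual = total
  expect_equal(fm$ss_fit + fm$ss_res, fm$ss_tot, tolerance = 1e-8)
})

test_that("collinear predictors are aliased with a warning", {
  withr::with_seed(16, x <- rnorm(20))
  xx <- cbind(a = x, b = 2 * x)
  y <- cbind(withr::with_seed(17, rnorm(20)))
  expect_warning(f <- rda_fit(y, xx), "aliased")
  expect_equal(f$rank, 1L)
})

test_that("permutation p-values respect their bounds and detect structure", {
  withr::with_seed(20, {
    x <- matrix(rnorm(30), 30)
    y <- cbind(x[, 1] * 1)
  })
  f <- rda_fit(y, x)
  t1 <- rda_perm_test(f, n_perm = 99, seed = 5)
  expect_equal(t1$p_value, 1 / 100)  # perfectly explained response
  withr::with_seed(21, {
    y2 <- cbind(rnorm(30))
  })
  t2 <- rda_perm_test(rda_fit(y2, x), n_perm = 99, seed = 6)
  expect_gte(t2$p_value, 1 / 100)
  expect_lte(t2$p_value, 1)
})

test_that("the permutation test keeps its nominal size under the null", {
  hits <- 0L
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    withr::with_seed(3000 + i, {
      y <- cbind(rnorm(25))
      x <- matrix(rnorm(50), 25)
    })
    p <- rda_perm_test(rda_fit(y, x), n_perm = 99, seed = 4000 + i)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_lt(hits / n_rep, 0.11)
  expect_gt(hits / n_rep, 0.005)
})

test_that("forward selection retains an obvious predictor and reports gains", {
  withr::with_seed(30, {
    x <- matrix(rnorm(200), 50)
    colnames(x) <- c("true", "noise1", "noise2", "noise3")
    y <- cbind(x[, "true"])
  })
  fs <- forward_select(y, x, n_perm = 199, seed = 7)
  expect_identical(fs$selected$variable[1], "true")
  expect_gt(max(fs$selected$adj_r2_cum), 0.99)
  # cumulative adjusted R2 is non-decreasing, all retained p < alpha
  expect_true(all(diff(c(0, fs$selected$adj_r2_cum)) > -1e-12))
  expect_true(all(fs$selected$p_value < 0.05))
  expect_s3_class(tidy(fs), "tbl_df")
  expect_identical(glance(fs)$n_selected, nrow(fs$selected))
})

test_that("the global gate blocks selection on pure noise", {
  picked <- 0L
  for (i in 1:40) {
    withr::with_seed(5000 + i, {
      y <- cbind(rnorm(40))
      x <- matrix(rnorm(40 * 5), 40)
      colnames(x) <- paste0("n", 1:5)
    })
    fs <- forward_select(y, x, n_perm = 99, seed = 6000 + i)
    picked <- picked + (nrow(fs$selected) > 0)
  }
  expect_lt(picked / 40, 0.2)
})

test_that("variation partitioning satisfies its algebraic identities", {
  withr::with_seed(40, {
    y <- matrix(rnorm(60), 30)
    xe <- matrix(rnorm(60), 30); colnames(xe) <- c("e1", "e2")
    xs <- matrix(rnorm(60), 30); colnames(xs) <- c("s1", "s2")
  })
  vp <- variation_partition(y, xe, xs, n_perm = 99, seed = 8)
  fr <- setNames(vp$fractions$adj_r2, vp$fractions$fraction)
  expect_equal(sum(fr), 1, tolerance = 1e-8)
  expect_equal(fr[["a"]] + fr[["b"]], rda_fit(y, xe)$adj_r2, tolerance = 1e-8)
  expect_equal(fr[["b"]] + fr[["c"]], rda_fit(y, xs)$adj_r2, tolerance = 1e-8)
  expect_equal(fr[["a"]] + fr[["b"]] + fr[["c"]],
               rda_fit(y, cbind(xe, xs))$adj_r2, tolerance = 1e-8)
  # vegan::varpart cross-check (its [b]/[c] labels are swapped for 2 sets)
  vv <- vegan::varpart(y, xe, xs)$part$indfract$Adj.R.squared
  expect_equal(unname(fr), unname(c(vv[1], vv[3], vv[2], vv[4])),
               tolerance = 1e-8)
  expect_s3_class(tidy(vp), "tbl_df")
  expect_equal(glance(vp)$adj_r2_env, fr[["a"]] + fr[["b"]], tolerance = 1e-10)
})

test_that("identical predictor sets put everything in the shared fraction", {
  withr::with_seed(41, {
    x <- matrix(rnorm(60), 30); colnames(x) <- c("v1", "v2")
    y <- cbind(x %*% c(1, -1) + rnorm(30, sd = 0.5))
  })
  vp <- suppressWarnings(variation_partition(y, x, x, n_perm = 0))
  fr <- setNames(vp$fractions$adj_r2, vp$fractions$fraction)
  expect_equal(fr[["a"]], 0, tolerance = 1e-8)
  expect_equal(fr[["c"]], 0, tolerance = 1e-8)
  expect_equal(fr[["b"]], rda_fit(y, x)$adj_r2, tolerance = 1e-8)
})

test_that("aliasing inside a predictor set keeps the partition identities", {
  withr::with_seed(42, {
    xe <- matrix(rnorm(60), 30)
    xe <- cbind(xe, xe[, 1])  # rank-deficient env set
    colnames(xe) <- c("e1", "e2", "dup")
    xs <- matrix(rnorm(60), 30); colnames(xs) <- c("s1", "s2")
    y <- matrix(rnorm(60), 30)
  })
  vp <- suppressWarnings(variation_partition(y, xe, xs, n_perm = 0))
  expect_equal(sum(vp$fractions$adj_r2), 1, tolerance = 1e-8)
})

test_that("distance-based RDA equals RDA on embedding coordinates", {
  # rotation invariance: R2 from PCoA axes of Euclidean distances matches
  # R2 from the raw coordinates
  withr::with_seed(43, {
    pts <- matrix(rnorm(40), 20)
    x <- matrix(rnorm(40), 20)
  })
  d <- dist_matrix(as.matrix(dist(pts)), labels = paste0("s", 1:20),
                   provenance = "beta")
  ax <- pcoa_axes(d, criterion = "all_positive")
  f1 <- rda_fit(as.matrix(ax$all_points[, -1]), x)
  f2 <- rda_fit(pts, x)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("adjusted R2 of pure noise is centred on zero", {
  vals <- vapply(1:300, function(i) {
    withr::with_seed(9000 + i, {
      y <- cbind(rnorm(50))
      x <- matrix(rnorm(150), 50)
    })
    rda_fit(y, x)$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.015)
})
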