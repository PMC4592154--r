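#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Gower double-centering followed by eigendecomposition; axes are the
#' eigenvectors scaled by the square root of their eigenvalues, so Euclidean
#' distances among the scores reproduce Euclidean-embeddable input distances.
#' Negative eigenvalues are reported; an optional Lingoes correction (adding
#' a constant to squared off-diagonal dissimilarities) is available for
#' strongly non-Euclidean matrices. The "significant" axes used as a
#' response table downstream are chosen by the broken-stick criterion by
#' default.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param criterion axis-retention rule: `"broken_stick"` (leading axes whose
#'   relative eigenvalue exceeds the broken-stick expectation),
#'   `"all_positive"`, or `"fixed"` (first `k`).
#' @param k number of axes when `criterion = "fixed"`.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return an object of class `pcoa_axes`: `points` (tibble `site` + axes,
#'   retained axes only), `all_points` (every positive axis), `eig` (all
#'   eigenvalues), `retained`, `negative_share`.
#' @export
pcoa_axes <- function(d, criterion = c("broken_stick", "all_positive", "fixed"),
                      k = 2L, correction = c("none", "lingoes")) {
  criterion <- match.arg(criterion)
  correction <- match.arg(correction)
  labels <- rownames(d)
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) abort("dissimilarity matrix must be symmetric")
  if (correction == "lingoes") {
    e_min <- min(eigen(double_center(d), symmetric = TRUE,
                       only.values = TRUE)$values)
    if (e_min < 0) {
      c2 <- -e_min
      d2 <- d^2 + 2 * c2
      diag(d2) <- 0
      d <- sqrt(d2)
    }
  }
  eig <- eigen(double_center(d), symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  neg_share <- sum(pmax(-eig$values, 0)) / sum(pmax(eig$values, 0))
  if (neg_share > 0.05)
    inform(sprintf("negative PCoA eigenvalues amount to %.1f%% of the positive sum",
                   100 * neg_share))
  vals <- eig$values[pos]
  vecs <- sweep(eig$vectors[, pos, drop = FALSE], 2, sqrt(vals), `*`)
  colnames(vecs) <- paste0("axis", seq_len(ncol(vecs)))
  n_keep <- switch(criterion,
    all_positive = length(vals),
    fixed = min(k, length(vals)),
    broken_stick = {
      p <- length(vals)
      bs <- rev(cumsum(1 / rev(seq_len(p)))) / p
      rel <- vals / sum(vals)
      above <- rel > bs
      if (!above[1]) 1L else max(which(cumsum(!above) == 0))
    })
  n_keep <- max(1L, n_keep)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  pts <- function(j) dplyr::bind_cols(
    tibble::tibble(site = labels),
    tibble::as_tibble(vecs[, seq_len(j), drop = FALSE]))
  structure(list(points = pts(n_keep), all_points = pts(length(vals)),
                 eig = eig$values, retained = n_keep,
                 negative_share = neg_share),
            class = "pcoa_axes")
}

#' @export
print.pcoa_axes <- function(x, ...) {
  cat("PCoA:", sum(x$eig > 0), "positive axes,", x$retained, "retained\n")
  invisible(x)
}

#' Redundancy analysis (multivariate linear regression ordination)
#'
#' Regresses a (multi-column) response table on a predictor table, both
#' centred; `R^2` is the share of total response variance captured by the
#' fitted values and is adjusted with Ezekiel's formula
#' `1 - (1 - R^2) (n - 1)/(n - p - 1)`. With a conditioning table `z` the
#' model is a partial RDA: response and predictors are residualized on `z`
#' first, and `R^2` quantifies the semi-partial (additional) variance share.
#' Collinear predictor columns are dropped with a warning.
#'
#' @param response data frame (or matrix) of response columns; an id column
#'   named `site` is ignored.
#' @param predictors data frame/matrix of predictors.
#' @param z optional conditioning data frame/matrix (partial RDA).
#' @return an object of class `rda_fit` with elements `r2`, `adj_r2`,
#'   `pseudo_f`, `rank`, `n`, residual/total sums of squares, and the
#'   matrices needed by the permutation test.
#' @export
rda_fit <- function(response, predictors, z = NULL) {
  y <- scale(numeric_matrix(response), scale = FALSE)
  x <- scale(numeric_matrix(predictors), scale = FALSE)
  n <- nrow(y)
  if (nrow(x) != n) abort("response and predictors differ in rows")
  zc <- if (!is.null(z)) scale(numeric_matrix(z), scale = FALSE)
  qz <- NULL; rank_z <- 0L
  if (!is.null(zc)) {
    qrz <- qr(zc)
    rank_z <- qrz$rank
    qz <- qr.Q(qrz)[, seq_len(rank_z), drop = FALSE]
    y_res <- y - qz %*% crossprod(qz, y)
    x_res <- x - qz %*% crossprod(qz, x)
  } else {
    y_res <- y; x_res <- x
  }
  qrx <- qr(x_res)
  rank_x <- qrx$rank
  if (rank_x < ncol(x_res))
    warn(sprintf("dropped %d aliased (collinear) predictor columns",
                 ncol(x_res) - rank_x))
  if (rank_x == 0L) abort("predictors have no variation")
  if (n < rank_x + rank_z + 2L) abort("too few sites for this many predictors")
  qx <- qr.Q(qrx)[, seq_len(rank_x), drop = FALSE]
  ss_tot <- sum(y_res^2)
  if (ss_tot == 0) abort("response has no variation")
  proj <- crossprod(qx, y_res)
  ss_fit <- sum(proj^2)
  ss_res <- ss_tot - ss_fit
  df_res <- n - rank_x - rank_z - 1L
  r2 <- ss_fit / ss_tot
  structure(list(
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1 - rank_z) / df_res,
    pseudo_f = (ss_fit / rank_x) / (ss_res / df_res),
    rank = rank_x, rank_z = rank_z, n = n,
    ss_fit = ss_fit, ss_res = ss_res, ss_tot = ss_tot,
    qx = qx, qz = qz, y = y, y_res = y_res),
    class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: n = %d, rank = %d%s, R2 = %.4f, adjusted R2 = %.4f\n",
              x$n, x$rank,
              if (x$rank_z) paste0(" (partial | ", x$rank_z, ")") else "",
              x$r2, x$adj_r2))
  invisible(x)
}

#' Permutation test of an RDA (pseudo-F)
#'
#' Permutes response rows (simple RDA) or the residuals of the reduced model
#' (partial RDA, the standard scheme for testing a fraction conditioned on
#' covariables) and reports `p = (#{F* >= F} + 1)/(n_perm + 1)`.
#'
#' @param fit an [rda_fit()] object.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return a tibble: `pseudo_f`, `p_value`, `n_perm`.
#' @export
rda_perm_test <- function(fit, n_perm = 999, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  n <- fit$n
  df_res <- n - fit$rank - fit$rank_z - 1L
  f_perm <- with_seed_or_global(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    if (is.null(fit$qz)) {
      yp <- fit$y[p, , drop = FALSE]
      yp <- sweep(yp, 2, colMeans(yp))
    } else {
      # permute reduced-model residuals, re-residualize on the covariables
      yp <- fit$y_res[p, , drop = FALSE]
      yp <- yp - fit$qz %*% crossprod(fit$qz, yp)
    }
    ssf <- sum(crossprod(fit$qx, yp)^2)
    sst <- sum(yp^2)
    (ssf / fit$rank) / ((sst - ssf) / df_res)
  }, numeric(1)))
  tibble::tibble(pseudo_f = fit$pseudo_f,
                 p_value = perm_pvalue(f_perm, fit$pseudo_f),
                 n_perm = n_perm)
}

#' Forward selection of predictors with permutation tests and double stopping
#'
#' Adds at each step the candidate giving the largest gain in adjusted
#' `R^2`; the candidate is retained only if its marginal permutation test
#' (partial RDA conditioned on the already-selected set) gives `p < alpha`.
#' Selection stops when the best candidate fails the test, when the
#' cumulative adjusted `R^2` would exceed the adjusted `R^2` of the
#' all-candidates model (the second stopping rule that guards against
#' inflation), or when candidates are exhausted. A global gate first tests
#' the full-candidate model and selects nothing when it is not significant.
#'
#' @param response data frame/matrix of response columns.
#' @param candidates data frame/matrix of candidate predictors.
#' @param alpha retention threshold on the marginal permutation p-value.
#' @param n_perm permutations per test.
#' @param seed RNG seed (per-step seeds are derived from it).
#' @param global_gate require the all-candidates model to be significant
#'   before selecting anything.
#' @param r2_stop apply the global adjusted-`R^2` stopping rule.
#' @return an object of class `forward_selection`: `selected` (tibble with
#'   per-step `variable`, `adj_r2_cum`, `adj_r2_gain`, `p_value`),
#'   `stopped_because`, `global_adj_r2`, `global_p`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05, n_perm = 999,
                           seed = NULL, global_gate = TRUE, r2_stop = TRUE) {
  xall <- numeric_matrix(candidates)
  y <- numeric_matrix(response)
  cand <- colnames(xall)
  if (is.null(cand)) cand <- paste0("V", seq_len(ncol(xall)))
  colnames(xall) <- cand
  seeds <- if (is.null(seed)) rep(list(NULL), ncol(xall) + 1L)
           else as.list(derive_seeds(seed, ncol(xall) + 1L))
  empty <- tibble::tibble(variable = character(), adj_r2_cum = numeric(),
                          adj_r2_gain = numeric(), p_value = numeric())
  global_fit <- rda_fit(y, xall)
  global_p <- rda_perm_test(global_fit, n_perm, seeds[[1]])$p_value
  if (global_gate && global_p >= alpha) {
    return(structure(list(selected = empty, stopped_because = "global test not significant",
                          global_adj_r2 = global_fit$adj_r2, global_p = global_p),
                     class = "forward_selection"))
  }
  sel <- character()
  rows <- list()
  adj_prev <- 0
  reason <- "candidates exhausted"
  step <- 1L
  while (length(sel) < length(cand)) {
    remaining <- setdiff(cand, sel)
    adj <- vapply(remaining, function(v) {
      rda_fit(y, xall[, c(sel, v), drop = FALSE])$adj_r2
    }, numeric(1))
    best <- remaining[which.max(adj)]
    fit_m <- rda_fit(y, xall[, best, drop = FALSE],
                     z = if (length(sel)) xall[, sel, drop = FALSE])
    p <- rda_perm_test(fit_m, n_perm, seeds[[step + 1L]])$p_value
    if (p >= alpha) {
      reason <- "best candidate not significant"
      break
    }
    rows[[step]] <- tibble::tibble(variable = best, adj_r2_cum = adj[[best]],
                                   adj_r2_gain = adj[[best]] - adj_prev,
                                   p_value = p)
    sel <- c(sel, best)
    adj_prev <- adj[[best]]
    step <- step + 1L
    # second stopping rule: once the cumulative adjusted R2 reaches the
    # global model's, further additions would only overfit
    if (r2_stop && adj_prev > global_fit$adj_r2 + 1e-10) {
      reason <- "cumulative adjusted R2 reached the global model's"
      break
    }
  }
  structure(list(selected = if (length(rows)) dplyr::bind_rows(rows) else empty,
                 stopped_because = reason,
                 global_adj_r2 = global_fit$adj_r2, global_p = global_p),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection:", nrow(x$selected), "variable(s) retained (",
      x$stopped_because, ")\n")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Variation partitioning of a response between two predictor sets
#'
#' Decomposes the adjusted `R^2` of a response into pure environment `[a]`,
#' shared (spatially structured environment) `[b]`, pure space `[c]` and
#' residual `[d]` from three RDA fits (environment only, space only, both):
#' `a = R2_ES - R2_S`, `b = R2_E + R2_S - R2_ES`, `c = R2_ES - R2_E`,
#' `d = 1 - R2_ES` (all adjusted). The testable fractions `[a]` and `[c]`
#' get partial-RDA permutation p-values; the two marginal models and the
#' combined model are tested as well.
#'
#' @param response data frame/matrix of response columns.
#' @param env data frame/matrix of environmental predictors (possibly
#'   forward-selected).
#' @param space data frame/matrix of spatial predictors (e.g. PCNM scores).
#' @param n_perm permutations for the significance tests (0 to skip tests).
#' @param seed RNG seed.
#' @return an object of class `variation_partition` with `fractions` (tibble
#'   `fraction`, `adj_r2`, `p_value`) and the three underlying fits.
#' @export
variation_partition <- function(response, env, space, n_perm = 9999,
                                seed = NULL) {
  y <- numeric_matrix(response)
  xe <- if (!is.null(env)) numeric_matrix(env)
  xs <- if (!is.null(space)) numeric_matrix(space)
  if (is.null(xe) || ncol(xe) == 0L || is.null(xs) || ncol(xs) == 0L) {
    warn("empty predictor set: degenerate partition")
    one <- if (!is.null(xe) && ncol(xe)) xe else xs
    if (is.null(one) || ncol(one) == 0L) {
      frac <- tibble::tibble(fraction = c("a", "b", "c", "d"),
                             adj_r2 = c(0, 0, 0, 1), p_value = NA_real_)
      return(structure(list(fractions = frac, fits = list()),
                       class = "variation_partition"))
    }
    fe <- rda_fit(y, one)
    frac <- tibble::tibble(
      fraction = c("a", "b", "c", "d"),
      adj_r2 = c(if (!is.null(xe) && ncol(xe)) fe$adj_r2 else 0, 0,
                 if (is.null(xe) || ncol(xe) == 0L) fe$adj_r2 else 0,
                 1 - fe$adj_r2),
      p_value = NA_real_)
    return(structure(list(fractions = frac, fits = list(single = fe)),
                     class = "variation_partition"))
  }
  seeds <- if (is.null(seed)) rep(list(NULL), 5L) else as.list(derive_seeds(seed, 5L))
  fit_e <- rda_fit(y, xe)
  fit_s <- rda_fit(y, xs)
  fit_es <- rda_fit(y, cbind(xe, xs))
  a <- fit_es$adj_r2 - fit_s$adj_r2
  b <- fit_e$adj_r2 + fit_s$adj_r2 - fit_es$adj_r2
  cc <- fit_es$adj_r2 - fit_e$adj_r2
  dd <- 1 - fit_es$adj_r2
  p_a <- p_c <- p_e <- p_s <- p_es <- NA_real_
  if (n_perm > 0) {
    p_e <- rda_perm_test(fit_e, n_perm, seeds[[1]])$p_value
    p_s <- rda_perm_test(fit_s, n_perm, seeds[[2]])$p_value
    p_es <- rda_perm_test(fit_es, n_perm, seeds[[3]])$p_value
    p_a <- rda_perm_test(rda_fit(y, xe, z = xs), n_perm, seeds[[4]])$p_value
    p_c <- rda_perm_test(rda_fit(y, xs, z = xe), n_perm, seeds[[5]])$p_value
  }
  frac <- tibble::tibble(
    fraction = c("a", "b", "c", "d"),
    adj_r2 = c(a, b, cc, dd),
    p_value = c(p_a, NA_real_, p_c, NA_real_))
  structure(list(fractions = frac,
                 model_tests = tibble::tibble(
                   model = c("env", "space", "env+space"),
                   adj_r2 = c(fit_e$adj_r2, fit_s$adj_r2, fit_es$adj_r2),
                   p_value = c(p_e, p_s, p_es)),
                 fits = list(env = fit_e, space = fit_s, both = fit_es)),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("Variation partition (adjusted R2 fractions)\n")
  print(x$fractions)
  invisible(x)
}
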