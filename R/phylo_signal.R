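#' Pagel's lambda branch-length transform
#'
#' Multiplies the internal branch lengths of an ultrametric tree by `lambda`
#' and stretches each terminal branch so that every tip keeps its original
#' depth. Equivalently, the off-diagonal entries of the Brownian-motion
#' covariance matrix are multiplied by `lambda`: `lambda = 1` leaves the tree
#' unchanged, `lambda = 0` yields a star phylogeny (independent tips). For
#' ultrametric trees this parameterization is valid on `[0, 1]`.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param lambda value in `[0, 1]`.
#' @return the transformed `phylo` tree.
#' @export
lambda_transform <- function(tree, lambda) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape::phylo object")
  if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1]")
  nt <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  tr <- tree
  terminal <- tr$edge[, 2] <= nt
  tr$edge.length[!terminal] <- tr$edge.length[!terminal] * lambda
  # restore original tip depths through the terminal branches
  new_depths <- ape::node.depth.edgelength(tr)
  tip_edge <- match(seq_len(nt), tr$edge[, 2])
  tr$edge.length[tip_edge] <- tr$edge.length[tip_edge] +
    (depths[seq_len(nt)] - new_depths[seq_len(nt)])
  if (any(tr$edge.length < -1e-10)) abort("lambda out of admissible range for this tree")
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# BM covariance under Pagel's lambda: off-diagonals scaled, tip variances kept.
lambda_vcv <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Brownian-motion log-likelihood of a trait on a tree
#'
#' Multivariate-normal log-likelihood of tip values with mean equal to the
#' root state and covariance `sigma2 * C`, where `C_ij` is the shared
#' root-to-MRCA branch length. When `sigma2`/`root` are omitted they are
#' profiled analytically (GLS root estimate, ML variance with divisor `n`).
#' Zero off-tree variance (duplicate tips from zero-length branches) is
#' guarded by a small diagonal jitter of `1e-8` times the tree height.
#'
#' @param x named numeric vector of tip values (names = tip labels), or
#'   unnamed in tree tip order.
#' @param tree a `phylo` tree with branch lengths (or a covariance matrix).
#' @param sigma2 optional BM rate; profiled if `NULL`.
#' @param root optional root state; profiled if `NULL`.
#' @return the log-likelihood, with attributes `sigma2` and `root`.
#' @export
bm_loglik <- function(x, tree, sigma2 = NULL, root = NULL) {
  C <- if (is.matrix(tree)) tree else ape::vcv(tree)
  if (!is.null(names(x)) && !is.null(rownames(C))) x <- x[rownames(C)]
  n <- length(x)
  if (n != nrow(C)) abort("one value per tip required")
  jitter <- 1e-8 * max(diag(C))
  ch <- tryCatch(chol(C), error = function(e) chol(C + diag(jitter, n)))
  iC1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  iCx <- backsolve(ch, forwardsolve(t(ch), x))
  if (is.null(root)) root <- sum(iCx) / sum(iC1)
  r <- x - root
  iCr <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- drop(crossprod(r, iCr))
  if (is.null(sigma2)) sigma2 <- quad / n
  if (sigma2 <= 0) abort("sigma2 must be positive")
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + quad / sigma2)
  structure(ll, sigma2 = sigma2, root = root)
}

#' Maximum-likelihood fit of Pagel's lambda for one trait
#'
#' Profiles the Brownian-motion log-likelihood over `lambda` in `[0, 1]`
#' (root state and rate estimated analytically at each `lambda`) with
#' bounded scalar optimization at tolerance `1e-8`, and reports the
#' likelihood-ratio test against `lambda = 0` (no signal) on a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param x named numeric tip values.
#' @param tree prepared ultrametric `phylo` tree.
#' @return an object of class `lambda_fit`: `lambda`, `loglik`, `loglik0`
#'   (at `lambda = 0`), `lrt`, `p_value`, `sigma2`, `root`, `boundary`.
#' @export
fit_lambda <- function(x, tree) {
  C <- ape::vcv(tree)
  if (!is.null(names(x))) x <- x[rownames(C)]
  if (length(x) < 4L) abort("need at least 4 tips")
  if (sd(x) == 0) abort("constant trait")
  prof <- function(l) as.numeric(bm_loglik(x, lambda_vcv(C, l)))
  opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  # guard the interior optimum against the boundaries
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, prof(0), prof(1))
  best <- which.max(lls)
  lam <- cand[best]
  ll <- lls[best]
  ll0 <- lls[2]
  fit_at <- bm_loglik(x, lambda_vcv(C, lam))
  lrt <- max(0, 2 * (ll - ll0))
  structure(list(lambda = lam, loglik = ll, loglik0 = ll0, lrt = lrt,
                 p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
                 sigma2 = attr(fit_at, "sigma2"), root = attr(fit_at, "root"),
                 boundary = lam %in% c(0, 1)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.4f (logL = %.3f, LRT vs lambda=0: %.3f, p = %.4g)\n",
              x$lambda, x$loglik, x$lrt, x$p_value))
  invisible(x)
}

#' Likelihood-ratio test p-value for phylogenetic signal in one trait
#'
#' @inheritParams fit_lambda
#' @return the chi-squared (1 df) p-value of the LRT of `lambda = lambda_hat`
#'   against `lambda = 0`. Note the null is on the boundary of the parameter
#'   space, which makes this test conservative.
#' @export
lambda_lrt <- function(x, tree) fit_lambda(x, tree)$p_value

#' Phylogenetic-signal table for every trait column
#'
#' Fits Pagel's lambda per trait (binary and fuzzy-coded columns are treated
#' as continuous values under the Gaussian model — a documented coercion) and
#' returns a per-trait summary table with significance stars.
#'
#' @param traits validated trait table.
#' @param tree prepared tree covering the trait species.
#' @return tibble: `trait`, `lambda`, `loglik`, `lrt`, `p_value`, `signif`.
#' @export
phylo_signal_table <- function(traits, tree) {
  traits <- validate_traits(traits, fuzzy_groups = attr(traits, "fuzzy_groups"),
                            species = tree$tip.label)
  cols <- setdiff(names(traits), "species")
  purrr::map_dfr(cols, function(cl) {
    x <- setNames(traits[[cl]], traits$species)
    if (sd(x) == 0) {
      return(tibble::tibble(trait = cl, lambda = NA_real_, loglik = NA_real_,
                            lrt = NA_real_, p_value = NA_real_, signif = ""))
    }
    f <- fit_lambda(x, tree)
    tibble::tibble(trait = cl, lambda = f$lambda, loglik = f$loglik,
                   lrt = f$lrt, p_value = f$p_value,
                   signif = signif_stars(f$p_value))
  })
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   p < 0.1 ~ ".", TRUE ~ "")
}
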