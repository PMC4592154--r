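#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a variation partition into one row per fraction
#'
#' @param x a [variation_partition()] object.
#' @param ... unused.
#' @return tibble with `fraction`, `adj_r2`, `p_value`.
#' @exportS3Method
#' @export
tidy.variation_partition <- function(x, ...) x$fractions

#' One-row summary of a variation partition
#'
#' @param x a [variation_partition()] object.
#' @param ... unused.
#' @return tibble with the three model adjusted R2 values and the residual.
#' @exportS3Method
#' @export
glance.variation_partition <- function(x, ...) {
  fr <- setNames(x$fractions$adj_r2, x$fractions$fraction)
  tibble::tibble(adj_r2_env = fr[["a"]] + fr[["b"]],
                 adj_r2_space = fr[["b"]] + fr[["c"]],
                 adj_r2_total = fr[["a"]] + fr[["b"]] + fr[["c"]],
                 residual = fr[["d"]])
}

#' Tidy an RDA fit
#'
#' @param x an [rda_fit()] object.
#' @param ... unused.
#' @return one-row tibble with `r2`, `adj_r2`, `pseudo_f`, `rank`, `n`.
#' @exportS3Method
#' @export
tidy.rda_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adj_r2 = x$adj_r2, pseudo_f = x$pseudo_f,
                 rank = x$rank, n = x$n)
}

#' @rdname tidy.rda_fit
#' @exportS3Method
#' @export
glance.rda_fit <- tidy.rda_fit

#' Tidy a forward-selection result (one row per retained variable)
#'
#' @param x a [forward_select()] object.
#' @param ... unused.
#' @exportS3Method
#' @export
tidy.forward_selection <- function(x, ...) x$selected

#' One-row summary of a forward selection
#'
#' @param x a [forward_select()] object.
#' @param ... unused.
#' @exportS3Method
#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(n_selected = nrow(x$selected),
                 adj_r2 = if (nrow(x$selected)) max(x$selected$adj_r2_cum) else 0,
                 global_adj_r2 = x$global_adj_r2, global_p = x$global_p,
                 stopped_because = x$stopped_because)
}

#' Tidy a Pagel's-lambda fit
#'
#' @param x a [fit_lambda()] object.
#' @param ... unused.
#' @exportS3Method
#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, loglik = x$loglik, loglik0 = x$loglik0,
                 lrt = x$lrt, p_value = x$p_value, sigma2 = x$sigma2,
                 root = x$root, boundary = x$boundary)
}

#' Tidy a Rao partition: the per-site alpha table
#'
#' @param x a [rao_partition()] object.
#' @param ... unused.
#' @exportS3Method
#' @export
tidy.rao_partition <- function(x, ...) x$alpha

#' One-row summary of a Rao partition
#'
#' @param x a [rao_partition()] object.
#' @param ... unused.
#' @exportS3Method
#' @export
glance.rao_partition <- function(x, ...) {
  bt <- x$beta[upper.tri(x$beta)]
  tibble::tibble(facet = x$facet, n_sites = nrow(x$alpha),
                 mean_alpha_equivalent = mean(x$alpha$equivalent),
                 mean_beta = mean(bt), max_beta = max(bt))
}

#' Tidy a pipeline report: the fraction table
#'
#' @param x a [run_pipeline()] report.
#' @param ... unused.
#' @exportS3Method
#' @export
tidy.rao_report <- function(x, ...) x$fractions
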