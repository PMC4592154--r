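#' @importFrom rlang abort warn inform .data
#' @importFrom stats cor cophenetic dist prcomp sd var quantile rnorm runif
#'   plogis optimize pchisq rbinom complete.cases setNames
#' @importFrom utils head read.csv write.csv
NULL

# Run `expr` under a local RNG state seeded with `seed`; if `seed` is NULL the
# global stream is used untouched.
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive `n` independent child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Permutation p-value: (number of permuted statistics >= observed, + 1) / (n + 1)
perm_pvalue <- function(stat_perm, stat_obs) {
  (sum(stat_perm >= stat_obs - 1e-12) + 1) / (length(stat_perm) + 1)
}

#' Construct a labelled species/site distance matrix
#'
#' Distance matrices in raopart are plain symmetric base matrices with a zero
#' diagonal, dimnames, and a `provenance` attribute recording what the
#' distances measure (`"taxonomic"`, `"functional"`, `"phylogenetic"`,
#' `"geographic"` or `"beta"`).
#'
#' @param m symmetric numeric matrix, zero diagonal, non-negative entries.
#' @param labels character vector of row/column labels.
#' @param provenance one of `"taxonomic"`, `"functional"`, `"phylogenetic"`,
#'   `"geographic"`, `"beta"`.
#' @return the matrix with class `dist_matrix` and a `provenance` attribute.
#' @export
dist_matrix <- function(m, labels = rownames(m),
                        provenance = c("taxonomic", "functional",
                                       "phylogenetic", "geographic", "beta")) {
  provenance <- match.arg(provenance)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (any(m < -1e-12)) abort("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-10)) abort("distance matrix diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m[m < 0] <- 0
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  structure(m, class = c("dist_matrix", "matrix", "array"),
            provenance = provenance)
}

#' Rescale a distance matrix so its largest off-diagonal value is 1
#'
#' @param d a `dist_matrix` (or plain symmetric matrix).
#' @return the rescaled matrix; degenerate all-zero matrices are returned
#'   unchanged with a warning.
#' @export
rescale_unit <- function(d) {
  off <- d[upper.tri(d)]
  mx <- if (length(off)) max(off) else 0
  if (mx <= 0) {
    warn("all off-diagonal distances are zero; matrix left unscaled")
    return(d)
  }
  out <- d / mx
  attributes(out) <- attributes(d)
  out
}

#' Write a distance matrix as a labelled square CSV
#'
#' @param d a `dist_matrix`.
#' @param path output file path.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square CSV back into a distance matrix
#'
#' @param path CSV written by [write_dist_matrix()].
#' @param provenance provenance tag for the result.
#' @return a `dist_matrix`.
#' @export
read_dist_matrix <- function(path, provenance = "beta") {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, provenance = provenance)
}

# Extract the site x species 0/1 matrix from a community tibble.
community_matrix <- function(comm, site_col = "site") {
  stopifnot(is.data.frame(comm))
  if (!site_col %in% names(comm)) abort(
    paste0("community table needs a `", site_col, "` column"))
  m <- as.matrix(comm[, setdiff(names(comm), site_col), drop = FALSE])
  rownames(m) <- as.character(comm[[site_col]])
  storage.mode(m) <- "double"
  m
}

# Extract a numeric predictor/response matrix from a tibble, dropping an id
# column when present.
numeric_matrix <- function(df, id_col = "site") {
  if (is.matrix(df)) return(df)
  stopifnot(is.data.frame(df))
  keep <- setdiff(names(df), id_col)
  m <- as.matrix(df[, keep, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric columns in table")
  if (id_col %in% names(df)) rownames(m) <- as.character(df[[id_col]])
  m
}
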