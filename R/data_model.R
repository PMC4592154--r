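#' Read a site x species presence-absence table
#'
#' Reads a CSV/TSV whose first column holds site identifiers and whose
#' remaining columns hold species occurrences. Abundance values are coerced to
#' presence (`> 0` becomes 1) with a warning, and species that occur nowhere
#' are dropped with a message, so the result satisfies the community
#' invariants: binary entries, unique identifiers, every site and every
#' species non-empty.
#'
#' @param path file path.
#' @param site_col name of the site identifier column (default first column).
#' @param sep field separator; guessed from the file extension when `NULL`.
#' @return a tibble with a `site` column and one binary column per species.
#' @export
read_community <- function(path, site_col = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (is.null(site_col)) site_col <- names(df)[1]
  names(df)[names(df) == site_col] <- "site"
  validate_community(tibble::as_tibble(df))
}

#' Validate (and coerce) a community table
#'
#' @param comm data frame with a `site` column and numeric species columns.
#' @return the validated tibble, invisibly modified: abundances coerced to
#'   0/1 (warning), all-zero species dropped (message).
#' @export
validate_community <- function(comm) {
  comm <- tibble::as_tibble(comm)
  if (!"site" %in% names(comm)) abort("community table needs a `site` column")
  if (anyDuplicated(comm$site)) abort("duplicate site identifiers")
  sp <- setdiff(names(comm), "site")
  if (anyDuplicated(sp)) abort("duplicate species identifiers")
  if (length(sp) == 0L || nrow(comm) == 0L) abort("empty community matrix")
  m <- as.matrix(comm[, sp, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) abort("non-numeric or missing occurrence values")
  if (any(m < 0)) abort("negative occurrence values cannot be coerced to presence")
  if (any(m != 0 & m != 1)) {
    warn("abundance values coerced to presence (> 0 -> 1)")
    m <- (m > 0) + 0
  }
  empty_sp <- colSums(m) == 0
  if (any(empty_sp)) {
    inform(paste0("dropped ", sum(empty_sp),
                  " species with zero occurrences: ",
                  paste(head(sp[empty_sp], 5), collapse = ", "),
                  if (sum(empty_sp) > 5) ", ..." else ""))
    m <- m[, !empty_sp, drop = FALSE]
    if (ncol(m) == 0L) abort("empty community matrix after dropping species")
  }
  if (any(rowSums(m) == 0)) abort(
    paste("sites with no species:",
          paste(head(comm$site[rowSums(m) == 0], 5), collapse = ", ")))
  dplyr::bind_cols(tibble::tibble(site = as.character(comm$site)),
                   tibble::as_tibble(m))
}

#' Simpson index of land-use diversity
#'
#' `1 - sum(p_k^2)` over land-use category shares, the probability that two
#' randomly chosen points of a site fall in different land-use categories.
#' Ranges over `[0, 1 - 1/K]` for `K` categories.
#'
#' @param proportions non-negative category shares summing to 1 (renormalized
#'   with a warning otherwise).
#' @return the Simpson diversity of the shares.
#' @export
simpson_landuse_index <- function(proportions) {
  p <- as.numeric(proportions)
  if (length(p) < 1L || anyNA(p)) abort("need at least one non-missing share")
  if (any(p < 0)) abort("negative category shares")
  s <- sum(p)
  if (s <= 0) abort("all-zero share vector")
  if (abs(s - 1) > 1e-6) {
    warn("shares do not sum to 1; renormalizing")
    p <- p / s
  }
  1 - sum(p^2)
}

#' Anthropogenic disturbance index
#'
#' The proportion of a site's surface occupied by artificial cover, stored
#' as-is as the disturbance variable.
#'
#' @param artificial_share proportion in `[0, 1]`.
#' @return the share, validated.
#' @export
disturbance_index <- function(artificial_share) {
  x <- as.numeric(artificial_share)
  if (anyNA(x) || any(x < 0 | x > 1)) abort("share must lie in [0, 1]")
  x
}

#' Read a site table (coordinates + environmental variables)
#'
#' @param path CSV with columns `site`, `x`, `y` and environmental variables.
#' @param lonlat are coordinates longitude/latitude (`TRUE`) or projected
#'   planar units (`FALSE`, default)?
#' @return a tibble with a `lonlat` attribute.
#' @export
read_sites <- function(path, lonlat = FALSE) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  validate_sites(df, lonlat = lonlat)
}

#' Validate a site table
#'
#' @param sites data frame with `site`, `x`, `y` and numeric environment
#'   columns.
#' @param lonlat logical flag stored as an attribute for distance computation.
#' @return the validated tibble.
#' @export
validate_sites <- function(sites, lonlat = FALSE) {
  sites <- tibble::as_tibble(sites)
  need <- c("site", "x", "y")
  if (!all(need %in% names(sites))) abort("site table needs columns site, x, y")
  if (anyDuplicated(sites$site)) abort("duplicate site identifiers")
  if (!all(is.finite(sites$x)) || !all(is.finite(sites$y)))
    abort("non-finite coordinates")
  env <- env_columns(sites)
  if (length(env)) {
    m <- as.matrix(sites[, env, drop = FALSE])
    if (!is.numeric(m) || anyNA(m)) abort("missing or non-numeric environmental values")
  }
  sites$site <- as.character(sites$site)
  attr(sites, "lonlat") <- isTRUE(lonlat)
  sites
}

env_columns <- function(sites) setdiff(names(sites), c("site", "x", "y"))

#' Standardize environmental variables to mean 0, variance 1
#'
#' Uses the sample standard deviation (divisor `n - 1`). Identifier and
#' coordinate columns are passed through unchanged. Idempotent.
#'
#' @param sites a validated site table.
#' @param cols columns to standardize (default: every column except
#'   `site`, `x`, `y`).
#' @return the site table with standardized environment columns.
#' @export
standardize_env <- function(sites, cols = NULL) {
  sites <- tibble::as_tibble(sites)
  if (is.null(cols)) cols <- env_columns(sites)
  if (nrow(sites) < 2L) abort("need at least two sites to standardize")
  for (cl in cols) {
    v <- sites[[cl]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) abort(paste0("constant column: ", cl))
    sites[[cl]] <- (v - mean(v)) / s
  }
  sites
}

#' Read a species x trait table
#'
#' @param path CSV with a `species` column and trait columns.
#' @param fuzzy_groups optional named list of character vectors; each element
#'   names the columns of one fuzzy-coded trait (shares summing to 1 per
#'   species).
#' @return a validated tibble carrying a `fuzzy_groups` attribute.
#' @export
read_traits <- function(path, fuzzy_groups = NULL) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  validate_traits(df, fuzzy_groups = fuzzy_groups)
}

#' Validate a trait table
#'
#' Checks uniqueness, completeness (missing values are an error, never
#' imputed) and that each fuzzy-coded group of columns sums to 1 per species.
#'
#' @inheritParams read_traits
#' @param traits data frame with a `species` column and numeric trait columns.
#' @param species optional character vector that must be covered (e.g. the
#'   community's species).
#' @return the validated tibble with a `fuzzy_groups` attribute.
#' @export
validate_traits <- function(traits, fuzzy_groups = NULL, species = NULL) {
  traits <- tibble::as_tibble(traits)
  if (!"species" %in% names(traits)) abort("trait table needs a `species` column")
  if (anyDuplicated(traits$species)) abort("duplicate species in trait table")
  tr <- setdiff(names(traits), "species")
  if (!length(tr)) abort("no trait columns")
  m <- as.matrix(traits[, tr, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric trait columns")
  if (anyNA(m)) abort("missing trait values (imputation is not supported)")
  for (g in names(fuzzy_groups)) {
    colsg <- fuzzy_groups[[g]]
    if (!all(colsg %in% tr)) abort(paste0("fuzzy group `", g, "` names unknown columns"))
    rs <- rowSums(traits[, colsg, drop = FALSE])
    if (any(abs(rs - 1) > 1e-6)) abort(
      paste0("fuzzy group `", g, "` rows do not sum to 1"))
  }
  if (!is.null(species)) {
    miss <- setdiff(species, traits$species)
    if (length(miss)) abort(paste("species missing from trait table:",
                                  paste(head(miss, 5), collapse = ", ")))
  }
  traits$species <- as.character(traits$species)
  attr(traits, "fuzzy_groups") <- fuzzy_groups
  traits
}

#' Pairwise geographic distances between sites
#'
#' Euclidean distances for projected coordinates; great-circle (haversine,
#' km) when the table was declared lon/lat.
#'
#' @param sites validated site table.
#' @return a `dist_matrix` with provenance `"geographic"`.
#' @export
geographic_distances <- function(sites) {
  lonlat <- isTRUE(attr(sites, "lonlat"))
  xy <- cbind(sites$x, sites$y)
  if (lonlat) {
    rad <- pi / 180
    lat <- sites$y * rad
    lon <- sites$x * rad
    n <- nrow(xy)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      a <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      dij <- 2 * 6371.0088 * asin(pmin(1, sqrt(a)))
      d[i, j] <- dij
      d[j, i] <- dij
    }
  } else {
    d <- as.matrix(dist(xy))
  }
  dist_matrix(d, labels = sites$site, provenance = "geographic")
}
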