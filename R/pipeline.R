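#' Run the full diversity-partitioning pipeline
#'
#' End-to-end workflow on an input bundle: builds the taxonomic,
#' phylogenetic and functional species distance matrices; computes per-site
#' Rao alpha (Jost equivalent numbers) and pairwise Rao beta for each facet;
#' constructs PCNM spatial predictors (positive Moran's I subset) and uses
#' the standardized environmental variables; forward-selects each predictor
#' set per response; partitions variation into pure-environment, shared,
#' pure-space and residual adjusted-R2 fractions; and adds spatial
#' correlograms (Moran's I for alpha, Mantel for beta) plus a Pagel's-lambda
#' phylogenetic-signal table per trait. Every stochastic stage receives a
#' seed derived from the master seed, so re-running a configuration
#' reproduces every number.
#'
#' @param bundle a `rao_bundle` (from [simulate_scenario()] or
#'   [read_bundle()]).
#' @param facets subset of `c("TD", "PD", "FD")`.
#' @param per_trait_fd also run the FD path separately for each trait column.
#' @param n_perm_select permutations for forward selection (default 999).
#' @param n_perm_test permutations for fraction tests (default 9999).
#' @param alpha forward-selection significance threshold.
#' @param axes_criterion PCoA axis-retention rule for beta responses.
#' @param rho Grafen exponent used if the bundle's tree still needs
#'   preparation.
#' @param n_perm_correlogram permutations per correlogram class.
#' @param seed master seed.
#' @param out_dir optional directory for the CSV reports
#'   (`table1_style.csv`, `fig3_fractions.csv`, `tableS4_lambda.csv`,
#'   `correlograms.csv`).
#' @return an object of class `rao_report`: `partitions` (named list of
#'   [variation_partition()] objects per facet x scale), `fractions`
#'   (tidy tibble of all fractions), `table1` (retained variables with
#'   signed contributions), `lambda` (phylogenetic-signal table),
#'   `correlograms`, `selections`, `alpha_tables`, `log`.
#' @export
run_pipeline <- function(bundle, facets = c("TD", "PD", "FD"),
                         per_trait_fd = FALSE, n_perm_select = 999,
                         n_perm_test = 9999, alpha = 0.05,
                         axes_criterion = "broken_stick", rho = 1,
                         n_perm_correlogram = 999, seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(bundle, "rao_bundle"))
  facets <- match.arg(facets, c("TD", "PD", "FD"), several.ok = TRUE)
  logline <- character()
  say <- function(...) logline <<- c(logline, sprintf(...))
  comm <- validate_community(bundle$community)
  sp <- setdiff(names(comm), "site")
  sites <- validate_sites(bundle$sites,
                          lonlat = isTRUE(attr(bundle$sites, "lonlat")))
  tree <- bundle$tree
  if (is.null(tree$edge.length) || ape::is.binary(tree) == FALSE ||
      var(root_to_tip_depths(tree)) > 1e-12) {
    tree <- prepare_tree(tree, rho = rho, seed = seed, species = sp)
    say("tree prepared: Grafen rho = %g, seed = %d", rho, seed)
  }
  traits <- validate_traits(bundle$traits,
                            fuzzy_groups = attr(bundle$traits, "fuzzy_groups"),
                            species = sp)
  dists <- list()
  if ("TD" %in% facets) dists$TD <- taxonomic_distances(sp)
  if ("PD" %in% facets) dists$PD <- align_distances(phylogenetic_distances(tree), sp)
  if ("FD" %in% facets) dists$FD <- align_distances(functional_distances(traits), sp)
  if (per_trait_fd) {
    for (cl in setdiff(names(traits), "species")) {
      dists[[paste0("FD_", cl)]] <- align_distances(
        functional_distances(traits[, c("species", cl)]), sp)
    }
  }
  seeds <- derive_seeds(seed, 4L + 10L * length(dists))
  basis <- pcnm_basis(sites)
  say("PCNM: %d positive-eigenvalue eigenfunctions, %d with positive Moran's I, threshold %.4g",
      length(basis$values), sum(basis$positive_moran), basis$threshold)
  x_space <- pcnm_scores(basis, positive_moran = TRUE)
  x_env <- sites[, c("site", env_columns(sites))]

  partitions <- list(); selections <- list(); alpha_tables <- list()
  corr_rows <- list(); table1 <- list(); frac_rows <- list()
  si <- 5L
  for (f in names(dists)) {
    part <- rao_partition(comm, dists[[f]], facet = f)
    alpha_tables[[f]] <- part$alpha
    responses <- list(
      alpha = tibble::tibble(site = part$alpha$site,
                             equivalent = part$alpha$equivalent),
      beta = pcoa_axes(part$beta, criterion = axes_criterion)$points)
    say("%s: beta PCoA retained %d axes", f,
        ncol(responses$beta) - 1L)
    for (scale_ in names(responses)) {
      y <- responses[[scale_]]
      fs_env <- forward_select(y, x_env, alpha = alpha,
                               n_perm = n_perm_select, seed = seeds[si])
      fs_spa <- forward_select(y, x_space, alpha = alpha,
                               n_perm = n_perm_select, seed = seeds[si + 1L])
      key <- paste(f, scale_, sep = "_")
      selections[[key]] <- list(env = fs_env, space = fs_spa)
      say("%s %s: env retained {%s}; space retained {%s}", f, scale_,
          paste(fs_env$selected$variable, collapse = ","),
          paste(fs_spa$selected$variable, collapse = ","))
      xe <- if (nrow(fs_env$selected))
        x_env[, c("site", fs_env$selected$variable)] else NULL
      xs <- if (nrow(fs_spa$selected))
        x_space[, c("site", fs_spa$selected$variable)] else NULL
      vp <- suppressWarnings(
        variation_partition(y, xe, xs, n_perm = n_perm_test,
                            seed = seeds[si + 2L]))
      partitions[[key]] <- vp
      frac_rows[[key]] <- dplyr::mutate(vp$fractions, facet = f,
                                        scale = scale_, .before = 1)
      table1[[key]] <- signed_contributions(y, fs_env, fs_spa, x_env, x_space,
                                            facet = f, scale = scale_)
      si <- si + 3L
    }
    corr_rows[[paste0(f, "_alpha")]] <- dplyr::mutate(
      morans_correlogram(part$alpha$equivalent, sites,
                         n_perm = n_perm_correlogram, seed = seeds[si]),
      facet = f, scale = "alpha", statistic = .data$moran_i, .before = 1)
    corr_rows[[paste0(f, "_beta")]] <- dplyr::mutate(
      mantel_correlogram(part$beta, sites, n_perm = n_perm_correlogram,
                         seed = seeds[si + 1L]),
      facet = f, scale = "beta", statistic = .data$mantel_r, .before = 1)
    si <- si + 2L
  }
  lam <- phylo_signal_table(traits, tree)
  report <- structure(list(
    partitions = partitions,
    fractions = dplyr::bind_rows(frac_rows),
    table1 = dplyr::bind_rows(table1),
    lambda = lam,
    correlograms = dplyr::bind_rows(corr_rows),
    selections = selections,
    alpha_tables = dplyr::bind_rows(alpha_tables),
    pcnm = basis, log = logline,
    config = list(facets = facets, n_perm_select = n_perm_select,
                  n_perm_test = n_perm_test, alpha = alpha,
                  axes_criterion = axes_criterion, rho = rho, seed = seed)),
    class = "rao_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Signed adjusted-R2 contributions of retained variables. The sign follows
# the correlation between the predictor and the first canonical axis of the
# combined selected model (a convention: the response is multivariate).
signed_contributions <- function(y, fs_env, fs_spa, x_env, x_space,
                                 facet, scale) {
  rows <- list()
  sel <- dplyr::bind_rows(
    if (nrow(fs_env$selected)) dplyr::mutate(fs_env$selected, set = "env"),
    if (nrow(fs_spa$selected)) dplyr::mutate(fs_spa$selected, set = "space"))
  if (is.null(sel) || !nrow(sel)) {
    return(tibble::tibble(facet = character(), scale = character(),
                          set = character(), variable = character(),
                          adj_r2_gain = numeric(), sign = numeric(),
                          p_value = numeric(), signif = character()))
  }
  xall <- cbind(numeric_matrix(x_env)[, sel$variable[sel$set == "env"], drop = FALSE],
                numeric_matrix(x_space)[, sel$variable[sel$set == "space"], drop = FALSE])
  ym <- scale(numeric_matrix(y), scale = FALSE)
  xc <- scale(xall, scale = FALSE)
  fitted <- xc %*% qr.coef(qr(xc), ym)
  ax1 <- prcomp(fitted, center = FALSE)$x[, 1]
  sgn <- vapply(seq_len(ncol(xc)), function(j) sign(cor(xc[, j], ax1)),
                numeric(1))
  dplyr::mutate(sel, facet = facet, scale = scale, .before = 1,
                sign = sgn[match(sel$variable, colnames(xc))],
                signif = signif_stars(sel$p_value)) |>
    dplyr::select(dplyr::all_of(c("facet", "scale", "set", "variable",
                                  "adj_r2_gain", "sign", "p_value", "signif")))
}

#' @export
print.rao_report <- function(x, ...) {
  cat("Diversity-partitioning report:", length(x$partitions),
      "facet x scale partitions\n\n")
  print(x$fractions, n = nrow(x$fractions))
  invisible(x)
}

#' Write the pipeline report as CSV files
#'
#' @param report a `rao_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table1, file.path(dir, "table1_style.csv"), row.names = FALSE)
  write.csv(report$fractions, file.path(dir, "fig3_fractions.csv"), row.names = FALSE)
  write.csv(report$lambda, file.path(dir, "tableS4_lambda.csv"), row.names = FALSE)
  write.csv(report$correlograms, file.path(dir, "correlograms.csv"),
            row.names = FALSE)
  writeLines(report$log, file.path(dir, "pipeline_log.txt"))
  invisible(dir)
}

#' Validate an input bundle and print a report
#'
#' Runs every validator on the bundle's tables and tree and prints a short
#' structural summary (sites, species, traits, tree coverage).
#'
#' @param bundle a `rao_bundle`.
#' @return the validated bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  comm <- validate_community(bundle$community)
  sp <- setdiff(names(comm), "site")
  sites <- validate_sites(bundle$sites,
                          lonlat = isTRUE(attr(bundle$sites, "lonlat")))
  traits <- validate_traits(bundle$traits,
                            fuzzy_groups = attr(bundle$traits, "fuzzy_groups"),
                            species = sp)
  if (!all(sp %in% bundle$tree$tip.label))
    abort("tree does not cover all community species")
  if (!setequal(comm$site, sites$site)) abort("site tables disagree on sites")
  cat("valid bundle:", nrow(comm), "sites x", length(sp), "species;",
      length(setdiff(names(traits), "species")), "trait columns;",
      ape::Ntip(bundle$tree), "tree tips\n")
  invisible(bundle)
}
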