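#' Define a synthetic metacommunity scenario
#'
#' Fixes the generating conditions for a synthetic study: number of sites and
#' species, range of the environmental Gaussian-process autocorrelation (in
#' units of the unit-square landscape), niche strength (logistic slope on the
#' squared mismatch between a site's environment and a species' optimum),
#' dispersal-field scale, and the true Pagel's lambda per simulated trait.
#' Presets switch off the unused structure: `pure_env` removes the dispersal
#' field, `pure_space` removes the niche term, `neutral` removes both
#' (constant occurrence probability), `mixed` keeps both.
#'
#' @param preset `"mixed"`, `"pure_env"`, `"pure_space"` or `"neutral"`.
#' @param n_sites,n_species problem size (defaults emulate the study scale:
#'   300 sites, 150 species).
#' @param env_range GP range of the environmental surfaces.
#' @param niche_slope logistic slope on squared environment-optimum mismatch.
#' @param dispersal_scale GP range of the species-specific dispersal fields.
#' @param dispersal_sd standard deviation of the dispersal fields.
#' @param lambda_true true Pagel's lambda for each simulated quantitative
#'   trait.
#' @param intercept logistic intercept controlling prevalence.
#' @param seed master seed fixing every downstream draw.
#' @return a list of class `rao_scenario`.
#' @export
scenario <- function(preset = c("mixed", "pure_env", "pure_space", "neutral"),
                     n_sites = 300L, n_species = 150L,
                     env_range = 0.25, niche_slope = 1, dispersal_scale = 0.15,
                     dispersal_sd = 2, lambda_true = c(1, 1, 0.5, 0),
                     intercept = 0.5, seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(n_sites >= 3, n_species >= 2, env_range > 0, dispersal_scale > 0)
  if (preset %in% c("pure_space", "neutral")) niche_slope <- 0
  if (preset %in% c("pure_env", "neutral")) dispersal_sd <- 0
  structure(list(preset = preset, n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species), env_range = env_range,
                 niche_slope = niche_slope, dispersal_scale = dispersal_scale,
                 dispersal_sd = dispersal_sd, lambda_true = lambda_true,
                 intercept = intercept, seed = as.integer(seed)),
            class = "rao_scenario")
}

#' Simulate a Yule phylogeny
#'
#' Pure-birth tree with the requested number of tips, Grafen-prepared
#' (binary, ultrametric, height 1). Deterministic per seed.
#'
#' @param n_species number of tips (>= 2).
#' @param seed RNG seed.
#' @param rho Grafen exponent passed to [prepare_tree()].
#' @return a prepared `phylo` tree with tips `sp1..spn`.
#' @export
simulate_tree <- function(n_species, seed = 1L, rho = 1) {
  if (n_species < 2) abort("need at least 2 species")
  tr <- with_seed_or_global(seed, ape::rphylo(n_species, birth = 1, death = 0))
  tr$tip.label <- paste0("sp", seq_len(n_species))
  prepare_tree(tr, rho = rho, seed = seed)
}

#' Simulate traits with known phylogenetic signal
#'
#' Each quantitative trait is one draw from a multivariate normal with
#' covariance `sigma2 * C_lambda(tree)` (Brownian motion with the
#' off-diagonal covariances damped by the trait's true lambda). Optional
#' binary traits are made by thresholding extra draws at their median.
#'
#' @param tree prepared tree.
#' @param lambda_true numeric vector of true lambdas, one per trait.
#' @param sigma2 BM rate.
#' @param n_binary number of additional thresholded 0/1 traits (lambda 1).
#' @param seed RNG seed.
#' @return a validated trait tibble (`species`, `trait1..`, `bin1..`).
#' @export
simulate_traits <- function(tree, lambda_true = c(1, 1, 0.5, 0), sigma2 = 1,
                            n_binary = 1L, seed = 1L) {
  stopifnot(all(lambda_true >= 0 & lambda_true <= 1))
  C <- ape::vcv(tree)
  n <- nrow(C)
  draws <- with_seed_or_global(seed, {
    qs <- lapply(c(lambda_true, rep(1, n_binary)), function(l) {
      ch <- chol(lambda_vcv(C, l) + diag(1e-10, n))
      drop(crossprod(ch, rnorm(n)) * sqrt(sigma2))
    })
    qs
  })
  out <- tibble::tibble(species = rownames(C))
  for (i in seq_along(lambda_true)) out[[paste0("trait", i)]] <- unname(draws[[i]])
  for (j in seq_len(n_binary)) {
    v <- unname(draws[[length(lambda_true) + j]])
    out[[paste0("bin", j)]] <- as.numeric(v > stats::median(v))
  }
  validate_traits(out)
}

#' Simulate a landscape of sites with autocorrelated environment
#'
#' Sites are placed uniformly in the unit square; four climate-like
#' variables are drawn from a Gaussian process with exponential covariance
#' `exp(-d/range)`; a land-use diversity variable is built by applying the
#' Simpson index to spatially structured category shares, and a disturbance
#' proportion by a logistic transform of another GP draw. All environmental
#' columns are then standardized (mean 0, variance 1).
#'
#' @param n_sites number of sites.
#' @param range GP autocorrelation range.
#' @param seed RNG seed.
#' @param n_categories land-use categories behind the Simpson index.
#' @return a standardized site tibble (`site`, `x`, `y`, `temp_mean`,
#'   `temp_amplitude`, `precip`, `precip_seasonality`, `landuse_div`,
#'   `disturbance`).
#' @export
simulate_landscape <- function(n_sites, range = 0.25, seed = 1L,
                               n_categories = 7L) {
  stopifnot(n_sites >= 3, range > 0)
  with_seed_or_global(seed, {
    xy <- cbind(runif(n_sites), runif(n_sites))
    ch <- chol(gp_cov(xy, range))
    gp <- function() drop(crossprod(ch, rnorm(n_sites)))
    shares <- vapply(seq_len(n_categories), function(k) exp(gp()),
                     numeric(n_sites))
    shares <- shares / rowSums(shares)
    out <- tibble::tibble(
      site = paste0("s", seq_len(n_sites)), x = xy[, 1], y = xy[, 2],
      temp_mean = gp(), temp_amplitude = gp(), precip = gp(),
      precip_seasonality = gp(),
      landuse_div = apply(shares, 1, simpson_landuse_index),
      disturbance = disturbance_index(plogis(gp())))
    standardize_env(validate_sites(out))
  })
}

#' Simulate a presence-absence metacommunity
#'
#' Species occurrence at a site follows a Bernoulli draw with probability
#' `plogis(intercept - slope * (env_i - optimum_s)^2 + dispersal_is)`: the
#' environment filters each species through the mismatch between the site's
#' first environmental axis and the species' optimum, which is the species'
#' first (heritable) trait — so taxonomic, phylogenetic and functional
#' structure are coupled as in real assemblages. The dispersal term is a
#' species-specific spatially autocorrelated Gaussian field representing
#' dispersal limitation independent of the environment. Sites that come up
#' empty are re-drawn (with a message). Presets zero out the unused term.
#'
#' @param scn a [scenario()].
#' @param sites simulated (standardized) site table.
#' @param traits simulated trait table; `trait1` provides the optima.
#' @param seed RNG seed (defaults to the scenario's).
#' @return a validated community tibble.
#' @export
simulate_communities <- function(scn, sites, traits, seed = scn$seed) {
  n <- nrow(sites)
  sp <- traits$species
  env <- sites$temp_mean
  opt <- scale(traits$trait1)[, 1]
  with_seed_or_global(seed, {
    disp <- matrix(0, n, length(sp))
    if (scn$dispersal_sd > 0) {
      ch <- chol(gp_cov(cbind(sites$x, sites$y), scn$dispersal_scale))
      disp <- crossprod(ch, matrix(rnorm(n * length(sp)), n)) * scn$dispersal_sd
    }
    eta <- scn$intercept - scn$niche_slope *
      outer(env, opt, function(e, o) (e - o)^2) + disp
    prob <- plogis(eta)
    occ <- matrix(rbinom(length(prob), 1, prob), n)
    empty <- rowSums(occ) == 0
    tries <- 0L
    while (any(empty) && tries < 100L) {
      occ[empty, ] <- rbinom(sum(empty) * length(sp), 1, prob[empty, ])
      empty <- rowSums(occ) == 0
      tries <- tries + 1L
    }
    if (any(empty)) {
      # force the most probable species into stubbornly empty sites
      for (i in which(empty)) occ[i, which.max(prob[i, ])] <- 1L
    }
    if (tries > 0) inform(sprintf("re-drew empty sites (%d round(s))", tries))
    colnames(occ) <- sp
    suppressMessages(validate_community(
      dplyr::bind_cols(tibble::tibble(site = sites$site),
                       tibble::as_tibble(occ))))
  })
}

#' Simulate a full input bundle for one scenario
#'
#' Derives per-stage seeds from the scenario's master seed and generates the
#' tree, traits, landscape and community together, so one master seed fixes
#' every downstream number.
#'
#' @param scn a [scenario()].
#' @return a list of class `rao_bundle`: `scenario`, `tree`, `traits`,
#'   `sites`, `community`.
#' @export
simulate_scenario <- function(scn) {
  stopifnot(inherits(scn, "rao_scenario"))
  seeds <- derive_seeds(scn$seed, 4L)
  tree <- simulate_tree(scn$n_species, seed = seeds[1])
  traits <- simulate_traits(tree, lambda_true = scn$lambda_true,
                            seed = seeds[2])
  sites <- simulate_landscape(scn$n_sites, range = scn$env_range,
                              seed = seeds[3])
  comm <- simulate_communities(scn, sites, traits, seed = seeds[4])
  # keep only species that actually occur, everywhere in the bundle
  sp_kept <- setdiff(names(comm), "site")
  traits <- validate_traits(traits[traits$species %in% sp_kept, ])
  tree_kept <- ape::keep.tip(tree, sp_kept)
  attr(tree_kept, "rho") <- attr(tree, "rho")
  structure(list(scenario = scn, tree = tree_kept, traits = traits,
                 sites = sites, community = comm),
            class = "rao_bundle")
}

#' Write a simulated bundle to disk in the package's input formats
#'
#' @param bundle a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$community, file.path(dir, "community.csv"), row.names = FALSE)
  write.csv(bundle$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(bundle$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  invisible(dir)
}

#' Read an input bundle written by [write_bundle()] (or user data)
#'
#' @param dir directory with `community.csv`, `sites.csv`, `traits.csv`,
#'   `tree.nwk`.
#' @param lonlat are the site coordinates lon/lat?
#' @return a list of class `rao_bundle` (without a scenario).
#' @export
read_bundle <- function(dir, lonlat = FALSE) {
  comm <- read_community(file.path(dir, "community.csv"))
  structure(list(scenario = NULL,
                 tree = ape::read.tree(file.path(dir, "tree.nwk")),
                 traits = read_traits(file.path(dir, "traits.csv")),
                 sites = read_sites(file.path(dir, "sites.csv"), lonlat = lonlat),
                 community = comm),
            class = "rao_bundle")
}

# Exponential-covariance GP kernel over coordinates.
gp_cov <- function(xy, range) {
  d <- unname(as.matrix(dist(xy)))
  exp(-d / range) + diag(1e-8, nrow(xy))
}
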