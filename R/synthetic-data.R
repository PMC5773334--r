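#' Simulate a typed, correlated environmental landscape
#'
#' Generates `n_sites` sites on a latent environmental gradient space of
#' dimension `n_latent` (standard multivariate normal site coordinates) and
#' derives a set of observed environmental variables organised in typed groups
#' (temperature, precipitation, insolation, NDVI, topography). Each observed
#' variable is a linear combination of the latent coordinates plus independent
#' Gaussian observation noise; variables within a group share a common loading
#' direction, so within-group correlations exceed between-group correlations.
#' This emulates the structure of multi-source environmental predictor sets
#' used in surrogate-based reserve selection, where dozens of climatic and
#' topographic layers are collinear summaries of a few underlying gradients.
#'
#' The latent coordinates are attached as an attribute for use by
#' [simulate_species()] and by tests; the analysis pipeline itself only ever
#' sees the noisy observed variables and must rediscover the gradients via
#' PCA.
#'
#' @param n_sites Number of sites (rows). Must be at least 2.
#' @param n_latent Dimension of the latent gradient space.
#' @param variable_groups Named integer vector giving the number of observed
#'   variables per type; names must be among `temperature`, `precipitation`,
#'   `insolation`, `ndvi`, `topography`. The default has 38 variables, the
#'   size of a typical global predictor set.
#' @param noise_sd Standard deviation of the independent observation noise
#'   added to every variable. Nonnegative.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @param loadings Optional (total variables) x `n_latent` loading matrix
#'   overriding the random group-structured loadings (used mainly for
#'   controlled tests, e.g. identity loadings).
#'
#' @return A tibble of class `ed_env` with a `site_id` column and one numeric
#'   column per variable (named `<type>_<k>`), carrying attributes
#'   `var_types` (named character vector of per-column type tags), `latent`
#'   (the n x `n_latent` latent coordinate matrix) and `config`.
#' @seealso [simulate_species()], [simulate_ed_dataset()]
#' @export
#' @examples
#' env <- simulate_environment(n_sites = 50, seed = 1)
#' dim(env)
simulate_environment <- function(n_sites = 300,
                                 n_latent = 3,
                                 variable_groups = c(temperature = 8, precipitation = 8,
                                                     insolation = 6, ndvi = 6,
                                                     topography = 10),
                                 noise_sd = 0.3,
                                 seed = 1,
                                 loadings = NULL) {
  if (n_sites < 2) abort("n_sites must be >= 2: distance matrices need at least two sites")
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (is.null(names(variable_groups)) ||
      !all(names(variable_groups) %in% ED_VAR_TYPES)) {
    abort(paste0("variable_groups must be named with types among: ",
                 paste(ED_VAR_TYPES, collapse = ", ")))
  }
  variable_groups <- variable_groups[variable_groups > 0]
  n_vars <- sum(variable_groups)
  if (n_vars < n_latent) abort("total variable count must be >= n_latent")

  withr::local_seed(seed)

  Z <- matrix(stats::rnorm(n_sites * n_latent), n_sites, n_latent)

  if (is.null(loadings)) {
    # Each group gets a shared unit direction; each variable mixes it with an
    # idiosyncratic direction at half weight, giving within-group > between-group |r|.
    loadings <- matrix(0, n_vars, n_latent)
    row <- 1L
    for (g in seq_along(variable_groups)) {
      u <- stats::rnorm(n_latent)
      u <- u / sqrt(sum(u^2))
      for (v in seq_len(variable_groups[[g]])) {
        e <- stats::rnorm(n_latent)
        e <- e / sqrt(sum(e^2))
        w <- u + 0.5 * e
        loadings[row, ] <- w / sqrt(sum(w^2))
        row <- row + 1L
      }
    }
  } else {
    loadings <- as.matrix(loadings)
    if (nrow(loadings) != n_vars || ncol(loadings) != n_latent) {
      abort("loadings must be (total variables) x n_latent")
    }
  }

  X <- tcrossprod(Z, loadings)
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(n_sites * n_vars, sd = noise_sd),
                                    n_sites, n_vars)

  types <- rep(names(variable_groups), times = variable_groups)
  vnames <- unlist(lapply(seq_along(variable_groups), function(g) {
    paste0(names(variable_groups)[g], "_", seq_len(variable_groups[[g]]))
  }), use.names = FALSE)
  colnames(X) <- vnames
  names(types) <- vnames

  site_ids <- make_site_ids(n_sites)
  rownames(Z) <- site_ids
  out <- tibble::as_tibble(as.data.frame(X))
  out <- tibble::add_column(out, site_id = site_ids, .before = 1)
  structure(out,
            var_types = types,
            latent = Z,
            config = list(n_sites = n_sites, n_latent = n_latent,
                          variable_groups = variable_groups,
                          noise_sd = noise_sd, seed = seed),
            class = c("ed_env", class(out)))
}

#' Simulate species occurrences from unimodal niches
#'
#' Each species has a Gaussian (unimodal) niche in the latent environmental
#' space: its occurrence probability at a site decays with squared distance
#' from a niche centre. Centres are drawn uniformly over the per-axis range
#' of the latent site coordinates; niche breadths (the Gaussian standard
#' deviation, in latent units) are drawn uniformly from `breadth_range`.
#' Occurrence probability at site \eqn{i} for species \eqn{j} is
#' \deqn{P_{ij} = P_{max} \exp(-\|z_i - c_j\|^2 / (2 \sigma_j^2)),}
#' and presence is an independent Bernoulli draw. Any species left with zero
#' occurrences is assigned a presence at the site nearest its centre, so every
#' species occurs at least once (species counts are stable across seeds).
#'
#' @param env An `ed_env` landscape from [simulate_environment()] (its latent
#'   coordinates are used), or a numeric matrix of latent site coordinates.
#' @param n_species Number of species to simulate.
#' @param breadth_range Length-2 positive vector `(low, high)`: range of niche
#'   standard deviations, in latent units. `0 < low <= high`.
#' @param max_prevalence Occurrence probability at the niche centre, in (0, 1].
#' @param seed Integer seed.
#'
#' @return A tibble of class `ed_pa` with a `site_id` column and one 0/1
#'   column per species, carrying attributes `centers` (n_species x d),
#'   `breadths` and `config`.
#' @export
#' @examples
#' env <- simulate_environment(n_sites = 60, seed = 1)
#' pa <- simulate_species(env, n_species = 20, seed = 2)
#' all(colSums(pa[-1]) >= 1)
simulate_species <- function(env,
                             n_species = 120,
                             breadth_range = c(0.5, 1.5),
                             max_prevalence = 0.9,
                             seed = 1) {
  Z <- if (inherits(env, "ed_env")) attr(env, "latent") else as.matrix(env)
  if (is.null(Z)) abort("env carries no latent coordinates")
  n <- nrow(Z)
  if (n_species < 1) abort("n_species must be >= 1")
  if (length(breadth_range) != 2 || breadth_range[1] <= 0 ||
      breadth_range[1] > breadth_range[2]) {
    abort("breadth_range must satisfy 0 < low <= high")
  }
  if (max_prevalence <= 0 || max_prevalence > 1) {
    abort("max_prevalence must be in (0, 1]")
  }

  withr::local_seed(seed)
  d <- ncol(Z)
  lo <- apply(Z, 2, min)
  hi <- apply(Z, 2, max)
  centers <- sapply(seq_len(d), function(k) stats::runif(n_species, lo[k], hi[k]))
  centers <- matrix(centers, n_species, d)
  breadths <- stats::runif(n_species, breadth_range[1], breadth_range[2])

  occ <- matrix(0L, n, n_species)
  for (j in seq_len(n_species)) {
    d2 <- colSums((t(Z) - centers[j, ])^2)
    prob <- max_prevalence * exp(-d2 / (2 * breadths[j]^2))
    occ[, j] <- as.integer(stats::runif(n) < prob)
    if (sum(occ[, j]) == 0L) occ[which.min(d2), j] <- 1L  # nearest-site repair
  }

  site_ids <- if (inherits(env, "ed_env")) env$site_id else make_site_ids(n)
  sp_ids <- make_species_ids(n_species)
  colnames(occ) <- sp_ids
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- tibble::add_column(out, site_id = site_ids, .before = 1)
  structure(out,
            centers = centers,
            breadths = breadths,
            config = list(n_species = n_species, breadth_range = breadth_range,
                          max_prevalence = max_prevalence, seed = seed),
            class = c("ed_pa", class(out)))
}

#' Simulate a complete landscape + species dataset
#'
#' Convenience wrapper generating an environmental table and a matching
#' presence/absence table with one call; the species seed is derived from
#' `seed` by a fixed offset so the pair is reproducible from a single root
#' seed.
#'
#' @inheritParams simulate_environment
#' @inheritParams simulate_species
#' @param ... Passed on to [simulate_environment()].
#' @return A list with elements `env` (class `ed_env`) and `pa` (class `ed_pa`).
#' @export
simulate_ed_dataset <- function(n_sites = 300, n_species = 120, seed = 1,
                                noise_sd = 0.3, breadth_range = c(0.5, 1.5),
                                max_prevalence = 0.9, ...) {
  env <- simulate_environment(n_sites = n_sites, noise_sd = noise_sd,
                              seed = seed, ...)
  pa <- simulate_species(env, n_species = n_species,
                         breadth_range = breadth_range,
                         max_prevalence = max_prevalence, seed = seed + 101L)
  list(env = env, pa = pa)
}
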