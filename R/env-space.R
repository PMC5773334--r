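#' Combinations of variable types (CVT1-CVT5)
#'
#' The five fixed characterizations of environmental space used throughout
#' the pipeline, each a subset of the five variable types:
#' \describe{
#'   \item{CVT1}{all five types (full variable set)}
#'   \item{CVT2}{climate (temperature + precipitation) and NDVI}
#'   \item{CVT3}{climate and topography}
#'   \item{CVT4}{climate only}
#'   \item{CVT5}{insolation and topography}
#' }
#'
#' @param name One of `"CVT1"` ... `"CVT5"`.
#' @return Character vector of included type tags.
#' @export
#' @examples
#' cvt_types("CVT4")
cvt_types <- function(name) {
  defs <- list(
    CVT1 = ED_VAR_TYPES,
    CVT2 = c("temperature", "precipitation", "ndvi"),
    CVT3 = c("temperature", "precipitation", "topography"),
    CVT4 = c("temperature", "precipitation"),
    CVT5 = c("insolation", "topography")
  )
  name <- match.arg(name, names(defs))
  defs[[name]]
}

#' Subset an environment table by a combination of variable types
#'
#' Keeps the columns whose type tag belongs to the chosen CVT, preserving
#' column order. Errors if any included type has no columns in the table:
#' a characterization of environmental space that silently lacked one of its
#' constituent variable types would not be comparable across datasets.
#'
#' @param env An `ed_env` tibble with per-column type tags.
#' @param cvt CVT name (`"CVT1"` ... `"CVT5"`) or a character vector of type
#'   tags.
#' @return An `ed_env` tibble with the selected columns.
#' @export
subset_cvt <- function(env, cvt = "CVT1") {
  types <- var_types(env)
  included <- if (length(cvt) == 1 && grepl("^CVT[1-5]$", cvt)) cvt_types(cvt) else cvt
  missing_types <- setdiff(included, unique(types))
  if (length(missing_types)) {
    abort(paste0("environment table has no columns of type: ",
                 paste(missing_types, collapse = ", ")))
  }
  keep <- names(types)[types %in% included]
  out <- env[c("site_id", keep)]
  structure(out, var_types = types[keep],
            latent = attr(env, "latent"),
            class = unique(c("ed_env", class(out))))
}

#' Principal components with Kaiser retention
#'
#' Standardizes every variable to zero mean and unit variance (PCA on the
#' correlation matrix) and retains exactly the components whose eigenvalue
#' exceeds 1.0 (Kaiser criterion) -- a component is kept only if it explains
#' more variance than a single standardized variable. Eigenvalues equal to
#' 1.0 up to floating-point error (exact ties, e.g. perfectly uncorrelated
#' variables) do not count as exceeding the cutoff. If no eigenvalue
#' exceeds 1.0, the single largest component is kept and the result flagged,
#' so downstream sweeps remain runnable.
#'
#' @param env An `ed_env` tibble (or numeric matrix) with at least two
#'   variables, none of them constant.
#' @return An `ed_ordination` object: list with `coordinates` (tibble of
#'   site_id + retained component scores), `kind = "pca"`, `k`,
#'   `eigenvalues` (all of them), and `kaiser_fallback`.
#' @export
#' @examples
#' env <- simulate_environment(n_sites = 100, seed = 1)
#' sp <- pca_kaiser(env)
#' sp$k
pca_kaiser <- function(env) {
  X <- env_matrix(env)
  if (ncol(X) < 2) abort("PCA needs at least two variables")
  v <- apply(X, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    abort(paste0("zero-variance column(s): ",
                 paste(colnames(X)[v == 0 | !is.finite(v)], collapse = ", "),
                 " -- drop them before ordination"))
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- fit$sdev^2
  # strict Kaiser cutoff, with a small tolerance so eigenvalues that are 1.0
  # up to floating-point error (exact ties) do not count as exceeding it
  k <- sum(eig > 1.0 + 1e-9)
  fallback <- k == 0
  if (fallback) {
    warn("no eigenvalue exceeds 1.0; retaining the single largest component")
    k <- 1L
  }
  scores <- fit$x[, seq_len(k), drop = FALSE]
  coords <- tibble::as_tibble(as.data.frame(scores))
  coords <- tibble::add_column(coords, site_id = rownames(X), .before = 1)
  structure(list(coordinates = coords, kind = "pca", k = k,
                 eigenvalues = eig, kaiser_fallback = fallback),
            class = "ed_ordination")
}

#' Two-dimensional nonmetric multidimensional scaling
#'
#' Embeds the sites in two dimensions so that intersite distance reflects
#' their distances in full retained-PCA space, as required by the continuous
#' p-median selector whose demand grid is two-dimensional. Minimizes Kruskal
#' stress-1 (vegan's `monoMDS`, global model, primary tie treatment) from a
#' classical metric-scaling initialization with a small seeded jitter to
#' break degeneracy; the fit is deterministic given the seed.
#'
#' @param space An `ed_ordination` (typically from [pca_kaiser()]), a `dist`
#'   object, or a symmetric distance matrix.
#' @param seed Integer seed for the initialization jitter.
#' @param max_iter Maximum refinement iterations.
#' @return An `ed_ordination` with `kind = "nmds2d"`, 2-D `coordinates` and
#'   the final `stress` (Kruskal stress-1, in \[0, 1\]).
#' @export
nmds_2d <- function(space, seed = 1, max_iter = 500) {
  if (inherits(space, "ed_ordination")) {
    ids <- space$coordinates$site_id
    d <- stats::dist(ord_coords(space))
  } else if (inherits(space, "dist")) {
    d <- space
    ids <- labels(d) %||% make_site_ids(attr(d, "Size"))
  } else {
    m <- as.matrix(space)
    ids <- rownames(m) %||% make_site_ids(nrow(m))
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  if (n < 3) abort("NMDS needs at least 3 sites")

  init <- stats::cmdscale(d, k = 2)
  if (ncol(init) < 2) init <- cbind(init, 0)[, 1:2, drop = FALSE]
  withr::local_seed(seed)
  scale0 <- max(stats::sd(init), 1e-8)
  init <- init + matrix(stats::rnorm(n * 2, sd = 1e-4 * scale0), n, 2)

  fit <- vegan::monoMDS(d, y = init, k = 2, model = "global",
                        maxit = max_iter, weakties = TRUE)
  coords <- fit$points
  colnames(coords) <- c("NMDS1", "NMDS2")
  ctbl <- tibble::as_tibble(as.data.frame(coords))
  ctbl <- tibble::add_column(ctbl, site_id = ids, .before = 1)
  structure(list(coordinates = ctbl, kind = "nmds2d", k = 2L,
                 stress = fit$stress, converged = fit$maxits > 0),
            class = "ed_ordination")
}

#' Pairwise Euclidean distances in an ordination space
#'
#' @param space An `ed_ordination` (PCA or NMDS).
#' @return A symmetric n x n matrix with zero diagonal, site ids as dimnames.
#' @export
ordination_distances <- function(space) {
  as.matrix(stats::dist(ord_coords(space)))
}

#' @export
print.ed_ordination <- function(x, ...) {
  cat("Ordination (", x$kind, "), ", nrow(x$coordinates), " sites, k = ", x$k,
      sep = "")
  if (x$kind == "nmds2d") cat(", stress = ", signif(x$stress, 4), sep = "")
  if (isTRUE(x$kaiser_fallback)) cat(" [Kaiser fallback: largest component kept]")
  cat("\n")
  invisible(x)
}
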