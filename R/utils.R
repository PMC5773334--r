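# Internal helpers shared across modules.

# The five recognised environmental variable types.
ED_VAR_TYPES <- c("temperature", "precipitation", "insolation", "ndvi", "topography")

#' @importFrom rlang abort warn %||% .data
NULL

#' @keywords internal
"_PACKAGE"

# Extract the numeric site x variable matrix from an ed_env tibble (or pass a
# plain matrix through). Row order is preserved; site_id column dropped.
env_matrix <- function(env) {
  if (is.matrix(env)) {
    storage.mode(env) <- "double"
    if (is.null(rownames(env))) rownames(env) <- make_site_ids(nrow(env))
    return(env)
  }
  stopifnot(is.data.frame(env))
  num <- env[setdiff(names(env), "site_id")]
  m <- as.matrix(num)
  if (!is.numeric(m)) abort("environment table must have numeric variable columns")
  rownames(m) <- env$site_id %||% as.character(seq_len(nrow(m)))
  m
}

# Extract the binary occurrence matrix (sites x species) from an ed_pa tibble.
pa_matrix <- function(pa) {
  if (is.matrix(pa)) {
    storage.mode(pa) <- "integer"
    m <- pa
  } else {
    stopifnot(is.data.frame(pa))
    m <- as.matrix(pa[setdiff(names(pa), "site_id")])
    storage.mode(m) <- "integer"
    rownames(m) <- pa$site_id %||% as.character(seq_len(nrow(m)))
  }
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    abort("presence/absence matrix must be binary with no missing values")
  }
  m
}

# Per-column variable type tags of an ed_env tibble.
var_types <- function(env) {
  vt <- attr(env, "var_types")
  if (is.null(vt)) abort("environment table carries no variable type tags")
  vt
}

# Coordinates matrix of an ed_ordination.
ord_coords <- function(space) {
  stopifnot(inherits(space, "ed_ordination"))
  m <- as.matrix(space$coordinates[setdiff(names(space$coordinates), "site_id")])
  rownames(m) <- space$coordinates$site_id
  m
}

# Row-wise argmin of a matrix (ties -> first/lowest column), via max.col for speed.
row_argmin <- function(M) max.col(-M, ties.method = "first")

# Euclidean cross-distance matrix between rows of A (q x d) and rows of B (n x d).
cross_dist <- function(A, B) {
  q <- nrow(A); n <- nrow(B)
  d2 <- matrix(rowSums(A^2), q, n) + matrix(rowSums(B^2), q, n, byrow = TRUE) -
    2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Format site ids like s001, s002, ...
make_site_ids <- function(n) sprintf("s%0*d", max(3L, nchar(n)), seq_len(n))

make_species_ids <- function(n) sprintf("sp%0*d", max(3L, nchar(n)), seq_len(n))
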