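#' Maximum-dispersion objective
#'
#' The maxdisp criterion scores a selected site set by the sum, over all
#' unordered pairs of selected sites, of the inverse squared distance
#' \eqn{\sum_{\{i,j\}} 1/d_{ij}^2}: small values mean the sites are spread
#' evenly through environmental space. A pair at zero distance (duplicated
#' sites) contributes a large finite sentinel \eqn{1/\epsilon^2} rather than
#' infinity, so objectives stay comparable.
#'
#' @param d Symmetric distance matrix.
#' @param selected Integer indices of the selected sites.
#' @param eps Zero-distance sentinel scale (distance floor), default 1e-12.
#' @return The objective value (0 for a single site: no pairs).
#' @export
#' @examples
#' d <- as.matrix(dist(c(0, 2, 10)))
#' maxdisp_objective(d, 1:3)  # 1/4 + 1/64 + 1/100
maxdisp_objective <- function(d, selected, eps = 1e-12) {
  if (length(selected) < 1) abort("at least one selected site required")
  if (length(selected) < 2) return(0)
  sub <- d[selected, selected, drop = FALSE]
  terms <- 1 / pmax(sub[upper.tri(sub)], eps)^2
  sum(terms)
}

#' Greedy maximum-dispersion site selection
#'
#' Selects `m` sites spread evenly through environmental space by greedily
#' minimizing the maxdisp objective. Initialization picks the pair with the
#' largest distance (the exact optimum for m = 2); each subsequent step adds
#' the unselected site with the smallest marginal contribution
#' \eqn{\sum_{s \in selected} 1/d_{is}^2}. Ties are broken by lowest site
#' index, so the procedure is fully deterministic. Because only a distance
#' matrix is needed, the selector works in retained-PCA space of any
#' dimension -- no reduction to two dimensions is involved.
#'
#' For `m = 1` the pair-sum objective is undefined; by convention the site
#' maximizing its minimum distance to all other sites is returned, with
#' objective 0.
#'
#' @param d Symmetric distance matrix (e.g. from [ordination_distances()]).
#' @param m Number of sites to select, `1 <= m <= n`.
#' @param eps Zero-distance sentinel scale passed to the objective.
#' @return An `ed_selection`: tibble with columns `step`, `site` (index),
#'   `site_id`, and `objective` (value after that addition), with attributes
#'   `method = "maxdisp"`, `objective` (final value) and `selected`.
#' @export
#' @examples
#' d <- as.matrix(dist(c(0, 1, 2, 10)))
#' greedy_maxdisp(d, m = 2)$site  # the extreme pair
greedy_maxdisp <- function(d, m, eps = 1e-12) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (m > n) abort("cannot select more sites than available (m > n)")
  if (m < 1) abort("m must be >= 1")
  ids <- rownames(d) %||% make_site_ids(n)

  inv2 <- 1 / pmax(d, eps)^2
  diag(inv2) <- 0

  if (m == 1) {
    dd <- d
    diag(dd) <- Inf
    pick <- which.max(apply(dd, 1, min))  # max-min-distance convention
    return(new_ed_selection(data.frame(step = 1L, site = as.integer(pick),
                                       site_id = ids[pick], objective = 0),
                            method = "maxdisp", objective = 0))
  }

  # Seed pair: maximum distance, ties by lexicographically smallest (i, j).
  ut <- which(upper.tri(d), arr.ind = TRUE)
  best <- max(d[ut])
  cand <- ut[d[ut] == best, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])
  obj <- 1 / pmax(best, eps)^2
  steps <- data.frame(step = 1:2, site = sel, site_id = ids[sel],
                      objective = c(0, obj))

  marg <- inv2[, sel[1]] + inv2[, sel[2]]  # marginal cost of each candidate
  in_sel <- logical(n)
  in_sel[sel] <- TRUE

  while (length(sel) < m) {
    mm <- marg
    mm[in_sel] <- Inf
    pick <- which.min(mm)  # which.min breaks ties by lowest index
    obj <- unname(obj + marg[pick])
    sel <- c(sel, as.integer(pick))
    in_sel[pick] <- TRUE
    marg <- marg + inv2[, pick]
    steps <- rbind(steps, data.frame(step = length(sel), site = as.integer(pick),
                                     site_id = ids[pick], objective = obj))
  }

  new_ed_selection(steps, method = "maxdisp", objective = obj)
}

# Constructor shared by both selectors.
new_ed_selection <- function(steps, method, objective, diagnostics = NULL) {
  out <- tibble::as_tibble(steps)
  structure(out,
            method = method,
            objective = objective,
            selected = as.integer(out$site),
            diagnostics = diagnostics,
            class = c("ed_selection", class(out)))
}

#' Selected site indices of a selection result
#' @param x An `ed_selection`.
#' @return Integer vector of selected site indices.
#' @export
selected_sites <- function(x) {
  stopifnot(inherits(x, "ed_selection"))
  attr(x, "selected")
}
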