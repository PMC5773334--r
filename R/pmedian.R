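#' Build a uniform demand-point grid over a 2-D ordination
#'
#' Divides each NMDS axis range into `g` equal intervals and returns the
#' `g^2` cell centroids as demand points. The grid is uniform over the
#' bounding box of the site coordinates (no padding), including cells that
#' contain no sites: demand is distributed uniformly throughout the
#' environmental space, which is what makes the p-median "continuous".
#'
#' @param space An `ed_ordination` with `kind = "nmds2d"`, or an n x 2
#'   coordinate matrix.
#' @param g Grid divisions per axis (default 50, i.e. 2,500 demand points).
#' @return An `ed_demand_grid`: tibble with columns `x`, `y` and attributes
#'   `g` and `bounds`.
#' @export
#' @examples
#' pts <- matrix(runif(20), 10, 2)
#' nrow(build_demand_grid(pts, g = 5))  # 25
build_demand_grid <- function(space, g = 50) {
  coords <- if (inherits(space, "ed_ordination")) {
    if (space$kind != "nmds2d") abort("demand grids are built over 2-D NMDS space")
    ord_coords(space)
  } else {
    as.matrix(space)
  }
  if (ncol(coords) != 2) abort("demand grids need 2-D coordinates")
  if (g < 1) abort("g must be >= 1")
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  if (any(hi - lo <= 0)) abort("degenerate ordination axis (zero range): cannot grid")
  midx <- lo[1] + (seq_len(g) - 0.5) * (hi[1] - lo[1]) / g
  midy <- lo[2] + (seq_len(g) - 0.5) * (hi[2] - lo[2]) / g
  pts <- expand.grid(x = midx, y = midy, KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(pts)
  structure(out, g = as.integer(g), bounds = rbind(lo = lo, hi = hi),
            class = c("ed_demand_grid", class(out)))
}

#' Continuous p-median cost of a selection
#'
#' Sum over demand points of the Euclidean distance to the nearest selected
#' site. With every site selected this is the global lower bound attainable
#' for any p.
#'
#' @param space Site coordinates: an `ed_ordination` (nmds2d) or n x 2 matrix.
#' @param selected Integer indices of selected sites (nonempty).
#' @param demand An `ed_demand_grid` (or q x 2 matrix of demand points).
#' @return The cost (nonnegative scalar).
#' @export
pmedian_cost <- function(space, selected, demand) {
  if (length(selected) < 1) abort("at least one selected site required")
  coords <- if (inherits(space, "ed_ordination")) ord_coords(space) else as.matrix(space)
  dpts <- if (is.data.frame(demand)) as.matrix(demand[, c("x", "y")]) else as.matrix(demand)
  D <- cross_dist(dpts, coords[selected, , drop = FALSE])
  a <- row_argmin(D)
  sum(D[cbind(seq_len(nrow(D)), a)])
}

#' Solve the continuous p-median by multistart + vertex substitution + elites
#'
#' Hybrid heuristic for selecting `p` sites minimizing the summed
#' demand-point-to-nearest-site distance in 2-D NMDS space. Each of `starts`
#' runs builds a solution by randomized greedy construction (each addition
#' drawn from the best three candidates by cost reduction) and polishes it by
#' first-improvement vertex substitution (swap a selected and an unselected
#' site whenever the swap reduces cost, candidate order seeded). The
#' `elite_size` best local optima are then pairwise recombined -- the union
#' of each pair is greedily reduced back to `p` by dropping the site whose
#' removal increases cost least -- and re-polished; the best solution found
#' anywhere is returned. Deterministic given `seed`.
#'
#' @param space An `ed_ordination` with `kind = "nmds2d"` (or n x 2 matrix).
#' @param p Number of sites to select, `1 <= p <= n`.
#' @param demand An `ed_demand_grid`; built with [build_demand_grid()] and
#'   `g` if omitted.
#' @param g Grid divisions per axis used when `demand` is not supplied.
#' @param starts Number of randomized construction starts (default 32).
#' @param elite_size Size of the elite pool recombined at the end (default 10).
#' @param seed Integer seed.
#' @param max_swaps Cap on accepted swaps per local search.
#' @return An `ed_selection`: tibble with columns `step`, `site`, `site_id`;
#'   attributes `method = "pmedian"`, `objective` (final cost), `selected`,
#'   and `diagnostics` (per-start construction and local-search costs).
#' @export
solve_pmedian <- function(space, p, demand = NULL, g = 50,
                          starts = 32, elite_size = 10, seed = 1,
                          max_swaps = 200L) {
  coords <- if (inherits(space, "ed_ordination")) {
    if (space$kind != "nmds2d") abort("solve_pmedian operates in 2-D NMDS space")
    ord_coords(space)
  } else {
    as.matrix(space)
  }
  n <- nrow(coords)
  ids <- rownames(coords) %||% make_site_ids(n)
  if (p > n) abort("cannot select more sites than available (p > n)")
  if (p < 1) abort("p must be >= 1")
  if (starts < 1) abort("starts must be >= 1")
  if (elite_size > starts) abort("elite_size must be <= starts")
  if (is.null(demand)) demand <- build_demand_grid(space, g = g)
  dpts <- if (is.data.frame(demand)) as.matrix(demand[, c("x", "y")]) else as.matrix(demand)

  D <- cross_dist(dpts, coords)  # q x n
  q <- nrow(D)

  sel_cost <- function(sel) {
    M <- D[, sel, drop = FALSE]
    a <- row_argmin(M)
    sum(M[cbind(seq_len(q), a)])
  }

  # nearest/second-nearest state for fast swap evaluation
  make_state <- function(sel) {
    M <- D[, sel, drop = FALSE]
    a <- row_argmin(M)
    i <- seq_len(q)
    d1 <- M[cbind(i, a)]
    if (length(sel) > 1) {
      M[cbind(i, a)] <- Inf
      a2 <- row_argmin(M)
      d2 <- M[cbind(i, a2)]
    } else {
      d2 <- rep(Inf, q)
    }
    list(sel = sel, a = a, d1 = d1, d2 = d2, cost = sum(d1))
  }

  # per-facility aggregation of a q-vector by current assignment (C-level)
  agg_by_fac <- function(x, a, p_len) {
    res <- rowsum(x, a)
    out <- numeric(p_len)
    out[as.integer(rownames(res))] <- res
    out
  }

  construct <- function() {
    sel <- integer(0)
    d1 <- rep(Inf, q)
    while (length(sel) < p) {
      red <- colSums(pmax(d1 - D, 0))
      red[sel] <- -Inf
      ord <- order(red, decreasing = TRUE)
      top <- ord[seq_len(min(3L, n - length(sel)))]
      pick <- top[sample.int(length(top), 1L)]
      sel <- c(sel, pick)
      d1 <- pmin(d1, D[, pick])
    }
    sel
  }

  local_search <- function(sel) {
    if (p >= n) return(make_state(sel))
    st <- make_state(sel)
    swaps <- 0L
    repeat {
      improved <- FALSE
      cands <- setdiff(seq_len(n), st$sel)
      cands <- cands[sample.int(length(cands))]  # seeded first-improvement order
      for (f in cands) {
        Df <- D[, f]
        u <- pmax(st$d1 - Df, 0)
        v <- st$d1 - pmin(st$d2, Df)
        su <- sum(u)
        uagg <- agg_by_fac(u, st$a, length(st$sel))
        vagg <- agg_by_fac(v, st$a, length(st$sel))
        profit <- su - uagg + vagg
        r <- which.max(profit)
        if (profit[r] > 1e-9 * (1 + st$cost)) {
          sel2 <- st$sel
          sel2[r] <- f
          st <- make_state(sel2)
          swaps <- swaps + 1L
          improved <- TRUE
          if (swaps >= max_swaps) return(st)
          break
        }
      }
      if (!improved) return(st)
    }
  }

  drop_to_p <- function(sel) {
    while (length(sel) > p) {
      st <- make_state(sel)
      inc <- agg_by_fac(st$d2 - st$d1, st$a, length(sel))
      r <- which.min(inc)  # ties -> facility with lowest position, i.e. lowest index order below
      sel <- sel[-r]
    }
    sel
  }

  withr::local_seed(seed)

  diagnostics <- vector("list", starts)
  pool <- vector("list", starts)
  for (s in seq_len(starts)) {
    sel0 <- construct()
    c0 <- sel_cost(sel0)
    st <- local_search(sel0)
    pool[[s]] <- list(sel = sort(st$sel), cost = st$cost)
    diagnostics[[s]] <- data.frame(start = s, construction_cost = c0,
                                   local_cost = st$cost)
  }

  ord <- order(vapply(pool, `[[`, numeric(1), "cost"))
  pool <- pool[ord]
  keys <- vapply(pool, function(x) paste(x$sel, collapse = ","), character(1))
  pool <- pool[!duplicated(keys)]
  elites <- pool[seq_len(min(elite_size, length(pool)))]

  best <- elites[[1]]
  if (length(elites) >= 2 && p < n) {
    for (i in seq_len(length(elites) - 1)) {
      for (j in seq((i + 1), length(elites))) {
        u <- sort(union(elites[[i]]$sel, elites[[j]]$sel))
        if (length(u) == p) next  # identical support: nothing to recombine
        sel2 <- drop_to_p(u)
        st <- local_search(sel2)
        if (st$cost < best$cost - 1e-12) best <- list(sel = sort(st$sel), cost = st$cost)
      }
    }
  }

  steps <- data.frame(step = seq_len(p), site = best$sel, site_id = ids[best$sel])
  new_ed_selection(steps, method = "pmedian", objective = best$cost,
                   diagnostics = dplyr::bind_rows(diagnostics))
}
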