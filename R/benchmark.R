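#' Number of species represented in a selection
#'
#' Counts the species with at least one presence among the selected sites --
#' the representation currency for S, R and O alike.
#'
#' @param pa An `ed_pa` tibble or binary site x species matrix.
#' @param selected Integer indices of selected sites (may be empty: 0).
#' @return Integer species count.
#' @export
species_represented <- function(pa, selected) {
  occ <- pa_matrix(pa)
  if (length(selected) == 0) return(0L)
  if (any(selected < 1 | selected > nrow(occ))) abort("selected indices out of range")
  sum(colSums(occ[selected, , drop = FALSE]) > 0)
}

#' Expected richness of a uniform random selection (closed form)
#'
#' For species j occupying \eqn{n_j} of n sites, the probability that a
#' uniform random p-subset misses it is \eqn{C(n-n_j, p)/C(n, p)}
#' (hypergeometric); the expected number represented is the sum of the
#' complements. Serves as the exact oracle for the Monte-Carlo baseline.
#'
#' @inheritParams species_represented
#' @param p Number of sites drawn without replacement.
#' @return Expected species count (real).
#' @export
expected_random_richness <- function(pa, p) {
  occ <- pa_matrix(pa)
  n <- nrow(occ)
  if (p < 1 || p > n) abort("p must be in 1..n")
  nj <- colSums(occ)
  miss <- exp(lchoose(n - nj, p) - lchoose(n, p))
  miss[n - nj < p] <- 0  # cannot miss a species occupying more than n - p sites
  sum(1 - miss)
}

#' Monte-Carlo random-selection baseline R
#'
#' Draws `reps` uniform p-subsets of sites without replacement and averages
#' the number of species represented. The closed-form hypergeometric
#' expectation is attached for comparison.
#'
#' @inheritParams expected_random_richness
#' @param reps Number of random draws (default 1000).
#' @param seed Integer seed.
#' @return A list of class `ed_random_baseline`: `R` (Monte-Carlo mean),
#'   `se` (standard error of the mean), `expected` (closed form), `reps`, `p`.
#' @export
random_baseline <- function(pa, p, reps = 1000, seed = 1) {
  occ <- pa_matrix(pa)
  n <- nrow(occ)
  if (p < 1 || p > n) abort("p must be in 1..n")
  if (reps < 1) abort("reps must be >= 1")
  withr::local_seed(seed)
  counts <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, p)
    sum(colSums(occ[idx, , drop = FALSE]) > 0)
  }, numeric(1))
  structure(list(R = mean(counts),
                 se = stats::sd(counts) / sqrt(reps),
                 expected = expected_random_richness(pa, p),
                 reps = reps, p = p),
            class = "ed_random_baseline")
}

#' @export
print.ed_random_baseline <- function(x, ...) {
  cat("Random baseline: R =", signif(x$R, 6), "(closed form", signif(x$expected, 6),
      ") over", x$reps, "draws of p =", x$p, "sites\n")
  invisible(x)
}

#' Core-area reverse-ranking of sites
#'
#' Reimplements, for binary occurrences with unit weights and costs, the
#' core-area reverse stepwise ranking: repeatedly remove from the remaining
#' set the site whose most important species loses least, i.e. the site
#' minimizing \eqn{\delta_i = \max_{j \in i} 1 / n_j^{rem}} where
#' \eqn{n_j^{rem}} is species j's occurrence count among remaining sites.
#' Ties are broken by lowest site index. The removal order reversed is the
#' priority ranking: the last site standing ranks first. A site holding a
#' species' final occurrence has \eqn{\delta_i = 1}, the maximum, so it is
#' never removed while any site with spare occurrences remains.
#'
#' @inheritParams species_represented
#' @return Integer vector of site indices, highest priority first.
#' @export
rank_sites_core_area <- function(pa) {
  occ <- pa_matrix(pa)
  n <- nrow(occ)
  S <- ncol(occ)
  remaining <- seq_len(n)
  cnt <- colSums(occ)
  removal <- integer(n)
  for (step in seq_len(n)) {
    w <- 1 / cnt
    w[cnt == 0] <- 0  # species already lost contribute nothing
    M <- occ[remaining, , drop = FALSE] * rep(w, each = length(remaining))
    delta <- M[cbind(seq_along(remaining), max.col(M, ties.method = "first"))]
    pick <- which.min(delta)  # lowest index on ties (remaining kept sorted)
    site <- remaining[pick]
    removal[step] <- site
    cnt <- cnt - occ[site, ]
    remaining <- remaining[-pick]
  }
  rev(removal)
}

#' Near-optimal representation O for p sites
#'
#' The largest number of species representable in p sites, estimated three
#' ways: `"zonation"` takes the top-p prefix of the core-area reverse
#' ranking (the default, and the estimator used for reported O values);
#' `"greedy"` is classic greedy maximum coverage (each step adds the site
#' covering the most unrepresented species, ties by lowest index);
#' `"exact"` enumerates all C(n, p) subsets and is intended as a test oracle
#' on small instances (refused when C(n, p) > 1e6).
#'
#' @inheritParams expected_random_richness
#' @param method One of `"zonation"`, `"greedy"`, `"exact"`.
#' @param ranking Optional precomputed ranking from [rank_sites_core_area()]
#'   (zonation method only), to avoid recomputation across fractions.
#' @return Integer species count.
#' @export
optimal_representation <- function(pa, p, method = c("zonation", "greedy", "exact"),
                                   ranking = NULL) {
  method <- match.arg(method)
  occ <- pa_matrix(pa)
  n <- nrow(occ)
  if (p < 1 || p > n) abort("p must be in 1..n")
  switch(method,
    zonation = {
      if (is.null(ranking)) ranking <- rank_sites_core_area(occ)
      species_represented(occ, ranking[seq_len(p)])
    },
    greedy = {
      covered <- rep(FALSE, ncol(occ))
      sel <- integer(0)
      for (step in seq_len(p)) {
        gain <- occ[, !covered, drop = FALSE]
        score <- rowSums(gain)
        score[sel] <- -1
        pick <- which.max(score)
        sel <- c(sel, pick)
        covered <- covered | occ[pick, ] > 0
      }
      sum(covered)
    },
    exact = {
      if (choose(n, p) > 1e6) {
        abort("exact enumeration refused for C(n, p) > 1e6; use zonation or greedy")
      }
      subsets <- utils::combn(n, p)
      best <- 0L
      for (c_ in seq_len(ncol(subsets))) {
        s <- sum(colSums(occ[subsets[, c_], , drop = FALSE]) > 0)
        if (s > best) best <- s
      }
      best
    })
}

#' Species Accumulation Index
#'
#' `SAI = (S - R)/(O - R)`: the efficiency of a surrogate selection relative
#' to random (0) and optimal (1) selection of the same number of sites.
#' Negative values mean worse than random; the scale runs from -Inf to 1.
#' When O = R the denominator vanishes and the index is undefined: `NA` is
#' returned with a warning. O < R indicates the upstream optimizer failed to
#' beat its own random baseline and is treated as an error.
#'
#' @param S Species represented by the surrogate selection.
#' @param R Random-baseline representation (mean over draws).
#' @param O Optimal (or near-optimal) representation.
#' @return The index value, or `NA` when O = R.
#' @export
#' @examples
#' sai(150, 100, 200)  # 0.5: surrogate realizes half the possible improvement
sai <- function(S, R, O) {
  if (O < R) abort("O < R: the optimizer fell below the random baseline")
  if (O == R) {
    warn("O = R: SAI undefined (zero denominator)")
    return(NA_real_)
  }
  (S - R) / (O - R)
}

#' Selector factories for the SAI sweep
#'
#' A selector is a function taking `p` (sites to select) and returning
#' integer site indices. These factories close over precomputed inputs:
#' `selector_maxdisp()` over the distance matrix in retained-PCA space,
#' `selector_pmedian()` over the 2-D NMDS ordination and its demand grid,
#' `selector_random()` over a seeded RNG stream (a null selector for
#' calibration), and `selector_optimal()` over the presence/absence truth
#' (upper-bound reference; S = O by construction).
#'
#' @param space An `ed_ordination` of the matching kind.
#' @param d Distance matrix in retained-PCA space.
#' @param g,starts,elite_size,seed,max_swaps See [solve_pmedian()].
#' @param pa Presence/absence table (optimal selector).
#' @param method Optimum method for `selector_optimal()`.
#' @return A `function(p)` returning integer site indices.
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_maxdisp <- function(d) {
  d <- as.matrix(d)
  function(p) selected_sites(greedy_maxdisp(d, m = p))
}

#' @rdname selectors
#' @export
selector_pmedian <- function(space, g = 50, starts = 32, elite_size = 10,
                             seed = 1, max_swaps = 200L) {
  demand <- build_demand_grid(space, g = g)
  function(p) selected_sites(solve_pmedian(space, p = p, demand = demand,
                                           starts = starts,
                                           elite_size = elite_size,
                                           seed = seed, max_swaps = max_swaps))
}

#' @rdname selectors
#' @param n Number of sites the random selector draws from.
#' @export
selector_random <- function(n, seed = 1) {
  force(n); force(seed)
  function(p) {
    withr::with_seed(seed + p, sample.int(n, p))
  }
}

#' @rdname selectors
#' @export
selector_optimal <- function(pa, method = "greedy") {
  occ <- pa_matrix(pa)
  ranking <- if (method == "zonation") rank_sites_core_area(occ) else NULL
  function(p) {
    if (method == "zonation") return(ranking[seq_len(p)])
    if (method == "greedy") {
      covered <- rep(FALSE, ncol(occ))
      sel <- integer(0)
      for (step in seq_len(p)) {
        score <- rowSums(occ[, !covered, drop = FALSE])
        score[sel] <- -1
        pick <- which.max(score)
        sel <- c(sel, pick)
        covered <- covered | occ[pick, ] > 0
      }
      return(sel)
    }
    abort("unknown optimal selector method")
  }
}

#' Sweep SAI over reserved-area fractions
#'
#' Evaluates a selector at each fraction of the landscape hypothetically
#' reserved (default 15, 20, 25, 30, 35 percent; `p = round(fraction * n)`,
#' floored at 1), computing S from the selector, R from `reps` random draws,
#' O from the chosen optimum estimator, and SAI per fraction; the summary is
#' the median of the defined SAI values. Fractions where O = R are flagged
#' undefined and excluded from the median with a warning.
#'
#' @inheritParams species_represented
#' @param selector A `function(p)` returning site indices (see
#'   [selectors]).
#' @param fractions Numeric vector of reserved fractions in (0, 1\].
#' @param reps Random-baseline draws per fraction.
#' @param seed Integer root seed (per-fraction baseline seeds are derived by
#'   fixed offsets).
#' @param optimum_method Estimator for O (see [optimal_representation()]).
#' @return An `ed_sai_report`: tibble with columns `fraction`, `p`, `S`,
#'   `R`, `O`, `SAI`, `defined`; attributes `median_sai`, `seed`,
#'   `optimum_method`.
#' @export
sai_sweep <- function(pa, selector,
                      fractions = c(0.15, 0.20, 0.25, 0.30, 0.35),
                      reps = 1000, seed = 1,
                      optimum_method = c("zonation", "greedy", "exact")) {
  optimum_method <- match.arg(optimum_method)
  occ <- pa_matrix(pa)
  n <- nrow(occ)
  if (length(fractions) < 1 || any(fractions <= 0 | fractions > 1)) {
    abort("fractions must lie in (0, 1]")
  }
  ranking <- if (optimum_method == "zonation") rank_sites_core_area(occ) else NULL

  rows <- purrr::imap(fractions, function(f, i) {
    p <- max(1L, as.integer(round(f * n)))
    sel <- selector(p)
    if (length(sel) != p) abort("selector returned a set of the wrong size")
    S <- species_represented(occ, sel)
    R <- random_baseline(occ, p, reps = reps, seed = seed + 1000L + i)$R
    O <- optimal_representation(occ, p, method = optimum_method, ranking = ranking)
    sai_val <- if (O < R) {
      abort(sprintf("O < R at fraction %.2f: optimum estimator below random baseline", f))
    } else if (O == R) NA_real_ else (S - R) / (O - R)
    tibble::tibble(fraction = f, p = p, S = S, R = R, O = O,
                   SAI = sai_val, defined = !is.na(sai_val))
  })
  report <- dplyr::bind_rows(rows)
  if (!any(report$defined)) abort("SAI undefined at every fraction (O = R throughout)")
  if (any(!report$defined)) {
    warn("SAI undefined at some fractions (O = R); excluded from the median")
  }
  structure(report,
            median_sai = stats::median(report$SAI[report$defined]),
            seed = seed, optimum_method = optimum_method,
            class = c("ed_sai_report", class(report)))
}

#' Median SAI of a sweep report
#' @param report An `ed_sai_report`.
#' @return The median of the defined per-fraction SAI values.
#' @export
median_sai <- function(report) {
  stopifnot(inherits(report, "ed_sai_report"))
  attr(report, "median_sai")
}
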