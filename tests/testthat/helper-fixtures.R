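# Fixture builders and independent brute-force oracles used across tests.

# Random coordinates -> distance matrix (tie-free with probability 1).
random_dist <- function(n, d = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
  })
  as.matrix(dist(x))
}

# Random binary occurrence matrix with every species occurring at least once.
random_pa <- function(n_sites, n_species, prob = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(as.integer(runif(n_sites * n_species) < prob), n_sites, n_species)
    for (j in which(colSums(m) == 0)) m[sample.int(n_sites, 1), j] <- 1L
  })
  m
}

# Brute-force maxdisp objective: explicit double loop, independent of the
# vectorized implementation.
bf_maxdisp_objective <- function(d, sel, eps = 1e-12) {
  tot <- 0
  for (a in seq_along(sel)) {
    for (b in seq_along(sel)) {
      if (a < b) {
        dd <- d[sel[a], sel[b]]
        if (dd == 0) dd <- eps
        tot <- tot + 1 / dd^2
      }
    }
  }
  tot
}

# Exhaustive best pair for m = 2 (minimum objective = maximum distance pair).
bf_best_pair <- function(d) {
  n <- nrow(d)
  best <- NULL
  best_obj <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      obj <- bf_maxdisp_objective(d, c(i, j))
      if (obj < best_obj) {
        best_obj <- obj
        best <- c(i, j)
      }
    }
  }
  list(pair = best, objective = best_obj)
}

# Brute-force p-median cost: explicit loops over demand points and sites.
bf_pmedian_cost <- function(coords, sel, demand) {
  tot <- 0
  for (i in seq_len(nrow(demand))) {
    best <- Inf
    for (s in sel) {
      dd <- sqrt(sum((demand[i, ] - coords[s, ])^2))
      if (dd < best) best <- dd
    }
    tot <- tot + best
  }
  tot
}

# Exhaustive p-median optimum over all C(n, p) subsets.
bf_pmedian_opt <- function(coords, p, demand) {
  subsets <- utils::combn(nrow(coords), p)
  best_cost <- Inf
  for (c_ in seq_len(ncol(subsets))) {
    cost <- bf_pmedian_cost(coords, subsets[, c_], demand)
    if (cost < best_cost) best_cost <- cost
  }
  best_cost
}

# Exhaustive maximum species coverage over all C(n, p) subsets.
bf_max_coverage <- function(occ, p) {
  subsets <- utils::combn(nrow(occ), p)
  best <- 0L
  for (c_ in seq_len(ncol(subsets))) {
    s <- sum(colSums(occ[subsets[, c_], , drop = FALSE]) > 0)
    if (s > best) best <- s
  }
  best
}

# Mean species count over ALL p-subsets (exact random baseline by enumeration).
bf_random_expectation <- function(occ, p) {
  subsets <- utils::combn(nrow(occ), p)
  mean(apply(subsets, 2, function(s) {
    sum(colSums(occ[s, , drop = FALSE]) > 0)
  }))
}
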