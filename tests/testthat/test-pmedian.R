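unit_square <- function() matrix(c(0, 1, 0, 1, 0, 0, 1, 1), 4, 2)

test_that("demand grids tile the bounding box with g^2 cell centroids", {
  sq <- unit_square()
  g1 <- build_demand_grid(sq, g = 1)
  expect_equal(nrow(g1), 1)
  expect_equal(unlist(g1[1, ], use.names = FALSE), c(0.5, 0.5))

  g2 <- build_demand_grid(sq, g = 2)
  expect_equal(nrow(g2), 4)
  expect_setequal(paste(g2$x, g2$y),
                  c("0.25 0.25", "0.25 0.75", "0.75 0.25", "0.75 0.75"))

  withr::with_seed(1, pts <- matrix(rnorm(200), 100, 2))
  g50 <- build_demand_grid(pts, g = 50)
  expect_equal(nrow(g50), 2500)
  # strictly inside the bounding box
  expect_true(all(g50$x > min(pts[, 1]) & g50$x < max(pts[, 1])))
  expect_true(all(g50$y > min(pts[, 2]) & g50$y < max(pts[, 2])))
})

test_that("degenerate axes are rejected", {
  flat <- cbind(c(0, 1, 2), c(3, 3, 3))
  expect_error(build_demand_grid(flat, g = 10), "degenerate")
})

test_that("p-median cost matches the brute-force oracle and its bounds", {
  withr::with_seed(2, {
    coords <- matrix(runif(10), 5, 2)
    demand <- matrix(runif(8), 4, 2)
  })
  # every p = 2 subset agrees with the double-loop oracle
  for (pair in utils::combn(5, 2, simplify = FALSE)) {
    expect_equal(pmedian_cost(coords, pair, demand),
                 bf_pmedian_cost(coords, pair, demand))
  }
  # a site coincident with the single centroid gives zero cost
  c1 <- build_demand_grid(unit_square(), g = 1)
  coin <- rbind(c(0.5, 0.5), unit_square())
  expect_equal(pmedian_cost(coin, 1, c1), 0)
  # cost is monotone non-increasing in the selected set
  full <- pmedian_cost(coords, 1:5, demand)
  for (pair in utils::combn(5, 2, simplify = FALSE)) {
    expect_gte(pmedian_cost(coords, pair, demand), full - 1e-12)
  }
  expect_error(pmedian_cost(coords, integer(0), demand), "one selected")
})

test_that("the heuristic recovers exhaustive optima on small instances", {
  withr::with_seed(3, coords <- matrix(rnorm(20), 10, 2))
  demand <- build_demand_grid(coords, g = 6)
  dm <- as.matrix(demand[, c("x", "y")])
  for (p in 1:3) {
    sol <- solve_pmedian(coords, p = p, demand = demand, starts = 8,
                         elite_size = 4, seed = 10 + p)
    expect_equal(attr(sol, "objective"), bf_pmedian_opt(coords, p, dm),
                 tolerance = 1e-9)
    expect_equal(pmedian_cost(coords, selected_sites(sol), demand),
                 attr(sol, "objective"))
  }
})

test_that("p = n selects everything at the global lower bound", {
  withr::with_seed(4, coords <- matrix(rnorm(16), 8, 2))
  demand <- build_demand_grid(coords, g = 5)
  sol <- solve_pmedian(coords, p = 8, demand = demand, starts = 4,
                       elite_size = 2, seed = 1)
  expect_setequal(selected_sites(sol), 1:8)
  expect_equal(attr(sol, "objective"), pmedian_cost(coords, 1:8, demand))
})

test_that("the solver is deterministic given the seed and validates p", {
  withr::with_seed(5, coords <- matrix(rnorm(30), 15, 2))
  demand <- build_demand_grid(coords, g = 6)
  a <- solve_pmedian(coords, p = 4, demand = demand, starts = 6, elite_size = 3, seed = 7)
  b <- solve_pmedian(coords, p = 4, demand = demand, starts = 6, elite_size = 3, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_error(solve_pmedian(coords, p = 16, demand = demand), "p > n")
  expect_error(solve_pmedian(coords, p = 4, demand = demand, starts = 2,
                             elite_size = 5), "elite_size")
})

test_that("the returned cost never exceeds any start's construction cost", {
  withr::with_seed(6, coords <- matrix(rnorm(40), 20, 2))
  demand <- build_demand_grid(coords, g = 8)
  sol <- solve_pmedian(coords, p = 5, demand = demand, starts = 10,
                       elite_size = 5, seed = 3)
  diag_ <- attr(sol, "diagnostics")
  expect_true(all(attr(sol, "objective") <= diag_$construction_cost + 1e-12))
  expect_true(all(diag_$local_cost <= diag_$construction_cost + 1e-12))
})
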