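test_that("species representation counts presences among selected sites", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(species_represented(m, integer(0)), 0L)
  expect_equal(species_represented(m, 1:3), 2L)
  expect_equal(species_represented(m, 1:2), 1L)
  expect_error(species_represented(m, 5), "out of range")
})

test_that("closed-form random baseline matches full enumeration", {
  # one species at exactly 1 of 4 sites, p = 2: expectation 1 - C(3,2)/C(4,2) = 0.5
  m <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(expected_random_richness(m, 2), 0.5)
  # random fixtures: closed form equals the mean over all subsets
  for (seed in 1:5) {
    occ <- random_pa(7, 5, prob = 0.35, seed = seed)
    for (p in c(2, 3)) {
      expect_equal(expected_random_richness(occ, p),
                   bf_random_expectation(occ, p), tolerance = 1e-10)
    }
  }
})

test_that("Monte-Carlo baseline agrees with the closed form within 3 SE", {
  occ <- random_pa(30, 20, prob = 0.2, seed = 3)
  rb <- random_baseline(occ, p = 8, reps = 1000, seed = 4)
  expect_lt(abs(rb$R - rb$expected), 3 * max(rb$se, 1e-9))
  # p = n represents everything with zero variance
  rb_full <- random_baseline(occ, p = 30, reps = 10, seed = 1)
  expect_equal(rb_full$R, 20)
  expect_equal(rb_full$se, 0)
})

test_that("core-area ranking honours tie-breaks and irreplaceable sites", {
  # every site hosts the same single species: removal is pure tie-breaking,
  # so the priority ranking is reverse site order
  mono <- matrix(1L, 6, 1)
  expect_equal(rank_sites_core_area(mono), 6:1)

  # a species with a single occurrence protects its site until the end
  occ <- rbind(
    c(1, 0, 0),  # site 1: sole holder of species 1
    c(0, 1, 1),
    c(0, 1, 1),
    c(0, 1, 0),
    c(0, 0, 1))
  rk <- rank_sites_core_area(occ)
  expect_lte(which(rk == 1), 3)  # within the top n_species positions
  # the full ranking prefix represents every species
  expect_equal(species_represented(occ, rk), 3L)
})

test_that("optimum estimators agree at p = n and obey dominance", {
  occ <- random_pa(12, 8, prob = 0.25, seed = 5)
  for (m in c("zonation", "greedy", "exact")) {
    expect_equal(optimal_representation(occ, 12, method = m), 8L)
  }
  for (seed in 1:10) {
    occ <- random_pa(12, 8, prob = 0.2, seed = seed)
    ex <- optimal_representation(occ, 3, method = "exact")
    expect_equal(ex, bf_max_coverage(occ, 3))
    expect_gte(ex, optimal_representation(occ, 3, method = "greedy"))
    expect_gte(ex, optimal_representation(occ, 3, method = "zonation"))
  }
})

test_that("a known small instance is solved exactly and bounds the greedy", {
  # 6 sites, 5 species; sites 1 and 2 together cover all five
  occ <- rbind(
    c(1, 1, 1, 0, 0),
    c(0, 0, 0, 1, 1),
    c(1, 1, 0, 0, 0),
    c(0, 0, 1, 1, 0),
    c(1, 0, 0, 0, 1),
    c(0, 1, 0, 1, 0))
  ex <- optimal_representation(occ, 2, method = "exact")
  expect_equal(ex, 5L)
  gr <- optimal_representation(occ, 2, method = "greedy")
  expect_gte(gr, ceiling((1 - 1 / exp(1)) * ex))
})

test_that("exact enumeration refuses oversized instances", {
  occ <- random_pa(40, 5, seed = 1)
  expect_error(optimal_representation(occ, 15, method = "exact"), "refused")
})

test_that("the SAI formula is oriented and bounded as documented", {
  expect_equal(sai(150, 100, 200), 0.5)
  expect_equal(sai(200, 100, 200), 1)
  expect_equal(sai(100, 100, 200), 0)
  expect_equal(sai(90, 100, 200), -0.1)   # worse than random
  expect_error(sai(150, 210, 200), "O < R")
  expect_warning(v <- sai(150, 200, 200), "undefined")
  expect_true(is.na(v))
  # strictly increasing in S for fixed R < O
  s_vals <- vapply(c(100, 120, 140, 160), sai, numeric(1), R = 100, O = 200)
  expect_true(all(diff(s_vals) > 0))
})

test_that("the fraction sweep sizes p correctly and scores an oracle at 1", {
  occ <- random_pa(100, 25, prob = 0.08, seed = 7)
  rep <- sai_sweep(occ, selector_optimal(occ, method = "greedy"),
                   reps = 300, seed = 8, optimum_method = "greedy")
  expect_equal(rep$p, c(15L, 20L, 25L, 30L, 35L))
  defined <- rep$defined
  expect_true(all(abs(rep$SAI[defined] - 1) < 1e-9))
  expect_equal(median_sai(rep), 1)
})

test_that("the sweep flags a selector of the wrong size and empty results", {
  occ <- random_pa(40, 10, seed = 9)
  expect_error(sai_sweep(occ, function(p) 1:2, reps = 10, seed = 1),
               "wrong size")
})

test_that("a uniform random selector scores near zero", {
  occ <- random_pa(80, 30, prob = 0.1, seed = 10)
  meds <- vapply(1:20, function(r) {
    sel <- selector_random(80, seed = 1000 + r)
    median_sai(sai_sweep(occ, sel, reps = 300, seed = 11))
  }, numeric(1))
  expect_lt(abs(mean(meds)), 0.1)
})
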