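make_env <- function(n = 60, seed = 1) {
  simulate_environment(n_sites = n,
                       variable_groups = c(temperature = 10, precipitation = 9,
                                           insolation = 7, ndvi = 5, topography = 7),
                       seed = seed)
}

test_that("CVT subsetting keeps exactly the tagged columns, order preserved", {
  env <- make_env()
  expect_identical(names(subset_cvt(env, "CVT1")), names(env))
  cvt4 <- subset_cvt(env, "CVT4")
  expect_equal(ncol(cvt4) - 1, 19)  # 10 temperature + 9 precipitation
  expect_true(all(attr(cvt4, "var_types") %in% c("temperature", "precipitation")))
  cvt5 <- subset_cvt(env, "CVT5")
  expect_equal(ncol(cvt5) - 1, 14)
  # column order within the subset matches the original table
  expect_identical(names(cvt4)[-1], intersect(names(env), names(cvt4))[-1])
})

test_that("CVT subsetting errors when an included type is absent", {
  env <- simulate_environment(n_sites = 30,
                              variable_groups = c(temperature = 5, precipitation = 5),
                              seed = 1)
  expect_error(subset_cvt(env, "CVT5"), "insolation|topography")
  expect_silent(subset_cvt(env, "CVT4"))
})

test_that("two perfectly correlated pairs give eigenvalues {2, 2, 0, 0} and k = 2", {
  withr::with_seed(7, {
    a <- rnorm(50)
    b <- rnorm(50)
  })
  X <- cbind(t1 = a, t2 = 2 * a + 5, p1 = b, p2 = -3 * b)
  # orthogonalize b against a so the pairs are exactly uncorrelated
  X[, 3] <- residuals(lm(b ~ a))
  X[, 4] <- -3 * X[, 3]
  sp <- pca_kaiser(X)
  expect_equal(sort(sp$eigenvalues, decreasing = TRUE), c(2, 2, 0, 0),
               tolerance = 1e-8)
  expect_equal(sp$k, 2)
})

test_that("eigenvalues sum to the number of variables (correlation trace)", {
  env <- make_env(n = 40, seed = 3)
  sp <- pca_kaiser(env)
  expect_equal(sum(sp$eigenvalues), ncol(env) - 1)
})

test_that("PCA scores are invariant to affine rescaling of input columns", {
  env <- make_env(n = 40, seed = 4)
  X <- as.matrix(env[, -1])
  Y <- sweep(sweep(X, 2, runif(ncol(X), 0.5, 10), "*"), 2, rnorm(ncol(X)), "+")
  s1 <- pca_kaiser(X)
  s2 <- pca_kaiser(Y)
  c1 <- as.matrix(s1$coordinates[, -1])
  c2 <- as.matrix(s2$coordinates[, -1])
  expect_equal(s1$eigenvalues, s2$eigenvalues)
  # scores agree up to per-axis sign
  for (k in seq_len(s1$k)) {
    expect_equal(abs(c1[, k]), abs(c2[, k]), tolerance = 1e-8)
  }
})

test_that("zero-variance columns are rejected; Kaiser fallback keeps one axis", {
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(pca_kaiser(X), "zero-variance")
  # exactly orthogonal columns: all eigenvalues 1, none exceeds the cutoff
  Y <- cbind(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5))
  expect_warning(sp <- pca_kaiser(Y), "largest component")
  expect_equal(sp$k, 1)
  expect_true(sp$kaiser_fallback)
})

test_that("NMDS recovers an embeddable 2-D configuration with near-zero stress", {
  withr::with_seed(11, pts <- matrix(runif(40), 20, 2))
  d <- as.matrix(dist(pts))
  nm <- nmds_2d(d, seed = 1)
  expect_lte(nm$stress, 0.01)
  expect_equal(nm$k, 2)
})

test_that("NMDS is deterministic given the seed and needs at least 3 sites", {
  d <- random_dist(30, d = 4, seed = 2)
  a <- nmds_2d(d, seed = 5)
  b <- nmds_2d(d, seed = 5)
  expect_identical(a$coordinates, b$coordinates)
  expect_error(nmds_2d(as.matrix(dist(c(0, 1))), seed = 1), "3 sites")
})

test_that("2-D NMDS distances rank-correlate strongly with 4-D input distances", {
  withr::with_seed(3, x <- matrix(rnorm(400), 100, 4))
  d <- as.matrix(dist(x))
  nm <- nmds_2d(d, seed = 1)
  d2 <- dist(as.matrix(nm$coordinates[, -1]))
  rho <- cor(as.vector(as.dist(d)), as.vector(d2), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("NMDS refinement does not increase stress over the initial configuration", {
  d <- random_dist(40, d = 5, seed = 6)
  s0 <- nmds_2d(d, seed = 2, max_iter = 0)$stress
  s1 <- nmds_2d(d, seed = 2, max_iter = 200)$stress
  expect_lte(s1, s0 + 1e-12)
})

test_that("ordination distances match a brute-force double loop", {
  withr::with_seed(8, x <- matrix(rnorm(30), 10, 3))
  sp <- structure(list(coordinates = tibble::tibble(site_id = as.character(1:10),
                                                    A = x[, 1], B = x[, 2], C = x[, 3]),
                       kind = "pca", k = 3L, eigenvalues = rep(1, 3)),
                  class = "ed_ordination")
  d <- ordination_distances(sp)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # 3-4-5 triangle and coincident sites
  dd <- ordination_distances(structure(
    list(coordinates = tibble::tibble(site_id = c("a", "b", "c"),
                                      x = c(0, 3, 0), y = c(0, 4, 0)),
         kind = "pca", k = 2L, eigenvalues = c(1, 1)), class = "ed_ordination"))
  expect_equal(dd["a", "b"], 5)
  expect_equal(dd["a", "c"], 0)
})

test_that("pairwise distances satisfy the triangle inequality", {
  d <- random_dist(25, d = 4, seed = 13)
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:5) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})
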