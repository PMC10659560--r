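random_hyperboloid_points <- function(n, d, scale = 1) {
  lift <- chromAge:::lift_hyperboloid
  lift(matrix(rnorm(n * d, sd = scale), n, d))
}

test_that("information distance satisfies its defining identities", {
  withr::local_seed(1)
  x <- runif(400)
  expect_equal(informationDistance(x, x), 0)
  # hand-computed two-bin case: x alternates bins, y constant
  # H(X) = 1 bit, H(Y) = 0, H(X,Y) = 1 -> D = (2 - 1 - 0)/1 = 1
  x2 <- rep(c(0.05, 0.95), 50)
  y2 <- rep(0.55, 100)
  expect_equal(informationDistance(x2, y2, normalize = "none"), 1)
  # base invariance: D is a ratio of entropies
  y <- runif(400)
  expect_equal(informationDistance(x, y, base = 2),
               informationDistance(x, y, base = exp(1)), tolerance = 1e-12)
  # symmetry and range
  for (i in 1:5) {
    a <- runif(200); b <- runif(200)
    d1 <- informationDistance(a, b)
    expect_equal(d1, informationDistance(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
  expect_error(informationDistance(runif(5), runif(6)), "equal length")
  expect_error(informationDistance(x, y, h = 0.13), "integer")
})

test_that("independent samples approach distance 1 as features grow", {
  withr::local_seed(2)
  d_small <- mean(vapply(1:10, function(i)
    informationDistance(runif(50), runif(50)), numeric(1)))
  d_large <- mean(vapply(1:10, function(i)
    informationDistance(runif(5000), runif(5000)), numeric(1)))
  expect_gt(d_large, d_small)
  expect_gt(d_large, 0.95)
})

test_that("distance matrices are symmetric, zero-diagonal, and metric-sane", {
  withr::local_seed(3)
  m <- matrix(runif(5 * 100), 5, 100)
  m <- rbind(m, m[1, ])                      # duplicated row
  for (metric in c("information", "euclidean")) {
    D <- distanceMatrix(m, metric)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), numeric(6))
  }
  expect_equal(distanceMatrix(m, "information")[1, 6], 0)
  De <- distanceMatrix(m, "euclidean")
  # Euclidean triangle inequality spot-check
  expect_lte(De[1, 2], De[1, 3] + De[3, 2] + 1e-12)
})

test_that("Euclidean MDS recovers planar data and reports honest stress", {
  withr::local_seed(4)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  e <- emds(D, 2)
  expect_lt(e$stress, 1e-9)
  expect_gt(e$r2, 1 - 1e-9)
  # star-tree metric (3 leaves at pairwise 2 via a hub at 1) cannot embed in 2D
  Dt <- matrix(2, 4, 4) - diag(2, 4)
  Dt[1, ] <- Dt[, 1] <- 1; Dt[1, 1] <- 0
  expect_gt(emds(Dt, 2)$stress, 0.01)
  # stress is non-increasing in target dimension
  Dr <- as.matrix(dist(matrix(rnorm(60), 10, 6)))
  stresses <- vapply(1:5, function(k) emds(Dr, k)$stress, numeric(1))
  expect_true(all(diff(stresses) < 1e-9))
})

test_that("shepherd R2 equals direct arithmetic on a 4x4 case", {
  A <- matrix(0, 4, 4); A[upper.tri(A)] <- c(1, 2, 3, 4, 5, 6)
  A <- A + t(A)
  B <- matrix(0, 4, 4); B[upper.tri(B)] <- c(1.1, 1.9, 3.2, 4.1, 4.8, 6.3)
  B <- B + t(B)
  expect_equal(shepherdR2(A, B),
               cor(c(1, 2, 3, 4, 5, 6), c(1.1, 1.9, 3.2, 4.1, 4.8, 6.3))^2)
  expect_equal(shepherdR2(A, A), 1)
})

test_that("HMDS re-embeds hyperboloid-generated distances near-perfectly", {
  withr::local_seed(5)
  pts <- random_hyperboloid_points(15, 3, scale = 0.8)
  D <- hyperbolicDistance(pts, kappa = 1)
  emb <- hmds(D, dim = 3, kappa = 1, seed = 11)
  expect_gt(emb@r2, 0.99)
  expect_lt(emb@stress, 0.05)
  # hyperboloid constraint holds for every embedded point
  q <- diag(chromAge:::lorentz_inner(emb@coords, emb@coords))
  expect_true(all(abs(q + 1) < 1e-9))
  # bit-reproducible under a fixed seed
  emb2 <- hmds(D, dim = 3, kappa = 1, seed = 11)
  expect_identical(emb@coords, emb2@coords)
  # two points embed exactly
  D2 <- matrix(c(0, 0.7, 0.7, 0), 2)
  expect_lt(hmds(D2, dim = 2, kappa = 1, seed = 1)@stress, 1e-6)
})

test_that("hyperbolic embedding beats Euclidean on tree-like distances", {
  # balanced binary tree metric: hierarchical structure favors negative
  # curvature at equal embedding dimension
  withr::local_seed(6)
  n_leaves <- 16
  depth <- 4
  path_len <- function(i, j) {
    if (i == j) return(0)
    a <- i - 1; b <- j - 1; d <- 0
    while (a != b) {
      if (a >= b) a <- a %/% 2 else b <- b %/% 2
      d <- d + 1
    }
    d
  }
  idx <- (2^depth):(2^(depth + 1) - 1)
  D <- outer(seq_len(n_leaves), seq_len(n_leaves),
             Vectorize(function(i, j) path_len(idx[i], idx[j])))
  r2_h <- hmds(D, dim = 2, kappa = 2, seed = 3)@r2
  r2_e <- emds(D, 2)$r2
  expect_gt(r2_h, r2_e - 0.02)
})

test_that("geometry grid search returns the full table and a sane optimum", {
  withr::local_seed(7)
  pts <- random_hyperboloid_points(12, 2, scale = 0.9)
  D <- hyperbolicDistance(pts, kappa = 2)
  single <- selectGeometry(D, dims = 3, kappas = 1, seed = 2)
  expect_equal(c(single$dim, single$kappa), c(3, 1))
  sel <- selectGeometry(D, dims = 2:3, kappas = c(0.5, 2, 8), seed = 2)
  expect_equal(nrow(sel$table), 6)
  expect_gt(sel$best@r2, 0.98)
  # recovered curvature within one grid step of the generating one
  expect_true(sel$kappa %in% c(0.5, 2))
})

test_that("Karcher mean behaves at fixed points, midpoints, and symmetry", {
  lift <- chromAge:::lift_hyperboloid
  p1 <- lift(c(0.3, -0.2)); p2 <- lift(c(-0.5, 0.4))
  expect_equal(hyperbolicCentroid(p1), as.numeric(p1), tolerance = 1e-8)
  mid <- hyperbolicCentroid(rbind(p1, p2))
  d1 <- hyperbolicDistance(rbind(mid, p1))[1, 2]
  d2 <- hyperbolicDistance(rbind(mid, p2))[1, 2]
  expect_lt(abs(d1 - d2), 1e-6)
  # centroid of a reflection-symmetric cloud sits at the symmetry center
  z <- rbind(c(0.4, 0.1), c(-0.4, 0.1), c(0.4, -0.1), c(-0.4, -0.1),
             c(0.2, 0.3), c(-0.2, 0.3), c(0.2, -0.3), c(-0.2, -0.3))
  cen <- hyperbolicCentroid(lift(z))
  expect_equal(cen[2], 0, tolerance = 1e-7)
  expect_equal(cen[3], 0, tolerance = 1e-7)
})

test_that("geodesic readout hits the endpoints and the flat-space limit", {
  lift <- chromAge:::lift_hyperboloid
  a <- lift(c(0.2, 0.1, 0)); b <- lift(c(-0.3, 0.25, 0.1))
  L <- hyperbolicDistance(rbind(a, b))[1, 2]
  pr_a <- hyperbolicImAge(a, a, b)
  expect_equal(pr_a$p, 0, tolerance = 1e-6)
  expect_equal(pr_a$d_o, 0, tolerance = 1e-6)
  pr_b <- hyperbolicImAge(b, a, b)
  expect_equal(pr_b$p, L, tolerance = 1e-6)
  expect_equal(pr_b$d_o, 0, tolerance = 1e-6)
  expect_error(hyperbolicImAge(a, a, a), "degenerate")
  # near the origin the hyperboloid is flat: geodesic projection matches
  # the Euclidean axis projection on the spatial coordinates
  withr::local_seed(8)
  scale <- 1e-3
  za <- c(-1, 0, 0) * scale; zb <- c(1, 0.2, 0) * scale
  zx <- matrix(rnorm(30, sd = scale), 10, 3)
  pr_h <- hyperbolicImAge(lift(zx), lift(za), lift(zb))
  u <- (zb - za) / sqrt(sum((zb - za)^2))
  p_e <- as.numeric(sweep(zx, 2, za) %*% u)
  expect_lt(max(abs(pr_h$p - p_e)), 1e-6)
})

test_that("geodesic variance fraction spans on-axis to isotropic regimes", {
  lift <- chromAge:::lift_hyperboloid
  a <- lift(c(-0.5, 0, 0)); b <- lift(c(0.5, 0, 0))
  on_geo <- lift(cbind(seq(-0.4, 0.4, length.out = 9), 0, 0))
  expect_equal(geodesicVarianceFraction(on_geo, a, b), 1, tolerance = 1e-6)
  withr::local_seed(9)
  iso <- lift(matrix(rnorm(3 * 800, sd = 0.05), 800, 3))
  f <- geodesicVarianceFraction(iso, a, b)
  expect_equal(f, 1 / 3, tolerance = 0.05)
  # drift along the geodesic raises the fraction monotonically
  drift <- lift(cbind(seq(-0.4, 0.4, length.out = 800),
                      matrix(rnorm(2 * 800, sd = 0.05), 800, 2)))
  expect_gt(geodesicVarianceFraction(drift, a, b), f)
})
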