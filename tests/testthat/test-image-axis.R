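make_blobs <- function(n = 40, d = 4, sep = 3, seed = 1) {
  withr::local_seed(seed)
  young <- matrix(rnorm(n * d), n, d)
  old <- matrix(rnorm(n * d), n, d)
  old[, 1] <- old[, 1] + sep
  list(z = rbind(young, old),
       groups = rep(c("young", "old"), each = n))
}

test_that("centroid axis connects the group centroids, oriented young to old", {
  z <- rbind(matrix(0, 5, 2), cbind(rep(2, 5), 0))
  groups <- rep(c("young", "old"), each = 5)
  ax <- fitCentroidAxis(z, groups)
  expect_equal(ax@direction, c(1, 0))
  expect_equal(ax@origin, c(0, 0))
  # swapping the labels swaps the roles: the axis still runs from the
  # young-labeled centroid to the old-labeled one, so old projects higher
  ax2 <- fitCentroidAxis(z, rev(groups))
  expect_equal(ax2@direction, c(-1, 0))
  p2 <- projectOnAxis(z, ax2, standardized = TRUE)$p
  expect_gt(mean(p2[rev(groups) == "old"]), mean(p2[rev(groups) == "young"]))
  expect_error(fitCentroidAxis(matrix(0, 4, 2),
                               rep(c("young", "old"), 2)), "degenerate")
  expect_error(fitCentroidAxis(z, rep("young", 10)), "missing reference")
})

test_that("SVM axis separates linearly separable blobs perfectly", {
  b <- make_blobs(sep = 8, seed = 2)
  ax <- fitSVMAxis(b$z, b$groups)
  expect_equal(separationAccuracy(b$z, b$groups, ax), 1)
  # orientation: old mean projection above young
  p <- projectOnAxis(b$z, ax, standardized = TRUE)$p
  expect_gt(mean(p[b$groups == "old"]), mean(p[b$groups == "young"]))
})

test_that("SVM and centroid directions differ on anisotropic separable data", {
  withr::local_seed(3)
  n <- 60
  young <- cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 4))
  old <- cbind(rnorm(n, 3, 0.3), rnorm(n, 3, 4))
  z <- rbind(young, old); groups <- rep(c("young", "old"), each = n)
  a1 <- fitCentroidAxis(z, groups); a2 <- fitSVMAxis(z, groups)
  expect_gt(sum(abs(a1@direction - a2@direction)), 0.05)
  for (ax in list(a1, a2)) {
    p <- projectOnAxis(z, ax, standardized = TRUE)$p
    expect_gt(mean(p[groups == "old"]), mean(p[groups == "young"]))
  }
})

test_that("SVM beats the centroid axis on a skewed young mixture", {
  wins <- vapply(1:20, function(s) {
    withr::local_seed(s)
    n <- 60
    # young group: main mode plus a distant minor mode pulling the centroid
    young <- rbind(cbind(rnorm(0.8 * n, 0, 0.4), rnorm(0.8 * n, 0, 0.4)),
                   cbind(rnorm(0.2 * n, -12, 0.4), rnorm(0.2 * n, 9, 0.4)))
    old <- cbind(rnorm(n, 3, 0.4), rnorm(n, 0, 0.4))
    z <- rbind(young, old); groups <- rep(c("young", "old"), each = n)
    tr <- c(sample(which(groups == "young"), 45),
            sample(which(groups == "old"), 45))
    te <- setdiff(seq_len(2 * n), tr)
    acc <- vapply(c("centroid", "svm"), function(m) {
      ax <- if (m == "svm") fitSVMAxis(z[tr, ], groups[tr])
            else fitCentroidAxis(z[tr, ], groups[tr])
      separationAccuracy(z[te, ], groups[te], ax)
    }, numeric(1))
    acc["svm"] - acc["centroid"]
  }, numeric(1))
  expect_gt(mean(wins), 0)
  expect_gt(mean(wins >= 0), 0.8)
})

test_that("projection matches an independent distance-to-line oracle", {
  withr::local_seed(5)
  z <- matrix(rnorm(200), 40, 5)
  b <- make_blobs(d = 5, seed = 6)
  ax <- fitCentroidAxis(b$z, b$groups)
  pr <- projectOnAxis(z, ax, standardized = TRUE)
  for (i in 1:10) {
    x <- z[i, ]
    # oracle: minimize |x - (origin + t u)| over t
    f <- function(t) sqrt(sum((x - ax@origin - t * ax@direction)^2))
    o <- optimize(f, c(-100, 100), tol = 1e-12)
    expect_equal(pr$d_o[i], o$objective, tolerance = 1e-9)
    expect_equal(pr$p[i], o$minimum, tolerance = 1e-6)
  }
  # Pythagoras and affine equivariance
  rel2 <- rowSums(sweep(z, 2, ax@origin)^2)
  expect_equal(pr$d_o^2 + pr$p^2, rel2, tolerance = 1e-9)
  shift <- rnorm(5)
  ax_s <- ax; ax_s@origin <- ax@origin + shift
  pr_s <- projectOnAxis(sweep(z, 2, -shift), ax_s, standardized = TRUE)
  expect_equal(pr_s$p, pr$p, tolerance = 1e-9)
  expect_equal(pr_s$d_o, pr$d_o, tolerance = 1e-9)
  expect_error(projectOnAxis(z[, 1:3], ax), "mismatch")
})

test_that("variance fraction is 1 on-axis and about 1/d for isotropic noise", {
  withr::local_seed(7)
  d <- 8
  b <- make_blobs(d = d, seed = 8)
  ax <- fitCentroidAxis(b$z, b$groups)
  on_axis <- outer(rnorm(30), ax@direction) +
    matrix(ax@origin, 30, d, byrow = TRUE)
  expect_equal(axisVarianceFraction(on_axis, ax), 1, tolerance = 1e-9)
  iso <- matrix(rnorm(4000 * d), 4000, d)
  expect_equal(axisVarianceFraction(iso, ax), 1 / d, tolerance = 0.2 / d * 3)
  expect_error(axisVarianceFraction(matrix(1, 5, d), ax), "zero total")
})

test_that("identical young/old distributions give chance-level accuracy", {
  accs <- vapply(1:10, function(s) {
    withr::local_seed(100 + s)
    z <- matrix(rnorm(200), 100, 2)
    groups <- rep(c("young", "old"), 50)
    ax <- fitSVMAxis(z[1:80, ], groups[1:80])
    separationAccuracy(z[81:100, ], groups[81:100], ax)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("age correlation reports monotone fixtures and aggregation metadata", {
  readouts <- data.frame(animal = rep(letters[1:6], each = 10),
                         age = rep(c(2, 5, 10, 15, 20, 27), each = 10),
                         p = rep(1:6, each = 10) + rnorm(60, sd = 0.01))
  ac <- ageCorrelation(readouts)
  expect_equal(unname(ac$spearman["rho"]), 1)
  expect_equal(ac$aggregation, "median")
  expect_equal(ageCorrelation(readouts, "mean")$aggregation, "mean")
  expect_error(ageCorrelation(readouts[1:10, ]), ">= 3 animals")
  readouts$p <- 1
  expect_error(ageCorrelation(readouts), "constant")
})

test_that("organ-pair robustness needs significance in every age subset", {
  withr::local_seed(9)
  base <- data.frame(animal = sprintf("m%02d", 1:12),
                     age = rep(c(2, 15, 27), each = 4))
  t_lin <- base$age + rnorm(12, sd = 0.3)
  mk <- function(organ, p) cbind(base, organ = organ, channel = "mark", p = p)
  # liver and blood share the signal; kidney correlates only through one
  # age group (constant within the other two ages)
  kidney <- ifelse(base$age == 27, t_lin, 0.01 * rnorm(12))
  readouts <- rbind(mk("liver", t_lin), mk("blood", t_lin + rnorm(12, sd = 0.05)),
                    mk("kidney", kidney))
  rp <- organPairSpearman(readouts)
  expect_equal(attr(rp, "bonferroni_factor"), 3 * 1 * 4)
  lb <- rp[rp$organ_a == "blood" & rp$organ_b == "liver", ]
  expect_true(lb$robust)
  kid <- rp[rp$organ_a == "kidney" | rp$organ_b == "kidney", ]
  expect_false(any(kid$robust))
  # identical readouts across organs: rho = 1 everywhere, robust
  dup <- rbind(mk("a", t_lin), mk("b", t_lin))
  rd <- organPairSpearman(dup)
  expect_equal(rd$rho_full, 1)
  expect_true(rd$robust)
})

test_that("validation protocol separates and orders a drifting cohort", {
  co <- tiny_cohort(seed = 21)
  v <- validateAxis(co$boot, "centroid", n_iterations = 20, seed = 22)
  expect_length(v$accuracy, 20)
  expect_gt(v$accuracy_mean, 0.9)
  by_age <- aggregate(readout ~ age, v$per_animal, median)
  expect_equal(cor(by_age$readout, by_age$age, method = "spearman"), 1)
  # centroid and SVM readouts recover the same ordering
  vs <- validateAxis(co$boot, "svm", n_iterations = 10, seed = 22)
  m <- merge(v$per_animal, vs$per_animal, by = "animal")
  expect_gt(cor(m$readout.x, m$readout.y, method = "spearman"), 0.9)
})

test_that("axis JSON round trip preserves projection behavior", {
  b <- make_blobs(seed = 30)
  std <- zscoreFit(b$z)
  ax <- fitCentroidAxis(zscoreApply(b$z, std), b$groups, standardizer = std)
  td <- withr::local_tempdir()
  fp <- file.path(td, "axis.json")
  writeAxisJson(ax, fp)
  ax2 <- readAxisJson(fp)
  pr1 <- projectOnAxis(b$z, ax, standardized = FALSE)
  pr2 <- projectOnAxis(b$z, ax2, standardized = FALSE)
  expect_equal(pr1$p, pr2$p, tolerance = 1e-12)
})
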