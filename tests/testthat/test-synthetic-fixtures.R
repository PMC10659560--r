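test_that("image fixture validates input and is seed-deterministic", {
  expect_error(makeImageFixture(n_nuclei = 0), "n_nuclei")
  a <- makeImageFixture(n_nuclei = 5, field_shape = c(128, 128), seed = 1)
  b <- makeImageFixture(n_nuclei = 5, field_shape = c(128, 128), seed = 1)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_false(identical(
    a$image, makeImageFixture(n_nuclei = 5, field_shape = c(128, 128),
                              seed = 2)$image))
  # impossible packing triggers the placement error
  expect_error(makeImageFixture(n_nuclei = 50, nucleus_radius_px = 20,
                                field_shape = c(100, 100), seed = 1),
               "placement")
})

test_that("texture granularity drift with age shifts TAS features", {
  feats <- function(age, seed) {
    fx <- makeImageFixture(n_nuclei = 8, age_latent = age,
                           field_shape = c(192, 192), seed = seed)
    featuresFromRecords(loadLabeledImage(fx$image, fx$mask,
                                         c("DAPI", "mark")))$features
  }
  young <- do.call(rbind, lapply(1:3, function(s) feats(0.1, s)))
  old <- do.call(rbind, lapply(1:3, function(s) feats(0.9, s + 100)))
  p <- vapply(seq_len(ncol(young)), function(j) {
    if (sd(young[, j]) == 0 && sd(old[, j]) == 0) return(1)
    t.test(young[, j], old[, j])$p.value
  }, numeric(1))
  # at least one feature separates the two latent ages decisively
  expect_lt(min(p), 1e-6 / length(p))
})

test_that("feature fixture has the promised structure and metadata", {
  expect_error(makeFeatureFixture(n_features = 1), "n_features")
  cfs <- makeFeatureFixture(n_animals_per_group = 2, cells_per_animal = 50,
                            n_features = 6, seed = 3)
  cd <- cellData(cfs)
  expect_equal(nrow(featureMatrix(cfs)), 2 * 3 * 50)
  expect_setequal(unique(cd$group), c("young", "middle", "old"))
  expect_equal(length(unique(cd$animal)), 6)
  truth <- S4Vectors::metadata(cfs)
  expect_equal(sum(truth$drift_vector^2), 1)
  b <- makeFeatureFixture(n_animals_per_group = 2, cells_per_animal = 50,
                          n_features = 6, seed = 3)
  expect_identical(featureMatrix(cfs), featureMatrix(b))
})

test_that("composition drift moves bootstrap means along the drift vector", {
  cfs <- makeFeatureFixture(n_animals_per_group = 4, cells_per_animal = 800,
                            n_features = 8, drift = "composition", seed = 6)
  bm <- bootstrapMeans(cfs, 200, 50, seed = 7)
  cd <- cellData(bm); m <- featureMatrix(bm)
  dv <- S4Vectors::metadata(cfs)$drift_vector
  proj <- as.numeric(m %*% dv)
  expect_gt(mean(proj[cd$group == "old"]), mean(proj[cd$group == "young"]))
  # single cells of the two extreme ages still overlap heavily off-axis:
  # per-cell type identity is unchanged, only composition shifts
  expect_gt(mean(proj[cd$group == "middle"]), mean(proj[cd$group == "young"]))
  expect_lt(mean(proj[cd$group == "middle"]), mean(proj[cd$group == "old"]))
})

test_that("null drift gives no spurious age association", {
  # animal-level held-out splits: axis training never sees the test animal,
  # so with zero drift the per-animal readouts carry no age signal
  p_vals <- vapply(1:20, function(s) {
    cfs <- makeFeatureFixture(n_animals_per_group = 4, cells_per_animal = 80,
                              n_features = 5,
                              drift_magnitude = function(a) 0, seed = s)
    bm <- bootstrapMeans(cfs, 40, 30, seed = s + 500)
    v <- validateAxis(bm, "centroid", n_iterations = 8, level = "animal",
                      seed = s + 900)
    cor.test(v$per_animal$readout, v$per_animal$age)$p.value
  }, numeric(1))
  # under the null the p-values are not systematically small
  expect_gt(mean(p_vals > 0.05), 0.6)
  expect_gt(median(p_vals), 0.1)
})

test_that("behavior fixture couples clusters to the age readout as declared", {
  expect_error(makeBehaviorFixture(1:2), "3 animals")
  expect_error(makeBehaviorFixture(1:10, n_trials = 1), "n_trials")
  im <- seq(0, 1, length.out = 12)
  # limiting case: one cluster, coupling -1, vanishing noise
  y <- makeBehaviorFixture(im, n_clusters = 1, readouts_per_cluster = 3,
                           within_cluster_corr = 0.999,
                           coupling_to_age = -1, cluster_noise_sd = 1e-4,
                           trial_noise_sd = 1e-4, seed = 2)
  m <- apply(y, c(1, 2), mean)
  fit <- optimizeAlpha(matrix(m[, 1], ncol = 1), im, n_perm = 200, seed = 3)
  expect_gt(fit$R, 0.999)
  expect_lt(fit$alpha[1], 0)     # recovered coefficient sign is negative
  expect_lt(cor(m[, 1], im), -0.999)
  b <- makeBehaviorFixture(im, n_clusters = 2, seed = 5)
  expect_identical(as.numeric(b),
                   as.numeric(makeBehaviorFixture(im, n_clusters = 2,
                                                  seed = 5)))
})

test_that("zero coupling yields a permutation-null |R| distribution", {
  withr::local_seed(31)
  im <- rnorm(15)
  y <- makeBehaviorFixture(im, n_clusters = 3, readouts_per_cluster = 2,
                           coupling_to_age = 0, seed = 8)
  F <- apply(y, c(1, 2), mean)[, c(1, 3, 5)]
  fit <- optimizeAlpha(F, im, n_perm = 500, seed = 9)
  expect_gt(fit$p, 0.05)
})
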