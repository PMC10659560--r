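# Independent brute-force oracle for threshold adjacency statistics:
# per-pixel neighbor scan over the full 3^ndim - 1 offset set.
tas_oracle <- function(fg) {
  d <- dim(fg)
  kmax <- if (length(d) == 2L) 8L else 26L
  idx <- which(fg, arr.ind = TRUE)
  if (!nrow(idx)) return(numeric(kmax + 1L))
  offs <- as.matrix(expand.grid(rep(list(-1:1), length(d))))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  counts <- apply(idx, 1, function(pt) {
    n <- 0L
    for (r in seq_len(nrow(offs))) {
      q <- pt + offs[r, ]
      if (any(q < 1L | q > d)) next
      if (fg[matrix(q, 1)]) n <- n + 1L
    }
    n
  })
  tabulate(counts + 1L, nbins = kmax + 1L) / nrow(idx)
}

random_mask <- function(dims, prob = 0.4) {
  array(runif(prod(dims)) < prob, dims)
}

# Minimal record wrapper for a dense crop (all pixels in-mask).
record_from_array <- function(values, label = 1) {
  d <- dim(values)
  coords <- arrayInd(seq_len(prod(d)), d)
  list(label = label, coords = coords,
       intensities = matrix(as.numeric(values), ncol = 1,
                            dimnames = list(NULL, "ch1")),
       size = prod(d), image_id = "test")
}

# Small end-to-end cohort used by several tests: fixture -> bootstrap means.
tiny_cohort <- function(seed, cells = 300, features = 10, animals = 3,
                        boots = 60, cells_pb = 100, drift = "mean",
                        noise_sd = 1) {
  cfs <- makeFeatureFixture(n_animals_per_group = animals,
                            cells_per_animal = cells,
                            n_features = features, drift = drift,
                            noise_sd = noise_sd, seed = seed)
  list(cells = cfs,
       boot = bootstrapMeans(cfs, cells_pb, boots, seed = seed + 1000))
}

# Two cell types whose separation shrinks with age: the erosion scenario.
erosion_cells <- function(seps = c(6, 3, 1), n = 120, d = 5,
                          ages = c(2, 15, 27), seed = 1) {
  withr::local_seed(seed)
  x <- NULL; type <- NULL; age <- NULL
  for (i in seq_along(ages)) {
    a <- matrix(rnorm(n * d), n, d)
    b <- matrix(rnorm(n * d), n, d); b[, 1] <- b[, 1] + seps[i]
    x <- rbind(x, a, b)
    type <- c(type, rep(c("T", "B"), each = n))
    age <- c(age, rep(ages[i], 2 * n))
  }
  list(x = x, type = type, age = age)
}

# Uniform sphere sampling oracle for the constrained alpha optimization.
sphere_search_R <- function(F, t, n_pts = 1e5) {
  k <- ncol(F)
  A <- matrix(rnorm(n_pts * k), n_pts, k)
  A <- A / sqrt(rowSums(A^2))
  proj <- tcrossprod(scale(F, scale = FALSE), A)   # n x n_pts combinations
  tc <- t - mean(t)
  num <- as.numeric(crossprod(proj, tc))
  den <- sqrt(colSums(proj^2) * sum(tc^2))
  max(abs(num / den))
}
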