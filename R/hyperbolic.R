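## Information (variation-of-information) distance between samples and
## embedding of the resulting distance matrix in Euclidean or hyperbolic
## (Lorentz-model) space, with Shepherd-diagram and Kruskal-stress
## diagnostics, Karcher means, and geodesic age readouts.

## ---- information distance -------------------------------------------------

hist_bin <- function(v, nbins) pmin(floor(v * nbins) + 1L, nbins)

entropy_from_counts <- function(counts, base = 2) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Information distance between two samples' feature-value distributions
#'
#' The normalized variation of information
#' `D(X, Y) = (2 H(X,Y) - H(X) - H(Y)) / H(X,Y)`,
#' estimated from histograms of the two feature vectors over `1/h` equal
#' bins on `[0, 1]` (bin width `h = 0.1` by default, final bin closed) and
#' the joint histogram of the paired values `(x_i, y_i)`. `D` lies in
#' `[0, 1]`: 0 for identical samples, 1 for independent ones, and is
#' invariant to the entropy's logarithm base since it is a ratio.
#' By default the two vectors are min-max normalized jointly (over their
#' union) before binning; set `normalize = "none"` when values are already
#' on `[0, 1]`.
#'
#' @param x,y numeric feature vectors of equal length (paired by feature).
#' @param h histogram bin width; `1/h` must be an integer (default 0.1).
#' @param base logarithm base for the entropies (cancels in the ratio).
#' @param normalize `"union"` (joint min-max) or `"none"`.
#' @return distance in `[0, 1]`; 0 when the joint entropy is 0.
#' @examples
#' x <- runif(500); informationDistance(x, x)      # 0
#' @export
informationDistance <- function(x, y, h = 0.1, base = 2,
                                normalize = c("union", "none")) {
  normalize <- match.arg(normalize)
  if (length(x) != length(y)) stop("x and y must have equal length")
  nbins <- round(1 / h)
  if (abs(nbins - 1 / h) > 1e-9) stop("1/h must be an integer")
  if (normalize == "union") {
    rng <- range(c(x, y))
    if (diff(rng) == 0) { x <- x * 0; y <- y * 0 }
    else { x <- (x - rng[1]) / diff(rng); y <- (y - rng[1]) / diff(rng) }
  }
  if (any(c(x, y) < 0 | c(x, y) > 1))
    stop("values must lie in [0, 1]; use normalize = 'union'")
  ix <- hist_bin(x, nbins); iy <- hist_bin(y, nbins)
  hx <- entropy_from_counts(tabulate(ix, nbins), base)
  hy <- entropy_from_counts(tabulate(iy, nbins), base)
  hxy <- entropy_from_counts(tabulate((ix - 1L) * nbins + iy, nbins^2), base)
  if (hxy == 0) return(0)
  (2 * hxy - hx - hy) / hxy
}

#' Pairwise distance matrix between rows
#'
#' @param rows numeric matrix (rows = samples) or [CellFeatureSet-class].
#' @param metric `"information"` or `"euclidean"`.
#' @param ... passed to [informationDistance()].
#' @return symmetric matrix with zero diagonal.
#' @export
distanceMatrix <- function(rows, metric = c("information", "euclidean"), ...) {
  metric <- match.arg(metric)
  if (is(rows, "CellFeatureSet")) rows <- featureMatrix(rows)
  rows <- as.matrix(rows)
  n <- nrow(rows)
  if (n < 2) stop("need >= 2 rows")
  if (metric == "euclidean") return(as.matrix(dist(rows)))
  D <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- informationDistance(rows[i, ], rows[j, ], ...)
  D
}

## ---- embedding diagnostics ------------------------------------------------

upper_tri <- function(m) m[upper.tri(m)]

#' Shepherd-diagram R-squared between target and achieved distances
#'
#' @param target,achieved conformable symmetric distance matrices.
#' @return squared Pearson correlation of their upper triangles.
#' @export
shepherdR2 <- function(target, achieved) {
  a <- upper_tri(as.matrix(target)); b <- upper_tri(as.matrix(achieved))
  if (length(a) < 2) return(NA_real_)    # undefined below 3 points
  if (sd(a) == 0 || sd(b) == 0) stop("constant distances")
  cor(a, b)^2
}

#' Kruskal stress-1 of an embedding
#'
#' @inheritParams shepherdR2
#' @return `sqrt(sum((achieved - target)^2) / sum(target^2))`.
#' @export
kruskalStress1 <- function(target, achieved) {
  a <- upper_tri(as.matrix(target)); b <- upper_tri(as.matrix(achieved))
  sqrt(sum((b - a)^2) / sum(a^2))
}

#' Euclidean multidimensional scaling with diagnostics
#'
#' Classical (Torgerson) MDS of a distance matrix into `dim` dimensions.
#'
#' @param D symmetric distance matrix with finite entries.
#' @param dim target dimension.
#' @return list: `coords`, `achieved`, `stress` (Kruskal stress-1), `r2`
#'   (Shepherd R-squared).
#' @export
emds <- function(D, dim = 2) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite distances")
  coords <- cmdscale(D, k = dim)
  if (ncol(coords) < dim)       # degenerate spectra pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), dim - ncol(coords)))
  achieved <- as.matrix(dist(coords))
  list(coords = coords, achieved = achieved,
       stress = kruskalStress1(D, achieved), r2 = shepherdR2(D, achieved))
}

## ---- Lorentz-model geometry ----------------------------------------------

## Lorentz (Minkowski) inner products between rows of A and B, signature
## (-, +, ..., +): <x, y>_L = -x0*y0 + <xs, ys>.
lorentz_inner <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  -tcrossprod(A[, 1, drop = FALSE], B[, 1, drop = FALSE]) +
    tcrossprod(A[, -1, drop = FALSE], B[, -1, drop = FALSE])
}

## Lift spatial coordinates z (n x d) onto the unit hyperboloid (n x (d+1)).
lift_hyperboloid <- function(z) {
  z <- rbind(z)
  cbind(sqrt(1 + rowSums(z^2)), z)
}

#' Pairwise geodesic distances between hyperboloid points
#'
#' @param coords n x (d+1) matrix of unit-hyperboloid points.
#' @param kappa curvature magnitude; the space has curvature `-kappa` and
#'   distances are `acosh(-<x,y>_L) / sqrt(kappa)`.
#' @return symmetric distance matrix.
#' @export
hyperbolicDistance <- function(coords, kappa = 1) {
  U <- -lorentz_inner(coords, coords)
  acosh(pmax(U, 1)) / sqrt(kappa)
}

hyp_exp <- function(x, v) {
  nv <- sqrt(max(as.numeric(lorentz_inner(v, v)), 0))
  if (nv < 1e-14) return(x)
  cosh(nv) * x + sinh(nv) * v / nv
}

hyp_log <- function(x, y) {
  u <- max(-as.numeric(lorentz_inner(x, y)), 1)   # cosh(d)
  d <- acosh(u)
  if (d < 1e-14) return(numeric(length(x)))
  w <- y - u * x
  d * w / sinh(d)
}

#' Hyperbolic multidimensional scaling (Lorentz model)
#'
#' Embeds a distance matrix into a d-dimensional hyperbolic space of
#' curvature `-kappa` by minimizing the squared stress
#' `sum_{i<j} (d_H(x_i, x_j) - delta_ij)^2` over hyperboloid points with a
#' quasi-Newton optimizer on the spatial coordinates (the hyperboloid
#' constraint is maintained exactly by parameterization). Multi-start from a
#' scaled classical-MDS configuration plus seeded perturbations; the start
#' with the lowest stress wins, so the result is deterministic given the
#' seed.
#'
#' @param D symmetric target distance matrix.
#' @param dim embedding dimension d (>= 2).
#' @param kappa positive curvature magnitude.
#' @param seed root seed.
#' @param n_starts optimizer restarts (default 5).
#' @param maxit iterations per start.
#' @return a [HyperbolicEmbedding-class].
#' @export
hmds <- function(D, dim = 2, kappa = 1, seed = 1, n_starts = 5, maxit = 300) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("non-finite distances")
  n <- nrow(D)
  if (dim < 2) stop("dim must be >= 2")
  delta <- D
  sqk <- sqrt(kappa)
  fn <- function(par) {
    z <- matrix(par, n, dim)
    t0 <- sqrt(1 + rowSums(z^2))
    U <- pmax(tcrossprod(t0) - tcrossprod(z), 1)
    d <- acosh(U) / sqk
    sum((d - delta)^2) / 2
  }
  gr <- function(par) {
    z <- matrix(par, n, dim)
    t0 <- sqrt(1 + rowSums(z^2))
    U <- pmax(tcrossprod(t0) - tcrossprod(z), 1)
    d <- acosh(U) / sqk
    G <- 2 * (d - delta) / (sqk * sqrt(pmax(U^2 - 1, 1e-12)))
    diag(G) <- 0
    A <- as.numeric(G %*% t0)
    grad <- (A / t0) * z - G %*% z    # full symmetric sum = d/dz of sum_{i<j}
    as.numeric(grad)
  }
  init0 <- cmdscale(delta, k = min(dim, n - 1L))
  if (ncol(init0) < dim)
    init0 <- cbind(init0, matrix(0, n, dim - ncol(init0)))
  init0 <- init0 * sqk
  best <- NULL
  with_seed(substream(seed, "hmds"), {
    for (s in seq_len(n_starts)) {
      par0 <- as.numeric(init0)
      if (s > 1) par0 <- par0 * runif(1, 0.5, 1.5) +
          rnorm(length(par0), sd = 0.05 * (sd(par0) + 1e-3))
      fit <- optim(par0, fn, gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  z <- matrix(best$par, n, dim)
  coords <- lift_hyperboloid(z)
  achieved <- hyperbolicDistance(coords, kappa)
  dimnames(achieved) <- dimnames(D)
  new("HyperbolicEmbedding", coords = coords, kappa = kappa, dim = dim,
      target = delta, achieved = achieved,
      stress = kruskalStress1(delta, achieved),
      r2 = shepherdR2(delta, achieved),
      meta = list(seed = seed, n_starts = n_starts, value = best$value,
                  convergence = best$convergence))
}

#' Grid search over embedding dimension and curvature
#'
#' Runs [hmds()] on every (dim, kappa) combination and returns the pair
#' maximizing the Shepherd R-squared; ties break toward the smallest
#' dimension, then the smallest curvature.
#'
#' @param D distance matrix.
#' @param dims,kappas non-empty grids.
#' @param seed root seed.
#' @param ... passed to [hmds()].
#' @return list: `dim`, `kappa`, `best` (its embedding), `table` with one
#'   row per grid cell (dim, kappa, r2, stress).
#' @export
selectGeometry <- function(D, dims = 2:4, kappas = c(0.5, 1, 2, 4),
                           seed = 1, ...) {
  if (!length(dims) || !length(kappas)) stop("empty grid")
  grid <- expand.grid(dim = sort(dims), kappa = sort(kappas))
  fits <- lapply(seq_len(nrow(grid)), function(i)
    hmds(D, grid$dim[i], grid$kappa[i], seed = seed, ...))
  tab <- cbind(grid,
               r2 = vapply(fits, function(f) f@r2, 0),
               stress = vapply(fits, function(f) f@stress, 0))
  ord <- order(-tab$r2, tab$dim, tab$kappa)
  best <- ord[1]
  list(dim = tab$dim[best], kappa = tab$kappa[best], best = fits[[best]],
       table = tab)
}

#' Karcher (Frechet) mean of hyperboloid points
#'
#' Fixed point of iterated tangent-space averaging via the log/exp maps.
#'
#' @param coords n x (d+1) matrix of unit-hyperboloid points.
#' @param tol convergence tolerance on the mean tangent norm (default 1e-8).
#' @param maxit iteration cap.
#' @return a unit-hyperboloid point.
#' @export
hyperbolicCentroid <- function(coords, tol = 1e-8, maxit = 200) {
  coords <- rbind(coords)
  m <- coords[1, ]
  for (it in seq_len(maxit)) {
    V <- t(apply(coords, 1, function(x) hyp_log(m, x)))
    vbar <- colMeans(rbind(V))
    if (sqrt(max(as.numeric(lorentz_inner(vbar, vbar)), 0)) < tol)
      return(m)
    m <- hyp_exp(m, vbar)
    m <- m / sqrt(-as.numeric(lorentz_inner(m, m)))   # re-project
  }
  stop("Karcher mean did not converge in ", maxit, " iterations")
}

#' Geodesic ImAge readout in hyperbolic space
#'
#' Projects a point onto the geodesic through the young centroid `a` and old
#' centroid `b`: the readout `p` is the arc-length coordinate of the nearest
#' point on the geodesic (0 at `a`, `d_H(a, b)` at `b`) and `d_o` the
#' geodesic distance to it. Distance to a geodesic is convex in a Hadamard
#' space, so a 1-D unimodal search finds the minimizer.
#'
#' @param points matrix of unit-hyperboloid points (rows), or one point.
#' @param a,b distinct unit-hyperboloid points (young and old centroids).
#' @param kappa curvature magnitude (scales `p` and `d_o`).
#' @param extend how far beyond the segment ends (in multiples of
#'   `d_H(a,b)`) the search bracket reaches.
#' @return data.frame with columns `p` and `d_o`.
#' @export
hyperbolicImAge <- function(points, a, b, kappa = 1, extend = 3) {
  points <- rbind(points)
  u0 <- hyp_log(a, b)
  L <- sqrt(max(as.numeric(lorentz_inner(u0, u0)), 0))
  if (L < 1e-12) stop("degenerate geodesic: a and b coincide")
  u <- u0 / L
  gamma <- function(t) hyp_exp(a, t * u)
  res <- t(apply(points, 1, function(x) {
    dfun <- function(t) {
      g <- gamma(t)
      acosh(max(-as.numeric(lorentz_inner(g, x)), 1))
    }
    opt <- optimize(dfun, interval = c(-extend * L, (1 + extend) * L),
                    tol = 1e-10)
    c(p = opt$minimum, d_o = opt$objective)
  }))
  data.frame(p = res[, "p"] / sqrt(kappa), d_o = res[, "d_o"] / sqrt(kappa))
}

#' Variance fraction along the young-old geodesic
#'
#' All points are mapped into the tangent space at the geodesic midpoint;
#' the fraction is the variance of the tangent component along the geodesic
#' direction over the total tangent variance (sum across tangent
#' directions). Points lying on the geodesic give 1; an isotropic tangent
#' cloud in d dimensions gives about 1/d.
#'
#' @inheritParams hyperbolicImAge
#' @return scalar in `[0, 1]`.
#' @export
geodesicVarianceFraction <- function(points, a, b, kappa = 1) {
  points <- rbind(points)
  if (nrow(points) < 2) stop("need >= 2 points")
  u0 <- hyp_log(a, b)
  L <- sqrt(max(as.numeric(lorentz_inner(u0, u0)), 0))
  if (L < 1e-12) stop("degenerate geodesic")
  m <- hyp_exp(a, 0.5 * u0)
  um <- hyp_log(m, b)
  um <- um / sqrt(max(as.numeric(lorentz_inner(um, um)), 1e-24))
  V <- t(apply(points, 1, function(x) hyp_log(m, x)))
  p <- as.numeric(lorentz_inner(V, um))
  Vc <- sweep(V, 2, colMeans(V))
  total <- sum(diag(lorentz_inner(Vc, Vc))) / (nrow(V) - 1)
  if (total <= 0) stop("zero tangent variance")
  var(p) / total
}
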