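## Seeded generators producing the three kinds of inputs the pipeline
## consumes: textured nuclear images with label masks, per-cell feature
## tables with a known aging drift, and behavior matrices with clustered
## readouts coupled to a latent age. Each draws from a named substream of a
## single root seed, so fixtures are bit-reproducible and independent.

## Periodic Gaussian-smoothed white noise via FFT; the smoothing length
## sigma (pixels) sets the spatial autocorrelation of the texture.
smooth_noise_field <- function(dims, sigma) {
  noise <- array(rnorm(prod(dims)), dims)
  if (sigma <= 0) return(noise)
  axes <- lapply(dims, function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    exp(-d^2 / (2 * sigma^2))
  })
  kern <- Reduce(outer, axes)
  kern <- array(kern, dims) / sum(kern)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / prod(dims)
  sm / sd(sm)
}

#' Synthetic multi-channel nuclei image with label mask and ground truth
#'
#' Generates a field of non-overlapping disc (2D) or sphere (3D) nuclei.
#' Each channel's intra-nuclear texture is Gaussian-smoothed white noise
#' whose smoothing length grows with the nucleus's latent age through
#' `granularity`, a minimal model of age-dependent chromatin puncta
#' coarsening whose threshold adjacency statistics are provably
#' age-sensitive. Grey levels are integers on the 16-bit scale.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param field_shape image shape `(y, x)` or `(y, x, z)`.
#' @param channels channel names; one textured channel is generated per name.
#' @param age_latent latent age in `[0, 1]`; scalar or one value per nucleus.
#' @param granularity monotone map from latent age to the texture smoothing
#'   length in pixels; default `1 + 3 * age`.
#' @param intensity_noise_sd i.i.d. grey-level noise added per pixel.
#' @param seed root seed.
#' @return list with `image` (y, x[, z], channel array), `mask` (integer
#'   labels), and `truth` (data.frame: label, age_latent, centroid, radius).
#' @examples
#' fx <- makeImageFixture(n_nuclei = 4, seed = 1)
#' dim(fx$image); max(fx$mask)
#' @export
makeImageFixture <- function(n_nuclei = 12, nucleus_radius_px = 10,
                             field_shape = c(192, 192),
                             channels = c("DAPI", "mark"),
                             age_latent = 0.5,
                             granularity = function(age) 1 + 3 * age,
                             intensity_noise_sd = 500,
                             seed = 1) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (nucleus_radius_px <= 0) stop("nucleus_radius_px must be positive")
  ndim <- length(field_shape)
  if (!ndim %in% 2:3) stop("field_shape must be 2D or 3D")
  ages <- rep_len(age_latent, n_nuclei)
  if (any(ages < 0 | ages > 1)) stop("age_latent must lie in [0, 1]")
  r <- nucleus_radius_px
  with_seed(substream(seed, "image_fixture"), {
    ## non-overlapping placement with bounded retries
    centers <- matrix(NA_real_, n_nuclei, ndim)
    placed <- 0L; tries <- 0L; max_tries <- 500L * n_nuclei
    while (placed < n_nuclei) {
      if ((tries <- tries + 1L) > max_tries)
        stop("could not place ", n_nuclei,
             " non-overlapping nuclei in the field (placement error)")
      cand <- vapply(field_shape, function(n) runif(1, r + 1, n - r), 0)
      if (placed == 0L ||
          all(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2)) > 2 * r + 1)) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    mask <- array(0L, field_shape)
    image <- array(0, c(field_shape, length(channels)))
    grid <- arrayInd(seq_len(prod(field_shape)), field_shape)
    for (i in seq_len(n_nuclei)) {
      d2 <- colSums((t(grid) - centers[i, ])^2)
      inside <- which(d2 <= r^2)
      mask[inside] <- i
      side <- 2L * ceiling(r) + 3L
      sigma <- granularity(ages[i])
      for (ch in seq_along(channels)) {
        tex <- smooth_noise_field(rep(side, ndim), sigma)
        lo <- floor(centers[i, ]) - ceiling(r) - 1L
        local <- sweep(grid[inside, , drop = FALSE], 2, lo)
        flat <- local[, 1]
        mult <- 1L
        for (j in seq_len(ndim - 1L)) {
          mult <- mult * side
          flat <- flat + (local[, j + 1L] - 1L) * mult
        }
        vals <- 28000 + 8000 * tex[flat] +
          rnorm(length(inside), sd = intensity_noise_sd)
        idx <- inside + (ch - 1L) * prod(field_shape)
        image[idx] <- pmin(pmax(round(vals), 0), 65535)
      }
    }
    list(image = image, mask = mask,
         truth = data.frame(label = seq_len(n_nuclei), age_latent = ages,
                            radius = r,
                            centroid = I(asplit(centers, 1))))
  })
}

#' Synthetic per-cell feature table with a known aging drift
#'
#' Emulates a multi-group cohort: each animal contributes a cloud of cells
#' drawn from a mixture of cell-type Gaussians. Aging acts along a known
#' unit `drift_vector` either by shifting all cell-type means (`"mean"`), by
#' shifting the cell-type composition between types whose means are offset
#' along the drift direction (`"composition"` — the situation bootstrap
#' aggregation exists for), or both. The lowest age is labeled `"young"`,
#' the highest `"old"`, others `"middle"`.
#'
#' @param n_animals_per_group animals per age group.
#' @param ages age groups in months.
#' @param cells_per_animal cells per animal.
#' @param n_features feature dimensionality (>= 2).
#' @param drift_vector unit direction of aging drift; default first basis
#'   vector.
#' @param drift_magnitude monotone map age -> drift scalar; default scales
#'   linearly to 2 z-units over the age range.
#' @param drift one of `"mean"`, `"composition"`, `"both"`.
#' @param n_types number of cell-type mixture components.
#' @param type_separation offset (z-units) between consecutive type means
#'   along the drift direction, used by the composition mechanism.
#' @param mixture_weights map age -> probability vector over types; default
#'   shifts linearly from (0.8, ...) toward (..., 0.8) across the age range.
#' @param noise_sd isotropic within-type SD.
#' @param seed root seed.
#' @return a [CellFeatureSet-class]; `metadata()` holds the ground truth
#'   (`drift_vector`, `drift_magnitude`, per-animal expected shift).
#' @export
makeFeatureFixture <- function(n_animals_per_group = 6,
                               ages = c(2, 15, 27),
                               cells_per_animal = 1000,
                               n_features = 20,
                               drift_vector = NULL,
                               drift_magnitude = NULL,
                               drift = c("mean", "composition", "both"),
                               n_types = 2,
                               type_separation = 4,
                               mixture_weights = NULL,
                               noise_sd = 1,
                               seed = 1) {
  drift <- match.arg(drift)
  if (n_features < 2) stop("n_features must be >= 2")
  if (is.null(drift_vector)) {
    drift_vector <- c(1, numeric(n_features - 1L))
  } else {
    if (length(drift_vector) != n_features)
      stop("drift_vector length must equal n_features")
    drift_vector <- drift_vector / sqrt(sum(drift_vector^2))
  }
  arange <- range(ages)
  rel_age <- function(a) if (diff(arange) == 0) 0 else (a - arange[1]) / diff(arange)
  drift_magnitude <- drift_magnitude %||% function(a) 2 * rel_age(a)
  mixture_weights <- mixture_weights %||% function(a) {
    w <- rep(0.1, n_types)                       # background mass for middles
    w[1] <- 0.8 - 0.6 * rel_age(a)
    w[n_types] <- 0.2 + 0.6 * rel_age(a)
    w / sum(w)
  }
  with_seed(substream(seed, "feature_fixture"), {
    type_means <- matrix(0, n_types, n_features)
    if (drift %in% c("composition", "both"))
      for (ty in seq_len(n_types))
        type_means[ty, ] <- (ty - 1) * type_separation * drift_vector
    rows <- list(); meta <- list(); k <- 0L
    for (a in ages) for (j in seq_len(n_animals_per_group)) {
      k <- k + 1L
      w <- if (drift %in% c("composition", "both")) mixture_weights(a)
           else rep(1 / n_types, n_types)
      types <- sample.int(n_types, cells_per_animal, replace = TRUE, prob = w)
      shift <- if (drift %in% c("mean", "both")) drift_magnitude(a) else 0
      cells <- type_means[types, , drop = FALSE] +
        matrix(shift * drift_vector, cells_per_animal, n_features, byrow = TRUE) +
        matrix(rnorm(cells_per_animal * n_features, sd = noise_sd),
               cells_per_animal, n_features)
      rows[[k]] <- cells
      meta[[k]] <- data.frame(
        animal = sprintf("m%02d_%g", k, a), age = a,
        group = if (a == arange[1]) "young"
                else if (a == arange[2]) "old" else "middle",
        type = types)
    }
    md <- do.call(rbind, meta)
    cfs <- CellFeatureSet(do.call(rbind, rows),
                          animal = md$animal, age = md$age, group = md$group)
    SummarizedExperiment::colData(cfs)$cell_type <- md$type
    S4Vectors::metadata(cfs) <- list(
      drift_vector = drift_vector, drift = drift,
      drift_magnitude = vapply(ages, drift_magnitude, 0),
      type_separation = type_separation, ages = ages, seed = seed)
    cfs
  })
}

#' Synthetic behavior matrix coupled to per-animal age readouts
#'
#' Readouts come in clusters sharing one latent factor per cluster; each
#' factor is `coupling * scale(imAge) + noise`, so clusters carry a signed
#' linear association with the age readout, and trials add i.i.d. replicate
#' noise. Emulates a battery of behavioral/metabolic assays with a handful
#' of orthogonal readout clusters.
#'
#' @param imAge numeric vector, one age readout per animal.
#' @param n_clusters number of readout clusters.
#' @param readouts_per_cluster readouts per cluster.
#' @param within_cluster_corr target correlation between readouts of one
#'   cluster, in `(0, 1]`.
#' @param coupling_to_age signed per-cluster coupling weights (recycled).
#' @param cluster_noise_sd SD of the latent factor's age-independent part
#'   (default 1: even a fully coupled cluster owes at most half its factor
#'   variance to age, and distinct clusters stay statistically separable).
#' @param trial_noise_sd SD of per-trial replicate noise.
#' @param n_trials trials per readout (>= 2).
#' @param seed root seed.
#' @return 3-D array `animals x readouts x trials` with named dimensions;
#'   attribute `"truth"` holds cluster membership and coupling signs.
#' @export
makeBehaviorFixture <- function(imAge, n_clusters = 9,
                                readouts_per_cluster = 5,
                                within_cluster_corr = 0.8,
                                coupling_to_age = c(-1, 1),
                                cluster_noise_sd = 1,
                                trial_noise_sd = 0.3,
                                n_trials = 4, seed = 1) {
  n <- length(imAge)
  if (n < 3) stop("need at least 3 animals")
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (within_cluster_corr <= 0 || within_cluster_corr > 1)
    stop("within_cluster_corr must lie in (0, 1]")
  w <- rep_len(coupling_to_age, n_clusters)
  t_std <- as.numeric(scale(imAge))
  with_seed(substream(seed, "behavior_fixture"), {
    n_read <- n_clusters * readouts_per_cluster
    y <- array(0, c(n, n_read, n_trials),
               dimnames = list(paste0("animal", seq_len(n)),
                               paste0("c", rep(seq_len(n_clusters),
                                               each = readouts_per_cluster),
                                      ".r", rep(seq_len(readouts_per_cluster),
                                                n_clusters)),
                               paste0("trial", seq_len(n_trials))))
    for (j in seq_len(n_clusters)) {
      g <- w[j] * t_std + rnorm(n, sd = cluster_noise_sd)
      idio_sd <- sqrt(var(g) * (1 - within_cluster_corr) /
                        within_cluster_corr)
      for (kk in seq_len(readouts_per_cluster)) {
        base <- g + rnorm(n, sd = idio_sd)
        col <- (j - 1L) * readouts_per_cluster + kk
        for (tr in seq_len(n_trials))
          y[, col, tr] <- base + rnorm(n, sd = trial_noise_sd)
      }
    }
    structure(y, truth = list(
      cluster = rep(seq_len(n_clusters), each = readouts_per_cluster),
      coupling = w))
  })
}
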