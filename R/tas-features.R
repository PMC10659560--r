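#' Band-pass threshold intervals relative to the mean masked intensity
#'
#' Builds the 28 binarization intervals used for threshold adjacency
#' statistics. With `v_m` the mean pixel/voxel intensity inside the nucleus
#' mask and width factors `p`, the intervals are, in fixed order:
#' one static interval `(v_m, Inf)`; nine lower-bounded intervals
#' `(v_m - v_m*p, Inf)`; nine upper-shifted intervals `(v_m + v_m*p, Inf)`;
#' and nine symmetric bands `(v_m - v_m*p, v_m + v_m*p]`. A pixel is
#' foreground when `lo < value <= hi`.
#'
#' @param v_m non-negative mean masked intensity.
#' @param p_factors band width factors; default `(1:9) / 10`.
#' @return data.frame with columns `family` (static/lower/upper/band), `p`,
#'   `lo`, `hi`; one row per binarization (28 with the default factors).
#' @examples
#' iv <- bandIntervals(100)
#' nrow(iv)                      # 28
#' subset(iv, family == "band" & p == 0.3)   # (70, 130]
#' @export
bandIntervals <- function(v_m, p_factors = (1:9) / 10) {
  stopifnot_scalar(v_m, "v_m")
  if (v_m < 0) stop("v_m must be non-negative")
  rbind(
    data.frame(family = "static", p = NA_real_, lo = v_m, hi = Inf),
    data.frame(family = "lower",  p = p_factors, lo = v_m - v_m * p_factors, hi = Inf),
    data.frame(family = "upper",  p = p_factors, lo = v_m + v_m * p_factors, hi = Inf),
    data.frame(family = "band",   p = p_factors, lo = v_m - v_m * p_factors,
               hi = v_m + v_m * p_factors)
  )
}

#' Binarize masked intensities against one interval
#'
#' @param values numeric array (2D matrix or 3D array) of intensities.
#' @param mask logical array of the same shape; pixels outside are background
#'   by definition.
#' @param lo,hi interval bounds; foreground iff `lo < value <= hi`.
#' @return logical array of the same shape.
#' @export
binarizeInterval <- function(values, mask, lo, hi) {
  if (!identical(dim(values), dim(mask)))
    stop("values and mask shapes differ")
  fg <- (values > lo) & (values <= hi) & mask
  fg[is.na(fg)] <- FALSE
  fg
}

## Per-pixel foreground-neighbor counts by shifted-array summation.
## 8-connectivity in 2D, 26-connectivity in 3D.
neighbor_counts <- function(fg) {
  d <- dim(fg)
  x <- fg * 1L
  if (length(d) == 2L) {
    nr <- d[1]; nc <- d[2]
    p <- matrix(0L, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- x
    counts <- matrix(0L, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      counts <- counts + p[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
    }
  } else if (length(d) == 3L) {
    nr <- d[1]; nc <- d[2]; nz <- d[3]
    p <- array(0L, d + 2L)
    p[2:(nr + 1L), 2:(nc + 1L), 2:(nz + 1L)] <- x
    counts <- array(0L, d)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L && dz == 0L) next
      counts <- counts +
        p[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx, (2:(nz + 1L)) + dz]
    }
  } else stop("fg must be a 2D or 3D array")
  counts
}

#' Threshold adjacency statistics of a binarized nucleus
#'
#' For each foreground pixel, counts how many of its 8 (2D) or 26 (3D)
#' neighbors are also foreground; the returned vector is the distribution of
#' these counts over foreground pixels. Out-of-mask and out-of-image neighbors
#' count as background. When the binarization has no foreground the vector is
#' all zeros (not NaN).
#'
#' @param fg logical array, the binarized image (already restricted to the
#'   nucleus mask).
#' @return numeric probability vector of length 9 (2D, counts 0..8) or 27
#'   (3D, counts 0..26); sums to 1, or to 0 when `fg` is empty.
#' @examples
#' tasStatistics(matrix(TRUE, 3, 3))  # 4 corners k=3, 4 edges k=5, center k=8
#' @export
tasStatistics <- function(fg) {
  d <- dim(fg)
  if (is.null(d) || !length(d) %in% 2:3) stop("fg must be a 2D or 3D array")
  kmax <- if (length(d) == 2L) 8L else 26L
  nfg <- sum(fg)
  if (nfg == 0L) return(numeric(kmax + 1L))
  counts <- neighbor_counts(fg)
  tab <- tabulate(counts[fg] + 1L, nbins = kmax + 1L)
  tab / nfg
}

## Crop a nucleus record into dense arrays (value + mask) for one channel.
nucleus_crop <- function(record, channel) {
  coords <- record$coords
  ndim <- ncol(coords)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  dims <- hi - lo + 1L
  mask <- array(FALSE, dims)
  vals <- array(0, dims)
  idx <- sweep(coords, 2, lo - 1L)    # 1-based within crop
  flat <- idx[, 1]
  mult <- 1L
  for (j in seq_len(ndim - 1L)) {
    mult <- mult * dims[j]
    flat <- flat + (idx[, j + 1L] - 1L) * mult
  }
  mask[flat] <- TRUE
  vals[flat] <- record$intensities[, channel]
  list(values = vals, mask = mask)
}

#' Full TAS feature vector for one nucleus
#'
#' Computes, per requested channel, the mean masked intensity `v_m`, the 28
#' band-pass binarizations of [bandIntervals()], and the adjacency statistics
#' of each binarization; features are concatenated channel-block by
#' channel-block in the requested channel order. The result has
#' `28 * 9 = 252` entries per channel in 2D and `28 * 27 = 756` in 3D.
#' Features are invariant to global intensity rescaling of the nucleus since
#' all interval bounds are proportional to `v_m`.
#'
#' @param record a nucleus record from [loadLabeledImage()] (fields `coords`,
#'   `intensities`, `label`).
#' @param channels character vector of channel names to use (must be columns
#'   of `record$intensities`).
#' @return named numeric feature vector with attribute `"annotation"`: a
#'   data.frame (channel, family, p, k) describing each entry, and attribute
#'   `"fg_counts"` with the per-binarization foreground pixel counts for QC.
#' @export
nucleusFeatures <- function(record, channels = colnames(record$intensities)) {
  missing <- setdiff(channels, colnames(record$intensities))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  ndim <- ncol(record$coords)
  kmax <- if (ndim == 2L) 8L else 26L
  out <- list(); ann <- list(); fgc <- list()
  for (ch in channels) {
    crop <- nucleus_crop(record, ch)
    v_m <- mean(crop$values[crop$mask])
    iv <- bandIntervals(v_m)
    blocks <- lapply(seq_len(nrow(iv)), function(i) {
      fg <- binarizeInterval(crop$values, crop$mask, iv$lo[i], iv$hi[i])
      list(tas = tasStatistics(fg), nfg = sum(fg))
    })
    out[[ch]] <- unlist(lapply(blocks, `[[`, "tas"))
    fgc[[ch]] <- vapply(blocks, `[[`, numeric(1), "nfg")
    ann[[ch]] <- data.frame(
      channel = ch,
      family = rep(iv$family, each = kmax + 1L),
      p = rep(iv$p, each = kmax + 1L),
      k = rep(0:kmax, times = nrow(iv)))
  }
  v <- unlist(out, use.names = FALSE)
  ann <- do.call(rbind, ann)
  names(v) <- with(ann, sprintf("%s.%s.p%s.k%02d", channel, family,
                                ifelse(is.na(p), "NA", format(p)), k))
  structure(v, annotation = ann,
            fg_counts = unlist(fgc, use.names = FALSE))
}

#' TAS feature table for a list of nucleus records
#'
#' @param records list of nucleus records ([loadLabeledImage()]).
#' @param channels channels to include, in block order.
#' @return list with `features` (nuclei x features matrix, rownames = labels),
#'   `annotation` (per-feature data.frame) and `info` (per-nucleus label,
#'   size, image id).
#' @export
featuresFromRecords <- function(records, channels = NULL) {
  if (!length(records))
    return(list(features = matrix(numeric(0), 0, 0), annotation = NULL,
                info = data.frame()))
  channels <- channels %||% colnames(records[[1]]$intensities)
  rows <- lapply(records, nucleusFeatures, channels = channels)
  features <- do.call(rbind, lapply(rows, as.numeric))
  colnames(features) <- names(rows[[1]])
  rownames(features) <- vapply(records, function(r) as.character(r$label), "")
  list(features = features,
       annotation = attr(rows[[1]], "annotation"),
       info = data.frame(
         label = vapply(records, function(r) r$label, numeric(1)),
         size = vapply(records, function(r) nrow(r$coords), numeric(1)),
         image = vapply(records, function(r) r$image_id %||% NA_character_, "")))
}
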