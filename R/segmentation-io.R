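## Multi-channel images are arrays in (y, x[, z], channel) order; label masks
## are integer arrays in (y, x[, z]) order. On disk both are multi-page
## 16-bit grey TIFFs; image pages are channel-major (all z planes of channel 1,
## then channel 2, ...). Grey levels are integers in [0, 65535].

#' Write a multi-channel image (or integer label mask) as 16-bit TIFF
#'
#' @param x numeric array `(y, x[, z][, channel])` with integer grey levels in
#'   `[0, 65535]`, or an integer label mask.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImageTiff <- function(x, path) {
  d <- dim(x)
  pages <- switch(as.character(length(d)),
    "2" = list(x),
    "3" = lapply(seq_len(d[3]), function(i) x[, , i]),
    "4" = unlist(lapply(seq_len(d[4]), function(ch)
            lapply(seq_len(d[3]), function(z) x[, , z, ch])), recursive = FALSE),
    stop("x must have 2-4 dimensions"))
  if (max(vapply(pages, max, numeric(1))) > 65535)
    stop("grey levels above 65535 cannot be stored as 16-bit")
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF back into an array
#'
#' @param path TIFF file written by [writeImageTiff()].
#' @param n_channels number of channels the pages encode (1 for a mask);
#'   `n_z` planes per channel are inferred from the page count.
#' @return numeric array of integer grey levels, `(y, x)` for a single page,
#'   `(y, x, channel)` or `(y, x, z, channel)` otherwise.
#' @export
readImageTiff <- function(path, n_channels = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * 65535))
  np <- length(pages)
  if (np %% n_channels != 0)
    stop("page count ", np, " is not a multiple of n_channels = ", n_channels)
  nz <- np %/% n_channels
  d <- dim(pages[[1]])
  if (np == 1L) return(pages[[1]])
  if (nz == 1L) {
    out <- array(0, c(d, n_channels))
    for (ch in seq_len(n_channels)) out[, , ch] <- pages[[ch]]
  } else {
    out <- array(0, c(d, nz, n_channels))
    for (ch in seq_len(n_channels)) for (z in seq_len(nz))
      out[, , z, ch] <- pages[[(ch - 1L) * nz + z]]
  }
  out
}

#' Extract per-nucleus records from an image and an integer label mask
#'
#' Consumes a multi-channel image together with an externally produced
#' integer segmentation mask (label 0 = background) and returns one record
#' per labeled nucleus, holding its pixel coordinates and per-channel
#' intensities. When the image carries a z dimension and `mode = "2d"`
#' (the default analysis mode), each channel and the mask are max-projected
#' over z before extraction; `mode = "3d"` keeps voxels.
#'
#' @param image array `(y, x[, z], channel)`, or path to a TIFF written by
#'   [writeImageTiff()].
#' @param mask integer array `(y, x[, z])`, or path to its TIFF.
#' @param channels character vector naming the image's channels; its length
#'   must equal the channel dimension.
#' @param mode `"2d"` (max projection over z) or `"3d"`.
#' @param illumination_corrected flag recorded on the records; flat-field
#'   correction is expected upstream and is only declared here.
#' @param image_id identifier stored on each record.
#' @return list of nucleus records; each a list with `label`, `coords`
#'   (n x 2 or n x 3 integer matrix), `intensities` (n x channel matrix),
#'   `centroid`, `size` and `image_id`.
#' @export
loadLabeledImage <- function(image, mask, channels, mode = c("2d", "3d"),
                             illumination_corrected = FALSE,
                             image_id = "image") {
  mode <- match.arg(mode)
  if (is.character(image)) image <- readImageTiff(image, length(channels))
  if (is.character(mask)) mask <- readImageTiff(mask, 1L)
  if (any(mask != round(mask)) || any(mask < 0))
    stop("mask must contain non-negative integer labels")
  di <- dim(image); dm <- dim(mask)
  if (length(di) == length(dm)) {     # single-channel image without channel dim
    image <- array(image, c(di, 1L)); di <- dim(image)
  }
  if (!identical(di[-length(di)], dm))
    stop("image and mask spatial shapes differ")
  nch <- di[length(di)]
  if (nch != length(channels))
    stop("channel dimension (", nch, ") does not match channel names (",
         length(channels), ")")
  if (mode == "2d" && length(dm) == 3L) {
    mask <- apply(mask, c(1, 2), max)
    image <- apply(image, c(1, 2, 4), max)
    dm <- dim(mask)
  }
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  flat_img <- matrix(image, nrow = prod(dm), ncol = nch,
                     dimnames = list(NULL, channels))
  lapply(labels, function(lb) {
    flat <- which(as.vector(mask) == lb)
    coords <- arrayInd(flat, dm)
    colnames(coords) <- c("y", "x", "z")[seq_len(ncol(coords))]
    list(label = lb,
         coords = coords,
         intensities = flat_img[flat, , drop = FALSE],
         centroid = colMeans(coords),
         size = length(flat),
         image_id = image_id,
         illumination_corrected = illumination_corrected)
  })
}

#' Remove nuclei smaller than a physical radius threshold
#'
#' Keeps a record iff its pixel area (2D) or voxel volume (3D) is at least
#' that of a disc / sphere of radius `min_radius_um`: records with
#' `size < pi * r^2` (2D) or `size < (4/3) * pi * r^3` (3D), with
#' `r = min_radius_um / pixel_size_um` in pixels, are removed. The filter is
#' idempotent and order-preserving. The default radius of 4 um sits inside
#' the 3-7 um working range typical for mammalian nuclei across tissues and
#' microscopes; tune per dataset.
#'
#' @param records list of nucleus records.
#' @param pixel_size_um physical pixel (voxel edge) size in micrometers.
#' @param min_radius_um minimum nucleus radius in micrometers (default 4).
#' @return filtered list, with attribute `"n_removed"`.
#' @examples
#' # a 2D record of 28 px is below the pi*3^2 = 28.27 px threshold at r = 3 um
#' @export
filterSmallObjects <- function(records, pixel_size_um, min_radius_um = 4) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (min_radius_um < 0) stop("min_radius_um must be non-negative")
  if (!length(records)) return(records)
  r_px <- min_radius_um / pixel_size_um
  ndim <- ncol(records[[1]]$coords)
  thr <- if (ndim == 2L) pi * r_px^2 else (4 / 3) * pi * r_px^3
  keep <- vapply(records, function(rec) rec$size >= thr, logical(1))
  structure(records[keep], n_removed = sum(!keep))
}
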