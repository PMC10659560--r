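#' CellFeatureSet: per-cell texture features with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay (`"features"`, features x cells) plus mandatory per-cell metadata
#' columns `animal`, `age` and `group` in `colData`. Rows are TAS features
#' (rowData carries `channel`, `family`, `p`, `k` when the features come from
#' [nucleusFeatures()]); columns are cells or bootstrap-mean pseudo-cells.
#' The class is the pipeline's lingua franca: generators, bootstrap
#' aggregation, axis fitting and projection all consume and return it.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("CellFeatureSet", contains = "SummarizedExperiment")

setValidity("CellFeatureSet", function(object) {
  need <- c("animal", "age", "group")
  missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    return(sprintf("colData must contain column(s): %s",
                   paste(missing, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  TRUE
})

#' Construct a CellFeatureSet
#'
#' @param features numeric matrix, cells in rows, features in columns (the
#'   user-facing orientation; stored transposed internally).
#' @param animal,age,group per-cell metadata vectors recycled to `nrow(features)`.
#' @param rowData optional `DataFrame`/data.frame of per-feature annotation.
#' @return A [CellFeatureSet-class] object.
#' @examples
#' cfs <- CellFeatureSet(matrix(rnorm(20), 5, 4), animal = "a1", age = 3,
#'                       group = "young")
#' dim(featureMatrix(cfs))
#' @export
CellFeatureSet <- function(features, animal, age, group, rowData = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  cd <- S4Vectors::DataFrame(animal = rep_len(animal, n),
                             age = rep_len(age, n),
                             group = rep_len(group, n))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  a <- t(features)
  colnames(a) <- sprintf("cell%06d", seq_len(n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a), colData = cd)
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
  new("CellFeatureSet", se)
}

#' @rdname CellFeatureSet
#' @param x a `CellFeatureSet`
#' @return `featureMatrix`: numeric matrix, cells x features.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @rdname CellFeatureSet
#' @return `cellData`: data.frame of per-cell metadata.
#' @export
cellData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "CellFeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("CellFeatureSet: %d cells x %d features\n",
              ncol(object), nrow(object)))
  cat(sprintf("  animals: %d | groups: %s\n",
              length(unique(cd$animal)),
              paste(unique(cd$group), collapse = ", ")))
})

#' ImAgeAxis: an oriented young-to-old axis in z-scored feature space
#'
#' The axis is a 1-D affine subspace: `origin` plus multiples of the unit
#' `direction`, oriented so the old reference group projects higher than the
#' young one. `standardizer` stores the z-scoring fitted on the training rows
#' so held-out cells are placed in the same space without refitting.
#'
#' @slot origin numeric, point on the axis.
#' @slot direction numeric unit vector, young -> old.
#' @slot method `"centroid"` or `"svm"`.
#' @slot standardizer a [FeatureStandardizer-class] or NULL.
#' @slot meta list of fitting details (cost, seeds, group labels).
#' @export
setClass("ImAgeAxis",
         representation(origin = "numeric", direction = "numeric",
                        method = "character", standardizer = "ANY",
                        meta = "list"))

setValidity("ImAgeAxis", function(object) {
  if (length(object@origin) != length(object@direction))
    return("origin and direction differ in length")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit vector")
  if (!object@method %in% c("centroid", "svm"))
    return("method must be 'centroid' or 'svm'")
  TRUE
})

setMethod("show", "ImAgeAxis", function(object) {
  cat(sprintf("ImAgeAxis (%s) in %d-dimensional z-scored feature space\n",
              object@method, length(object@direction)))
})

#' FeatureStandardizer: per-feature z-scoring parameters
#'
#' Fitted on a reference (training) set and applied unchanged to any other
#' rows; zero-variance features get scale 1 so they map to constant 0.
#'
#' @slot center,scale numeric vectors, one entry per feature.
#' @export
setClass("FeatureStandardizer",
         representation(center = "numeric", scale = "numeric"))

setMethod("show", "FeatureStandardizer", function(object) {
  cat(sprintf("FeatureStandardizer for %d features\n", length(object@center)))
})

#' HyperbolicEmbedding: points on a Lorentz hyperboloid plus diagnostics
#'
#' Coordinates live on the unit hyperboloid (`<x,x>_L = -1`, first coordinate
#' timelike); the space's curvature is `-kappa` and geodesic distances are
#' `acosh(-<x,y>_L) / sqrt(kappa)`.
#'
#' @slot coords n x (d+1) matrix of hyperboloid points.
#' @slot kappa positive curvature magnitude.
#' @slot dim embedding dimension d.
#' @slot target,achieved symmetric distance matrices.
#' @slot stress Kruskal stress-1 of the fit.
#' @slot r2 Shepherd-diagram R-squared.
#' @slot meta list (optimizer trace, seed, starts).
#' @export
setClass("HyperbolicEmbedding",
         representation(coords = "matrix", kappa = "numeric", dim = "numeric",
                        target = "matrix", achieved = "matrix",
                        stress = "numeric", r2 = "numeric", meta = "list"))

setValidity("HyperbolicEmbedding", function(object) {
  q <- lorentz_inner(object@coords, object@coords)
  if (any(abs(diag(q) + 1) > 1e-6))
    return("points must satisfy the hyperboloid constraint <x,x>_L = -1")
  if (object@kappa <= 0) return("kappa must be positive")
  TRUE
})

setMethod("show", "HyperbolicEmbedding", function(object) {
  cat(sprintf(
    "HyperbolicEmbedding: %d points, d = %d, curvature -%.3g (stress-1 %.4f, Shepherd R2 %.4f)\n",
    nrow(object@coords), object@dim, object@kappa, object@stress, object@r2))
})
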