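#' Bootstrap-mean aggregation of single cells, stratified by animal
#'
#' Draws `n_bootstraps` bootstrap samples of `cells_per_bootstrap` cells with
#' replacement from each animal's own cells and averages their feature
#' vectors. The bootstrap mean is the pipeline's unit of analysis: it is
#' sensitive to shifts in cell-type composition between animals even when
#' individual cells are indistinguishable, and it equalizes the number of
#' data points per animal. Cells are never pooled across animals.
#'
#' @param x a [CellFeatureSet-class] of single cells.
#' @param cells_per_bootstrap cells averaged per bootstrap (default 200).
#' @param n_bootstraps bootstrap replicates per animal (default 1000).
#' @param seed root seed.
#' @return a [CellFeatureSet-class] with `n_bootstraps` rows per animal;
#'   `colData` keeps `animal`, `age`, `group` and adds `bootstrap`.
#' @export
bootstrapMeans <- function(x, cells_per_bootstrap = 200,
                           n_bootstraps = 1000, seed = 1) {
  stopifnot(is(x, "CellFeatureSet"))
  cd <- cellData(x)
  feats <- featureMatrix(x)
  animals <- unique(cd$animal)
  with_seed(substream(seed, "bootstrap_means"), {
    out <- vector("list", length(animals))
    meta <- vector("list", length(animals))
    for (i in seq_along(animals)) {
      rows <- which(cd$animal == animals[i])
      if (!length(rows)) stop("animal with no cells: ", animals[i])
      xa <- feats[rows, , drop = FALSE]
      counts <- matrix(0, n_bootstraps, length(rows))
      for (b in seq_len(n_bootstraps)) {
        draw <- sample.int(length(rows), cells_per_bootstrap, replace = TRUE)
        counts[b, ] <- tabulate(draw, nbins = length(rows))
      }
      out[[i]] <- (counts %*% xa) / cells_per_bootstrap
      meta[[i]] <- data.frame(animal = animals[i], age = cd$age[rows[1]],
                              group = cd$group[rows[1]],
                              bootstrap = seq_len(n_bootstraps))
    }
    md <- do.call(rbind, meta)
    res <- CellFeatureSet(do.call(rbind, out), animal = md$animal,
                          age = md$age, group = md$group)
    SummarizedExperiment::colData(res)$bootstrap <- md$bootstrap
    S4Vectors::metadata(res) <- c(S4Vectors::metadata(x),
      list(cells_per_bootstrap = cells_per_bootstrap,
           n_bootstraps = n_bootstraps))
    res
  })
}

#' Fit per-feature z-scoring on a reference set
#'
#' Zero-variance features get scale 1 (they standardize to a constant 0);
#' their count is recorded in the `"n_constant"` attribute of the scale slot.
#'
#' @param x numeric matrix (rows = observations) or [CellFeatureSet-class].
#' @return a [FeatureStandardizer-class].
#' @export
zscoreFit <- function(x) {
  m <- if (is(x, "CellFeatureSet")) featureMatrix(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need >= 2 reference rows to fit a standardizer")
  center <- colMeans(m)
  scl <- apply(m, 2, sd)
  const <- !is.finite(scl) | scl == 0
  scl[const] <- 1
  new("FeatureStandardizer", center = center,
      scale = structure(scl, n_constant = sum(const)))
}

#' Apply a fitted standardizer
#'
#' @param x matrix or [CellFeatureSet-class] in the same feature space.
#' @param standardizer a [FeatureStandardizer-class] from [zscoreFit()].
#' @return object of the same class as `x`, standardized with the reference
#'   parameters (never refit on `x`).
#' @export
zscoreApply <- function(x, standardizer) {
  m <- if (is(x, "CellFeatureSet")) featureMatrix(x) else as.matrix(x)
  if (ncol(m) != length(standardizer@center))
    stop("feature dimensionality differs from the standardizer's")
  z <- sweep(sweep(m, 2, standardizer@center), 2, standardizer@scale, "/")
  if (is(x, "CellFeatureSet")) {
    SummarizedExperiment::assay(x, "features") <- t(z)
    x
  } else z
}

#' Repeated train/test splits of the reference groups
#'
#' Per iteration, `train_fraction` of the young and old rows are sampled
#' without replacement for axis construction and the remainder is held out;
#' rows of any other group (middle age, perturbations) are always test-only.
#' Splits are stratified within each young/old animal (`level = "row"`,
#' default) so both classes and every reference animal appear in each
#' training set, or whole animals are assigned (`level = "animal"`).
#'
#' @param groups character vector of per-row group labels.
#' @param animals character vector of per-row animal ids.
#' @param train_fraction fraction of reference rows trained on (default 0.75).
#' @param n_iterations number of splits (default 100).
#' @param reference_groups the two groups the axis is fit on.
#' @param level `"row"` or `"animal"`.
#' @param seed root seed.
#' @return list of `n_iterations` lists with integer index vectors `train`
#'   and `test` (a partition of all rows).
#' @export
splitIterations <- function(groups, animals, train_fraction = 0.75,
                            n_iterations = 100,
                            reference_groups = c("young", "old"),
                            level = c("row", "animal"), seed = 1) {
  level <- match.arg(level)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!all(reference_groups %in% groups))
    stop("both reference groups must be present")
  ref <- groups %in% reference_groups
  with_seed(substream(seed, "splits"), {
    lapply(seq_len(n_iterations), function(it) {
      train <- integer(0)
      if (level == "row") {
        for (an in unique(animals[ref])) {
          rows <- which(ref & animals == an)
          n_tr <- round(train_fraction * length(rows))
          if (n_tr < 1 || n_tr >= length(rows))
            stop("animal ", an, " has too few rows to split")
          train <- c(train, sample(rows, n_tr))
        }
      } else {
        for (g in reference_groups) {
          ans <- unique(animals[groups == g])
          n_tr <- round(train_fraction * length(ans))
          if (n_tr < 1 || n_tr >= length(ans))
            stop("group ", g, " has too few animals to split")
          keep <- sample(ans, n_tr)
          train <- c(train, which(animals %in% keep & groups == g))
        }
      }
      list(train = sort(train),
           test = sort(setdiff(seq_along(groups), train)))
    })
  })
}
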