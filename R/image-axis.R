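## Euclidean ImAge axes. The axis lives in z-scored feature space; its
## projection coordinate p is the ImAge readout and the orthogonal distance
## d_o the residual. Axes are always oriented young -> old.

axis_from_direction <- function(origin, w, method, z, groups,
                                reference_groups, standardizer, meta) {
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate axis: zero direction (coincident groups?)")
  u <- w / nw
  p <- as.numeric((z - matrix(origin, nrow(z), ncol(z), byrow = TRUE)) %*% u)
  if (mean(p[groups == reference_groups[2]]) <
      mean(p[groups == reference_groups[1]])) u <- -u
  new("ImAgeAxis", origin = origin, direction = u, method = method,
      standardizer = standardizer, meta = meta)
}

#' Fit a centroid-based ImAge axis
#'
#' The axis runs from the centroid of the young reference group to the
#' centroid of the old one; the origin is the young centroid, so young
#' projections sit near 0 and old near the centroid distance.
#'
#' @param z numeric matrix of z-scored rows (bootstrap means), or a
#'   [CellFeatureSet-class] already standardized.
#' @param groups per-row group labels (taken from `colData` for a
#'   `CellFeatureSet`).
#' @param reference_groups `c(young, old)` labels.
#' @param standardizer optional [FeatureStandardizer-class] recorded on the
#'   axis so other data can be placed in its space.
#' @return an [ImAgeAxis-class].
#' @export
fitCentroidAxis <- function(z, groups = NULL,
                            reference_groups = c("young", "old"),
                            standardizer = NULL) {
  if (is(z, "CellFeatureSet")) {
    groups <- groups %||% cellData(z)$group
    z <- featureMatrix(z)
  }
  ok <- reference_groups %in% groups
  if (!all(ok)) stop("missing reference group(s): ",
                     paste(reference_groups[!ok], collapse = ", "))
  cy <- colMeans(z[groups == reference_groups[1], , drop = FALSE])
  co <- colMeans(z[groups == reference_groups[2], , drop = FALSE])
  L <- sqrt(sum((co - cy)^2))
  axis_from_direction(cy, co - cy, "centroid", z, groups, reference_groups,
                      standardizer,
                      meta = list(reference_groups = reference_groups,
                                  threshold = L / 2, centroid_distance = L))
}

#' Fit a linear-SVM ImAge axis
#'
#' The axis direction is the unit normal of a soft-margin linear support
#' vector separator of the young and old reference rows; the origin is the
#' centroid of all training rows, and the decision hyperplane's position
#' along the axis is kept for classification. Less sensitive than the
#' centroid axis to skewed, non-normal reference distributions.
#'
#' @inheritParams fitCentroidAxis
#' @param cost soft-margin cost parameter passed to the linear SVM
#'   (default 1).
#' @return an [ImAgeAxis-class] with the fitted model in `meta$model`.
#' @export
fitSVMAxis <- function(z, groups = NULL,
                       reference_groups = c("young", "old"),
                       standardizer = NULL, cost = 1) {
  if (is(z, "CellFeatureSet")) {
    groups <- groups %||% cellData(z)$group
    z <- featureMatrix(z)
  }
  ok <- reference_groups %in% groups
  if (!all(ok)) stop("missing reference group(s): ",
                     paste(reference_groups[!ok], collapse = ", "))
  ref <- groups %in% reference_groups
  y <- factor(groups[ref], levels = reference_groups)
  fit <- e1071::svm(x = z[ref, , drop = FALSE], y = y, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  origin <- colMeans(z)
  ax <- axis_from_direction(origin, w, "svm", z, groups, reference_groups,
                            standardizer,
                            meta = list(reference_groups = reference_groups,
                                        cost = cost, model = fit))
  ## decision boundary on the p scale: <x, w> = rho with u = s * w/|w|
  ## gives p = s*rho/|w| - <origin, u>
  s <- sign(sum(ax@direction * w))
  ax@meta$threshold <- s * fit$rho / sqrt(sum(w^2)) -
    sum(origin * ax@direction)
  ax
}

#' Project rows onto an ImAge axis
#'
#' Returns the scalar projection `p` (the ImAge readout) and the orthogonal
#' distance `d_o = sqrt(|x - origin|^2 - p^2)` for each row; a slightly
#' negative radicand from floating-point cancellation is clamped at 0.
#'
#' @param x matrix of rows, or [CellFeatureSet-class]. If the axis carries a
#'   standardizer and `standardized = FALSE`, raw rows are standardized with
#'   it first.
#' @param axis an [ImAgeAxis-class].
#' @param standardized set `TRUE` when `x` is already in the axis's z-scored
#'   space.
#' @return data.frame with columns `p` and `d_o` (plus `animal`, `age`,
#'   `group` when `x` is a `CellFeatureSet`).
#' @export
projectOnAxis <- function(x, axis, standardized = is.null(axis@standardizer)) {
  md <- NULL
  if (is(x, "CellFeatureSet")) {
    md <- cellData(x)[, c("animal", "age", "group")]
    x <- featureMatrix(x)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(axis@direction)) stop("dimensionality mismatch")
  if (!standardized) {
    if (is.null(axis@standardizer))
      stop("axis has no standardizer; pass standardized rows")
    x <- zscoreApply(x, axis@standardizer)
  }
  rel <- sweep(x, 2, axis@origin)
  p <- as.numeric(rel %*% axis@direction)
  d2 <- rowSums(rel^2) - p^2
  out <- data.frame(p = p, d_o = sqrt(pmax(d2, 0)))
  if (!is.null(md)) out <- cbind(md, out)
  out
}

#' Fraction of total variance captured along the axis
#'
#' @param z matrix or `CellFeatureSet` of standardized rows.
#' @param axis an [ImAgeAxis-class].
#' @return `Var(p) / sum(per-feature variances)`, in `[0, 1]`.
#' @export
axisVarianceFraction <- function(z, axis) {
  if (is(z, "CellFeatureSet")) z <- featureMatrix(z)
  if (nrow(z) < 2) stop("need >= 2 rows")
  tot <- sum(apply(z, 2, var))
  if (tot == 0) stop("zero total variance")
  p <- projectOnAxis(z, axis, standardized = TRUE)$p
  var(p) / tot
}

#' Young/old classification accuracy of an axis on held-out rows
#'
#' SVM axes classify by the sign of the decision function; centroid axes by
#' which reference centroid is nearer along the axis (a midpoint threshold
#' on `p`).
#'
#' @param z standardized test rows (matrix or `CellFeatureSet`).
#' @param groups per-row labels.
#' @param axis an [ImAgeAxis-class].
#' @return fraction of reference-group test rows classified correctly.
#' @export
separationAccuracy <- function(z, groups = NULL, axis) {
  if (is(z, "CellFeatureSet")) {
    groups <- groups %||% cellData(z)$group
    z <- featureMatrix(z)
  }
  rg <- axis@meta$reference_groups
  ref <- groups %in% rg
  if (!any(ref)) stop("no reference-group rows to score")
  p <- projectOnAxis(z[ref, , drop = FALSE], axis, standardized = TRUE)$p
  pred <- ifelse(p > axis@meta$threshold, rg[2], rg[1])
  mean(pred == groups[ref])
}

#' Correlation of per-animal ImAge with chronological age
#'
#' @param readouts data.frame from [projectOnAxis()] with `animal`, `age`,
#'   `p` columns (typically held-out bootstrap rows).
#' @param aggregate `"median"` (default) or `"mean"` per-animal summary.
#' @return list with `pearson`/`spearman` estimates and p-values, the
#'   per-animal summary table, and the aggregation used.
#' @export
ageCorrelation <- function(readouts, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "median") median else mean
  per <- aggregate(p ~ animal + age, data = readouts, FUN = f)
  if (nrow(per) < 3) stop("need >= 3 animals")
  if (sd(per$p) == 0 || sd(per$age) == 0) stop("constant input")
  pe <- cor.test(per$p, per$age, method = "pearson")
  sp <- suppressWarnings(cor.test(per$p, per$age, method = "spearman"))
  list(pearson = c(r = unname(pe$estimate), p = pe$p.value),
       spearman = c(rho = unname(sp$estimate), p = sp$p.value),
       per_animal = per, aggregation = aggregate)
}

#' Robust organ-pair correlation of ImAge readouts
#'
#' For every organ pair and channel, Spearman correlation of matched
#' per-animal readouts is computed on all age groups and on every
#' leave-one-age-group-out subset; p-values are Bonferroni-corrected across
#' pairs x channels x subsets. A pair is flagged robust iff it is
#' significant (adjusted p < alpha) in the full set and in every subset.
#'
#' @param readouts data.frame with columns `animal`, `age`, `organ`,
#'   `channel`, `p` (one summary readout per animal/organ/channel).
#' @param alpha significance level (default 0.05).
#' @return data.frame per (organ pair, channel): rho and adjusted p for the
#'   full set, worst subset p, and `robust` flag; attribute
#'   `"bonferroni_factor"` documents the correction count.
#' @export
organPairSpearman <- function(readouts, alpha = 0.05) {
  ages <- sort(unique(readouts$age))
  if (length(ages) < 3) stop("need >= 3 age groups")
  organs <- sort(unique(readouts$organ))
  channels <- sort(unique(readouts$channel))
  pairs <- combn(organs, 2, simplify = FALSE)
  subsets <- c(list(ages), lapply(ages, function(a) setdiff(ages, a)))
  n_tests <- length(pairs) * length(channels) * length(subsets)
  rows <- list()
  for (pr in pairs) for (ch in channels) {
    a <- readouts[readouts$organ == pr[1] & readouts$channel == ch, ]
    b <- readouts[readouts$organ == pr[2] & readouts$channel == ch, ]
    m <- merge(a, b, by = "animal", suffixes = c(".a", ".b"))
    stats <- lapply(subsets, function(ss) {
      mm <- m[m$age.a %in% ss, ]
      if (length(unique(mm$age.a)) < 2 || nrow(mm) < 3)
        stop("fewer than 2 age groups after removal for pair ",
             paste(pr, collapse = "-"))
      ct <- suppressWarnings(cor.test(mm$p.a, mm$p.b, method = "spearman"))
      c(rho = unname(ct$estimate), p = ct$p.value)
    })
    p_adj <- pmin(vapply(stats, `[[`, 0, "p") * n_tests, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      organ_a = pr[1], organ_b = pr[2], channel = ch,
      rho_full = stats[[1]]["rho"], p_adj_full = p_adj[1],
      p_adj_worst_subset = max(p_adj[-1]),
      robust = all(p_adj < alpha))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, bonferroni_factor = n_tests)
}

#' Repeated train/test validation of an ImAge axis
#'
#' The full protocol on bootstrap-mean rows: per iteration, a fraction of
#' the young/old rows trains the standardizer and the axis (other groups are
#' never trained on), held-out rows are projected, and young/old separation
#' accuracy is scored on the held-out reference rows. Per-animal readouts
#' summarize each animal's held-out projections across all iterations.
#'
#' @param x [CellFeatureSet-class] of bootstrap-mean rows (raw scale).
#' @param method `"centroid"` or `"svm"`.
#' @param train_fraction,n_iterations split protocol (defaults 0.75, 100).
#' @param reference_groups `c(young, old)`.
#' @param aggregate per-animal summary, `"median"` (default) or `"mean"`.
#' @param cost SVM cost.
#' @param level split level, `"row"` or `"animal"`.
#' @param seed root seed.
#' @return list: `accuracy` (per-iteration vector), `accuracy_mean`,
#'   `accuracy_sd`, `per_animal` (animal, age, group, readout), `readouts`
#'   (all held-out projections with iteration), and the final iteration's
#'   axis as `axis` (with its standardizer) for downstream single-cell use.
#' @export
validateAxis <- function(x, method = c("centroid", "svm"),
                         train_fraction = 0.75, n_iterations = 100,
                         reference_groups = c("young", "old"),
                         aggregate = "median", cost = 1,
                         level = "row", seed = 1) {
  method <- match.arg(method)
  stopifnot(is(x, "CellFeatureSet"))
  cd <- cellData(x)
  feats <- featureMatrix(x)
  splits <- splitIterations(cd$group, cd$animal, train_fraction,
                            n_iterations, reference_groups, level, seed)
  acc <- numeric(n_iterations)
  readouts <- vector("list", n_iterations)
  axis <- NULL
  for (it in seq_len(n_iterations)) {
    tr <- splits[[it]]$train; te <- splits[[it]]$test
    std <- zscoreFit(feats[tr, , drop = FALSE])
    z_tr <- zscoreApply(feats[tr, , drop = FALSE], std)
    z_te <- zscoreApply(feats[te, , drop = FALSE], std)
    axis <- if (method == "centroid")
      fitCentroidAxis(z_tr, cd$group[tr], reference_groups, std)
    else fitSVMAxis(z_tr, cd$group[tr], reference_groups, std, cost)
    acc[it] <- separationAccuracy(z_te, cd$group[te], axis)
    pr <- projectOnAxis(z_te, axis, standardized = TRUE)
    readouts[[it]] <- cbind(cd[te, c("animal", "age", "group")], pr,
                            iteration = it)
  }
  readouts <- do.call(rbind, readouts)
  f <- if (aggregate == "median") median else mean
  per <- aggregate(p ~ animal + age + group, data = readouts, FUN = f)
  names(per)[names(per) == "p"] <- "readout"
  list(accuracy = acc, accuracy_mean = mean(acc), accuracy_sd = sd(acc),
       per_animal = per[order(per$animal), ], readouts = readouts,
       axis = axis, method = method)
}

#' Serialize an axis (with its standardizer) to JSON, and back
#'
#' @param axis an [ImAgeAxis-class].
#' @param path output file.
#' @return `path` invisibly; `readAxisJson` returns the axis (without any
#'   fitted SVM model object, which is not serialized).
#' @export
writeAxisJson <- function(axis, path) {
  std <- axis@standardizer
  obj <- list(method = axis@method, origin = axis@origin,
              direction = axis@direction,
              threshold = axis@meta$threshold,
              reference_groups = axis@meta$reference_groups,
              standardizer = if (!is.null(std))
                list(center = std@center, scale = as.numeric(std@scale)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeAxisJson
#' @export
readAxisJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (!is.null(obj$standardizer))
    new("FeatureStandardizer", center = obj$standardizer$center,
        scale = obj$standardizer$scale)
  new("ImAgeAxis", origin = obj$origin, direction = obj$direction,
      method = obj$method, standardizer = std,
      meta = list(threshold = obj$threshold,
                  reference_groups = obj$reference_groups))
}
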