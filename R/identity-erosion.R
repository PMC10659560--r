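## Age-related erosion of cell-/organ-type identity: silhouette scores of
## type separation per age group (information or Euclidean metric, with
## bootstrap CIs) and per-feature Kolmogorov-Smirnov distance profiles with
## two-stage significance filters.

#' Silhouette score of cell-type separation within each age group
#'
#' Scores how well cell-type labels cluster in raw feature space at each
#' age, using either Euclidean or information distance, with a bootstrap
#' over cells for a confidence interval. Declining scores with age indicate
#' erosion of type identity.
#'
#' @param x matrix (cells x features) or [CellFeatureSet-class].
#' @param type per-cell type labels (>= 2 types per age).
#' @param age per-cell age.
#' @param metric `"euclidean"` or `"information"`.
#' @param n_boot bootstrap replicates (default 100).
#' @param max_cells cells subsampled per age before the O(n^2) distance
#'   matrix (default 200, without replacement, seeded).
#' @param seed root seed.
#' @param ... passed to [informationDistance()].
#' @return data.frame per age: `score` (mean silhouette), `lo`, `hi`
#'   (2.5/97.5 bootstrap percentiles), `n_cells`.
#' @export
silhouetteByAge <- function(x, type, age, metric = c("euclidean", "information"),
                            n_boot = 100, max_cells = 200, seed = 1, ...) {
  metric <- match.arg(metric)
  if (is(x, "CellFeatureSet")) x <- featureMatrix(x)
  x <- as.matrix(x)
  ages <- sort(unique(age))
  with_seed(substream(seed, "silhouette"), {
    out <- lapply(ages, function(a) {
      idx <- which(age == a)
      if (length(idx) > max_cells) idx <- sample(idx, max_cells)
      ty <- factor(type[idx])
      if (nlevels(ty) < 2 || any(table(ty) < 2))
        stop("need >= 2 types with >= 2 cells each at age ", a)
      D <- distanceMatrix(x[idx, , drop = FALSE], metric, ...)
      sil <- function(rows) {
        cl <- as.integer(ty[rows])
        if (length(unique(cl)) < 2) return(NA_real_)
        mean(cluster::silhouette(cl, dmatrix = D[rows, rows])[, "sil_width"])
      }
      score <- sil(seq_along(idx))
      boots <- vapply(seq_len(n_boot), function(b) {
        repeat {
          rows <- sample(seq_along(idx), replace = TRUE)
          if (length(unique(ty[rows])) == nlevels(ty) &&
              all(table(ty[rows]) >= 2)) break
        }
        sil(rows)
      }, numeric(1))
      data.frame(age = a, score = score,
                 lo = quantile(boots, 0.025, names = FALSE),
                 hi = quantile(boots, 0.975, names = FALSE),
                 n_cells = length(idx))
    })
    do.call(rbind, out)
  })
}

#' Per-feature KS distance between cell types, per age
#'
#' For every feature and age group, the two-sample Kolmogorov-Smirnov
#' statistic is computed between each pair of cell types (on up to `n_cells`
#' cells per type, sampled without replacement) and averaged over the
#' `choose(N, 2)` pairs; for two types this is the plain pairwise KS
#' distance.
#'
#' @param x matrix (cells x features) or [CellFeatureSet-class].
#' @param type,age per-cell labels.
#' @param n_cells subsample size per (type, age) (default 5000; all
#'   available cells are used when fewer, recorded in `n_used`).
#' @param seed root seed.
#' @return data.frame per (feature, age): `ks` (pair-averaged statistic),
#'   `ks_p_max` (largest per-pair KS p-value), `n_used` (smallest sample).
#' @export
ksDistanceProfile <- function(x, type, age, n_cells = 5000, seed = 1) {
  if (is(x, "CellFeatureSet")) x <- featureMatrix(x)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  ages <- sort(unique(age))
  types <- sort(unique(type))
  if (length(types) < 2) stop("need >= 2 types")
  pairs <- combn(types, 2, simplify = FALSE)
  with_seed(substream(seed, "ks_profile"), {
    out <- list()
    for (a in ages) {
      samp <- lapply(types, function(ty) {
        idx <- which(age == a & type == ty)
        if (length(idx) > n_cells) idx <- sample(idx, n_cells)
        idx
      })
      names(samp) <- as.character(types)
      for (f in colnames(x)) {
        stats <- vapply(pairs, function(pr) {
          kt <- suppressWarnings(
            ks.test(x[samp[[as.character(pr[1])]], f],
                    x[samp[[as.character(pr[2])]], f]))
          c(kt$statistic, kt$p.value)
        }, numeric(2))
        out[[length(out) + 1L]] <- data.frame(
          feature = f, age = a, ks = mean(stats[1, ]),
          ks_p_max = max(stats[2, ]),
          n_used = min(lengths(samp)))
      }
    }
    do.call(rbind, out)
  })
}

#' Two-stage filter for features showing significant identity erosion
#'
#' A feature passes iff (i) it genuinely separates the cell types — every
#' per-pair KS test at the youngest age is significant at `alpha` and the
#' Pearson correlation of its KS profile with age is significant with
#' `|r| > r_separation` — and (ii) that correlation also clears the stricter
#' `|r| > r_age` gate. Negative passing correlations are the erosion
#' signature (type separation shrinking with age).
#'
#' @param profile output of [ksDistanceProfile()] (needs >= 3 ages).
#' @param alpha significance level (default 0.05).
#' @param r_separation,r_age the two |r| thresholds (defaults 0.85, 0.95).
#' @return data.frame per feature: `r`, `p` (KS-vs-age correlation),
#'   `ks_significant`, `pass`.
#' @export
significantErosionFeatures <- function(profile, alpha = 0.05,
                                       r_separation = 0.85, r_age = 0.95) {
  ages <- sort(unique(profile$age))
  if (length(ages) < 3) stop("need >= 3 ages for the correlation stage")
  young <- ages[1]
  out <- lapply(split(profile, profile$feature), function(pf) {
    pf <- pf[order(pf$age), ]
    ks_sig <- all(pf$ks_p_max[pf$age == young] < alpha)
    if (sd(pf$ks) == 0) {
      r <- 0; p <- 1
    } else {
      ct <- cor.test(pf$ks, pf$age)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(feature = pf$feature[1], r = r, p = p,
               ks_significant = ks_sig,
               pass = ks_sig && p < alpha && abs(r) > r_separation &&
                 abs(r) > r_age)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
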