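## Linking the age readout to behavioral/metabolic readouts: univariate
## p-value filtering, orthogonal clustering of correlated readouts, and the
## constrained optimization of linear coefficients alpha (||alpha|| = 1)
## maximizing the correlation of sum_i alpha_i f_i with the age readout.

trial_mean <- function(behavior) {
  if (length(dim(behavior)) == 3L) apply(behavior, c(1, 2), mean)
  else as.matrix(behavior)
}

#' Drop behaviors unrelated to the age readout
#'
#' Removes readouts whose univariate Pearson correlation with the age
#' readout has p-value above `p_threshold` (default 0.3), computed on
#' trial-averaged values.
#'
#' @param behavior animals x readouts matrix, or animals x readouts x trials
#'   array (from [makeBehaviorFixture()] or equivalent).
#' @param t per-animal age readouts, aligned with rows.
#' @param p_threshold retention threshold on the correlation p-value.
#' @return the input restricted to retained readouts, with attribute
#'   `"p_values"`; errors if nothing survives.
#' @export
filterBehaviors <- function(behavior, t, p_threshold = 0.3) {
  t <- as.numeric(t)
  m <- trial_mean(behavior)
  if (nrow(m) != length(t)) stop("animal count mismatch between matrix and t")
  p <- apply(m, 2, function(f) cor.test(f, t)$p.value)
  keep <- which(p <= p_threshold)
  if (!length(keep))
    stop("all readouts removed at p_threshold = ", p_threshold)
  out <- if (length(dim(behavior)) == 3L) behavior[, keep, , drop = FALSE]
         else behavior[, keep, drop = FALSE]
  structure(out, p_values = p)
}

#' Cluster correlated readouts and pick representatives
#'
#' Average-linkage hierarchical clustering under the distance `1 - |r|`,
#' cut at the silhouette-optimal cluster count; when several cuts have
#' statistically indistinguishable silhouettes (within `tie_window` of the
#' best) the finest of them wins, since the goal is mutually orthogonal
#' clusters. Mutually correlated readouts collapse to one cluster and
#' mutually orthogonal ones to singletons; the cluster count is an outcome,
#' never a parameter. The representative of each cluster is its medoid
#' (smallest summed distance to cluster mates).
#'
#' @param behavior animals x readouts matrix or 3-D array (trial-averaged
#'   internally).
#' @param max_k largest cluster count considered (default 12).
#' @param min_silhouette silhouette below which no grouping is supported
#'   and readouts are treated as mutually orthogonal singletons
#'   (default 0.25).
#' @param tie_window silhouette margin treated as a tie (default 0.02).
#' @return list: `cluster` (named assignments), `representatives` (readout
#'   names, one per cluster), `k`, `silhouette` (at the chosen cut).
#' @export
clusterBehaviors <- function(behavior, max_k = 12, min_silhouette = 0.25,
                             tie_window = 0.02) {
  m <- trial_mean(behavior)
  nm <- colnames(m) %||% paste0("readout", seq_len(ncol(m)))
  colnames(m) <- nm
  nr <- ncol(m)
  if (nr < 1) stop("need >= 1 readout")
  if (nr == 1)
    return(list(cluster = setNames(1L, nm), representatives = nm, k = 1L,
                silhouette = NA_real_))
  dmat <- 1 - abs(cor(m))
  medoids <- function(cl) vapply(sort(unique(cl)), function(g) {
    members <- which(cl == g)
    if (length(members) == 1) return(members)
    members[which.min(rowSums(dmat[members, members, drop = FALSE]))]
  }, integer(1))
  if (max(dmat) < 0.2)                       # everything mutually correlated
    return(list(cluster = setNames(rep(1L, nr), nm),
                representatives = nm[medoids(rep(1L, nr))], k = 1L,
                silhouette = NA_real_))
  hc <- hclust(as.dist(dmat), method = "average")
  ks <- 2:min(max_k, nr - 1L)
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k)
    if (length(unique(cl)) < 2) return(-Inf)
    mean(cluster::silhouette(cl, dmatrix = dmat)[, "sil_width"])
  }, numeric(1))
  if (max(sil) < min_silhouette) {           # mutually orthogonal readouts
    return(list(cluster = setNames(seq_len(nr), nm), representatives = nm,
                k = nr, silhouette = max(sil)))
  }
  k <- max(ks[sil >= max(sil) - tie_window])
  cl <- setNames(cutree(hc, k), nm)
  list(cluster = cl, representatives = nm[medoids(cl)], k = k,
       silhouette = sil[match(k, ks)])
}

## Closed-form constrained coefficients: corr(F alpha, t) is scale-invariant
## in alpha, so the maximizer on the unit sphere is the normalized OLS
## solution of the normal equations on centered data.
alpha_closed_form <- function(F, t, ridge = 0) {
  Fc <- scale(F, scale = FALSE)
  tc <- t - mean(t)
  G <- crossprod(Fc)
  if (ridge > 0) G <- G + diag(ridge, ncol(G))
  a <- tryCatch(solve(G, crossprod(Fc, tc)),
                error = function(e) NULL)
  if (is.null(a)) return(NULL)
  a <- as.numeric(a)
  n <- sqrt(sum(a^2))
  if (n == 0) return(rep(0, ncol(F)))
  a / n
}

#' Optimal linear coefficients linking behaviors to the age readout
#'
#' Finds `alpha` with `sum(alpha^2) = 1` maximizing the Pearson correlation
#' `R` of `F %*% alpha` with `t` (closed form via the normal equations on
#' centered data; `R` equals the multiple correlation coefficient). The
#' p-value comes from permutations of the animals, since the constrained
#' maximization invalidates the parametric null.
#'
#' @param F animals x representatives matrix (one column per cluster
#'   representative, trial-averaged).
#' @param t per-animal age readouts; `length(t)` must exceed `ncol(F)`.
#' @param n_perm permutations for the p-value (default 10000).
#' @param seed root seed.
#' @return list: `alpha` (named, unit norm), `R`, `p` (permutation),
#'   `ridge` (penalty used, 0 unless the design was singular), `n_perm`.
#' @export
optimizeAlpha <- function(F, t, n_perm = 10000, seed = 1) {
  F <- as.matrix(F)
  t <- as.numeric(t)
  if (nrow(F) != length(t)) stop("animal count mismatch")
  if (nrow(F) <= ncol(F))
    stop("need more animals than representatives")
  ridge <- 0
  a <- alpha_closed_form(F, t)
  if (is.null(a)) {
    ridge <- 1e-6 * mean(diag(crossprod(scale(F, scale = FALSE))))
    a <- alpha_closed_form(F, t, ridge)
    if (is.null(a)) stop("singular design even under ridge fallback")
  }
  R <- cor(as.numeric(F %*% a), t)
  with_seed(substream(seed, "alpha_perm"), {
    r_null <- vapply(seq_len(n_perm), function(i) {
      tp <- sample(t)
      ap <- alpha_closed_form(F, tp, ridge)
      if (is.null(ap) || all(ap == 0)) return(0)
      cor(as.numeric(F %*% ap), tp)
    }, numeric(1))
    p <- (1 + sum(r_null >= R)) / (n_perm + 1)
  })
  names(a) <- colnames(F)
  list(alpha = a, R = R, p = p, ridge = ridge, n_perm = n_perm)
}

#' Trial-resampled coefficients with stability spread
#'
#' Recomputes `alpha` over leave-one-trial-out jackknife replicates (one
#' per trial) and over seeded random recombinations (each readout's values
#' taken from one uniformly chosen trial), then averages. Replicate alphas
#' are sign-aligned to the all-trials solution before averaging (the
#' objective is sign-symmetric); the final alpha is renormalized to unit
#' norm and the per-coefficient SD over recombination draws is the spread.
#'
#' @param behavior animals x representatives x trials array (representative
#'   readouts only).
#' @param t per-animal age readouts.
#' @param n_draws recombination draws (default 1000).
#' @param seed root seed.
#' @return list: `alpha` (unit norm), `spread` (per-coefficient SD),
#'   `jackknife` (trials x coefficients matrix), `R` of the final alpha,
#'   `alpha_full` (all-trials solution).
#' @export
stabilizeAlpha <- function(behavior, t, n_draws = 1000, seed = 1) {
  t <- as.numeric(t)
  if (length(dim(behavior)) != 3L)
    stop("behavior must be an animals x readouts x trials array")
  n_trials <- dim(behavior)[3]
  k <- dim(behavior)[2]
  full <- alpha_closed_form(trial_mean(behavior), t)
  align <- function(a) if (sum(a * full) < 0) -a else a
  jk <- NULL
  if (n_trials >= 2) {
    jk <- t(vapply(seq_len(n_trials), function(tr) {
      m <- apply(behavior[, , -tr, drop = FALSE], c(1, 2), mean)
      align(alpha_closed_form(m, t))
    }, numeric(k)))
  } else message("single trial: jackknife skipped")
  with_seed(substream(seed, "alpha_recombine"), {
    draws <- t(vapply(seq_len(n_draws), function(i) {
      pick <- sample.int(n_trials, k, replace = TRUE)
      m <- vapply(seq_len(k), function(j) behavior[, j, pick[j]],
                  numeric(dim(behavior)[1]))
      align(alpha_closed_form(m, t))
    }, numeric(k)))
  })
  a <- colMeans(draws)
  a <- a / sqrt(sum(a^2))
  names(a) <- dimnames(behavior)[[2]]
  list(alpha = a, spread = apply(draws, 2, sd), jackknife = jk,
       R = cor(as.numeric(trial_mean(behavior) %*% a), t),
       alpha_full = setNames(full, dimnames(behavior)[[2]]))
}
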