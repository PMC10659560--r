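## Single-cell ImAge readouts and young/old signature calling. Signature
## cells are single cells whose readout is hardly seen in the opposite
## reference group: young-signature below the old group's 5th percentile,
## old-signature above the young group's 95th percentile.

#' Single-cell ImAge readouts from a bootstrap-trained axis
#'
#' Projects individual cells onto an axis constructed on bootstrap-mean
#' rows, using the axis's own standardizer (fitted on bootstrap means) —
#' no refitting, so cells land in exactly the training space. Single-cell
#' distributions are wider and overlap more than bootstrap-mean
#' distributions; that heterogeneity is the point of signature calling.
#'
#' @param cells [CellFeatureSet-class] of raw single cells.
#' @param axis an [ImAgeAxis-class] carrying a standardizer (e.g. from
#'   [validateAxis()]).
#' @return data.frame: `animal`, `age`, `group`, `p`, `d_o` per cell.
#' @export
singleCellReadouts <- function(cells, axis) {
  if (is.null(axis@standardizer))
    stop("axis has no standardizer; fit it via the bootstrap protocol")
  projectOnAxis(cells, axis, standardized = FALSE)
}

#' Call young/old signature cells from percentile thresholds
#'
#' Thresholds come from the reference groups: cells with readout strictly
#' below the `q_old`-th percentile of the old reference readouts are young
#' signatures, strictly above the `q_young`-th percentile of the young
#' reference readouts are old signatures, all others intermediate (ties at
#' a threshold are intermediate). Percentiles use the inverse-ECDF
#' convention (R quantile type 1): the threshold is an observed readout, so
#' at most `q_old`% of old reference cells fall strictly below it and at
#' most `100 - q_young`% of young reference cells strictly above, at any
#' sample size. Setting `q_old = 0, q_young = 100` gives the
#' purity limit: signatures only outside the other group's observed range.
#'
#' @param young_ref,old_ref numeric single-cell readouts of the reference
#'   groups.
#' @param query numeric readouts to label, or a data.frame with columns
#'   `p` and `animal` (per-animal proportions are then reported).
#' @param q_old percentile of the old group bounding young signatures
#'   (default 5).
#' @param q_young percentile of the young group bounding old signatures
#'   (default 95).
#' @return list: `calls` (data.frame with `readout`, `label`), `thresholds`,
#'   and `proportions` (per animal when ids are given: young / old /
#'   intermediate fractions summing to 1).
#' @export
callSignatures <- function(young_ref, old_ref, query,
                           q_old = 5, q_young = 95) {
  if (!length(young_ref) || !length(old_ref))
    stop("reference groups must be non-empty")
  if (q_old < 0 || q_young > 100 || q_old > 100 || q_young < 0)
    stop("percentiles must lie in [0, 100]")
  thr_young <- quantile(old_ref, q_old / 100, names = FALSE, type = 1)
  thr_old <- quantile(young_ref, q_young / 100, names = FALSE, type = 1)
  animal <- NULL
  if (is.data.frame(query)) {
    animal <- query$animal
    query <- query$p
  }
  ## literal indicator functions; a cell extreme for both references (possible
  ## when the groups separate so far that the thresholds cross) is ambiguous
  ## and stays intermediate, as does a tie at either threshold
  i_young <- query < thr_young
  i_old <- query > thr_old
  label <- ifelse(i_young & !i_old, "young",
                  ifelse(i_old & !i_young, "old", "intermediate"))
  if (diff(range(c(young_ref, old_ref))) == 0) {
    warning("degenerate references: all readouts equal; everything intermediate")
    label[] <- "intermediate"
  }
  calls <- data.frame(readout = query, label = label)
  prop_of <- function(lb) {
    f <- factor(lb, levels = c("young", "intermediate", "old"))
    as.data.frame(t(as.matrix(prop.table(table(f)))))
  }
  if (is.null(animal)) {
    proportions <- cbind(animal = NA, prop_of(label))
  } else {
    calls$animal <- animal
    proportions <- do.call(rbind, lapply(split(label, animal), prop_of))
    proportions <- cbind(animal = rownames(proportions), proportions)
    rownames(proportions) <- NULL
  }
  list(calls = calls,
       thresholds = c(young_below = thr_young, old_above = thr_old),
       proportions = proportions)
}

#' Rejuvenation report for a treated group against young/old references
#'
#' Summarizes a reprogramming-style perturbation: per-animal median
#' single-cell readouts, pairwise rank tests of every animal against the
#' "youngest" old reference animal (the old animal with the lowest median),
#' a group-level variance comparison of treated vs old readouts, and
#' signature-proportion shifts relative to that reference animal.
#'
#' @param readouts data.frame with columns `animal`, `group`, `p`
#'   (single-cell readouts); `group` must contain `young`, `old` and
#'   `treated` levels (names configurable).
#' @param groups named character vector mapping the roles
#'   `c(young=, old=, treated=)` to labels in `readouts$group`.
#' @param q_old,q_young signature percentiles (see [callSignatures()]).
#' @return list: `per_animal` medians, `reference_animal`, `mw` (per-animal
#'   Wilcoxon p-values vs the reference animal's cells), `variance_test`
#'   (Levene-type on absolute deviations, treated vs old), `signatures`
#'   (per-animal proportions and delta vs reference).
#' @export
reprogrammingReport <- function(readouts,
                                groups = c(young = "young", old = "old",
                                           treated = "treated"),
                                q_old = 5, q_young = 95) {
  need <- groups %in% readouts$group
  if (!all(need)) stop("missing group(s): ",
                       paste(groups[!need], collapse = ", "))
  med <- aggregate(p ~ animal + group, readouts, median)
  old_med <- med[med$group == groups["old"], ]
  ref_animal <- old_med$animal[which.min(old_med$p)]
  ref_cells <- readouts$p[readouts$animal == ref_animal]
  others <- setdiff(unique(readouts$animal), ref_animal)
  mw <- vapply(others, function(an)
    suppressWarnings(wilcox.test(readouts$p[readouts$animal == an],
                                 ref_cells))$p.value, numeric(1))
  ## Levene-type test on absolute deviations from group medians
  lev <- local({
    sel <- readouts$group %in% groups[c("old", "treated")]
    if (length(unique(readouts$animal[sel & readouts$group ==
          groups["treated"]])) < 2 ||
        length(unique(readouts$animal[sel & readouts$group ==
          groups["old"]])) < 2)
      stop("need >= 2 animals per group for the variance test")
    g <- readouts$group[sel]
    dev <- abs(readouts$p[sel] - ave(readouts$p[sel], g, FUN = median))
    suppressWarnings(wilcox.test(dev[g == groups["treated"]],
                                 dev[g == groups["old"]]))$p.value
  })
  sig <- callSignatures(
    young_ref = readouts$p[readouts$group == groups["young"]],
    old_ref = readouts$p[readouts$group == groups["old"]],
    query = readouts[, c("p", "animal")], q_old = q_old, q_young = q_young)
  props <- sig$proportions
  ref_young_prop <- props$young[props$animal == ref_animal]
  props$delta_young_vs_reference <- props$young - ref_young_prop
  list(per_animal = med, reference_animal = ref_animal,
       mw = data.frame(animal = others, p_value = unname(mw)),
       variance_test = c(p_value = lev),
       signatures = props, thresholds = sig$thresholds)
}
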