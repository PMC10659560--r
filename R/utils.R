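#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom methods new is validObject setClass setGeneric setMethod show
#' @importFrom stats sd var cor cor.test quantile rnorm runif ks.test hclust ave
#'   cutree as.dist dist cmdscale optim optimize median p.adjust aggregate
#'   complete.cases setNames wilcox.test ecdf
#' @importFrom utils head combn
NULL

## Evaluate `expr` under a fixed RNG state derived from `seed`, restoring the
## caller's RNG state afterwards. All randomness in the package flows through
## this helper so that a single root seed gives named, independent substreams.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic substream id: fold a stream name into a root seed.
## Keeps results independent across generators sharing one root seed.
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
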