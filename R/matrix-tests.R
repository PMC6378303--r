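.checkDistPair <- function(d1, d2) {
  n1 <- attr(d1, "Size"); n2 <- attr(d2, "Size")
  if (n1 != n2) stop("distance matrices have different sample counts")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    if (!setequal(l1, l2))
      stop("distance matrices cover different samples")
    stop("distance matrices have the same samples in different order")
  }
  if (n1 < 4) stop("Mantel tests need at least 4 samples")
  invisible(TRUE)
}

#' Mantel test
#'
#' Pearson correlation r between the lower triangles of two distance
#' matrices; significance by simultaneous row/column permutation of the
#' first matrix, one-sided for positive association:
#' p = (1 + #{r_null >= r}) / (1 + nPerm).
#'
#' @param d1,d2 `dist` objects over the same samples in the same order.
#' @param nPerm permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `r`, `p`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = NULL) {
  .checkDistPair(d1, d2)
  if (stats::sd(as.vector(d1)) == 0 || stats::sd(as.vector(d2)) == 0)
    stop("constant distance matrix: correlation undefined")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = "pearson", permutations = nPerm)
  list(r = unname(fit$statistic), p = fit$signif, nPerm = nPerm)
}

#' Partial Mantel test
#'
#' Partial correlation of `d1` and `d2` controlling `d3`:
#' r_{12.3} = (r12 - r13 r23) / sqrt((1 - r13^2)(1 - r23^2)) over the
#' pairwise distance vectors, with the permutation null built by
#' permuting `d1`'s rows/columns and recomputing the partial statistic.
#'
#' @param d1,d2,d3 conformable `dist` objects; `d3` is the control.
#' @inheritParams mantelTest
#' @return list with `r`, `p`, `nPerm`.
#' @export
partialMantelTest <- function(d1, d2, d3, nPerm = 999, seed = NULL) {
  .checkDistPair(d1, d2); .checkDistPair(d1, d3)
  v1 <- as.vector(d1); v2 <- as.vector(d2); v3 <- as.vector(d3)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0 || stats::sd(v3) == 0)
    stop("constant distance matrix: correlation undefined")
  if (isTRUE(all.equal(v2, v3, tolerance = 1e-12)))
    return(list(r = 0, p = 1, nPerm = nPerm))  # self-control annihilates
  r13 <- stats::cor(v1, v3); r23 <- stats::cor(v2, v3)
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12)
    stop("control matrix is perfectly collinear with an input")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel.partial(d1, d2, d3, method = "pearson",
                               permutations = nPerm)
  list(r = unname(fit$statistic), p = fit$signif, nPerm = nPerm)
}

#' Euclidean distance on standardized environmental variables
#'
#' Standard construction of the environmental distance matrix for Mantel
#' tests: each variable is z-scored, then Euclidean distances are taken
#' over samples.
#'
#' @param env data.frame/matrix of environmental variables (samples in
#'   rows).
#' @return `dist` object.
#' @export
envDistance <- function(env) {
  m <- as.matrix(as.data.frame(env))
  keep <- apply(m, 2, stats::sd) > 0
  d <- stats::dist(scale(m[, keep, drop = FALSE]))
  attr(d, "Labels") <- rownames(as.data.frame(env))
  d
}
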