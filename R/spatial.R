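#' Geographic distances between samples
#'
#' Euclidean distances on the planar coordinates (`x_m`, `y_m`).
#'
#' @param x an [OTUExperiment-class] with coordinates in `colData`, or a
#'   data.frame with `x_m`/`y_m` columns.
#' @return `dist` object over samples.
#' @export
geoDistance <- function(x) {
  md <- if (is(x, "OTUExperiment")) sampleData(x) else x
  if (!all(c("x_m", "y_m") %in% colnames(md)))
    stop("coordinates x_m/y_m are missing")
  xy <- cbind(md$x_m, md$y_m)
  if (any(!is.finite(xy))) stop("non-finite coordinates")
  d <- stats::dist(xy)
  attr(d, "Labels") <- rownames(md)
  d
}

#' PCNM spatial eigenvectors
#'
#' Principal coordinates of neighbour matrices: geographic distances
#' beyond the truncation distance are replaced by 4x that distance, the
#' truncated matrix is subjected to PCoA, and the positive-eigenvalue
#' axes are retained as spatial explanatory variables (PCNM1, PCNM2, ...)
#' describing broad- to fine-scale spatial structure. The default
#' truncation is the longest edge of the minimum spanning tree, the
#' smallest distance keeping all sites connected.
#'
#' @param d geographic `dist` (from [geoDistance()]).
#' @param truncation optional truncation distance.
#' @return list with `vectors` (samples x retained axes), `values`
#'   (positive eigenvalues) and `threshold` (truncation used).
#' @export
pcnmVectors <- function(d, truncation = NULL) {
  if (attr(d, "Size") < 3) stop("PCNM needs at least 3 sites")
  fit <- if (is.null(truncation)) vegan::pcnm(d)
         else vegan::pcnm(d, threshold = truncation)
  vec <- as.matrix(fit$vectors)
  list(vectors = vec,
       values = fit$values[seq_len(ncol(vec))],
       threshold = fit$threshold)
}

# R2 of a multivariate regression of (column-centred) Y on X, via QR
.constrainedR2 <- function(Y, X) {
  qx <- qr(cbind(1, as.matrix(X)))
  fit <- qr.fitted(qx, Y)
  fit <- sweep(fit, 2, colMeans(Y))
  Yc <- sweep(Y, 2, colMeans(Y))
  sum(fit^2) / sum(Yc^2)
}

#' Permutation-based forward selection of explanatory variables
#'
#' Greedy forward selection for constrained ordination. At each step the
#' candidate adding the largest constrained variance is considered; its
#' admission test permutes the residuals of the reduced model and
#' recomputes the *maximum* added variance over all remaining candidates,
#' so the permutation null accounts for best-of-k selection bias and the
#' procedure holds its nominal size under pure noise. Admission requires
#' p < `alpha` (double stopping: selection also stops once the adjusted
#' R2 of the selected set exceeds that of the full candidate model). Ties
#' in added variance break lexicographically by variable name. An
#' optional protective global test of the full model can be run first.
#'
#' @param Y response matrix (samples x variables), e.g.
#'   Hellinger-transformed composition ([hellinger()]).
#' @param candidates data.frame/matrix of candidate explanatory columns.
#' @param alpha admission level (default 0.05).
#' @param nPerm permutations per test (default 999).
#' @param seed optional integer seed.
#' @param globalTest also require the full candidate model to be
#'   significant at `alpha` before selecting (default FALSE; the
#'   max-statistic admission test is already family-wise calibrated).
#' @return data.frame of the selected variables in order, with columns
#'   `variable`, `r2_added`, `r2_cum`, `p`; zero rows when nothing is
#'   selected.
#' @export
forwardSelect <- function(Y, candidates, alpha = 0.05, nPerm = 999,
                          seed = NULL, globalTest = FALSE) {
  Y <- as.matrix(Y)
  X <- as.matrix(as.data.frame(candidates))
  empty <- data.frame(variable = character(), r2_added = numeric(),
                      r2_cum = numeric(), p = numeric())
  if (ncol(X) == 0) return(empty)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X <- X[, !duplicated(colnames(X)) & !duplicated(t(X)), drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)

  if (globalTest) {
    r2_full_obs <- .constrainedR2(Y, X)
    null <- replicate(nPerm, .constrainedR2(Y[sample.int(n), , drop = FALSE], X))
    p_global <- (1 + sum(null >= r2_full_obs)) / (1 + nPerm)
    if (p_global >= alpha) return(empty)
  }
  # ceiling undefined when the candidate set saturates the df; selection
  # then stops on the admission test alone
  r2adj_full <- if (n - ncol(X) - 1 >= 1)
    adjustedR2(.constrainedR2(Y, X), n, ncol(X)) else Inf

  selected <- character(); rows <- list()
  repeat {
    remaining <- setdiff(colnames(X), selected)
    if (!length(remaining)) break
    base <- X[, selected, drop = FALSE]
    r2_base <- if (length(selected)) .constrainedR2(Y, base) else 0
    cand_r2 <- vapply(remaining, function(v)
      .constrainedR2(Y, cbind(base, X[, v])), numeric(1))
    ord <- order(-cand_r2, remaining)  # ties by name
    best <- remaining[ord[1]]
    r2_best <- cand_r2[ord[1]]
    # admission test: permute residuals of the reduced model and compare
    # the observed best gain against the null distribution of the maximum
    # gain over all remaining candidates (family-wise calibrated)
    maxGain <- function(Yp, r2b) {
      max(vapply(remaining, function(v)
        .constrainedR2(Yp, cbind(base, X[, v])), numeric(1))) - r2b
    }
    if (length(selected)) {
      qb <- qr(cbind(1, base))
      fitted <- qr.fitted(qb, Y)
      resid <- Y - fitted
      null <- replicate(nPerm, {
        Yp <- fitted + resid[sample.int(n), , drop = FALSE]
        maxGain(Yp, .constrainedR2(Yp, base))
      })
    } else {
      null <- replicate(nPerm,
        maxGain(Y[sample.int(n), , drop = FALSE], 0))
    }
    pv <- (1 + sum(null >= r2_best - r2_base)) / (1 + nPerm)
    if (pv >= alpha) break
    selected <- c(selected, best)
    rows[[best]] <- data.frame(variable = best,
                               r2_added = r2_best - r2_base,
                               r2_cum = r2_best, p = pv)
    # second stopping rule: once the selected set's adjusted R2 exceeds
    # the full candidate model's, stop adding further variables
    if (adjustedR2(r2_best, n, length(selected)) > r2adj_full) break
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
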