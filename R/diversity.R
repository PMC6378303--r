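#' Per-sample alpha diversity
#'
#' Observed richness, bias-corrected Chao1
#' (S + F1(F1-1)/(2(F2+1)), defined also when no doubletons exist),
#' Shannon index (natural log) and the Gini-Simpson index (1 - sum p^2).
#'
#' @param x an [OTUExperiment-class] (integer counts; Chao1 needs
#'   singleton/doubleton counts).
#' @return data.frame with one row per sample: `sample`, `observed`,
#'   `chao1`, `shannon`, `simpson`.
#' @export
alphaDiversity <- function(x) {
  m <- t(otuCounts(x))  # vegan wants samples x taxa
  if (any(rowSums(m) == 0))
    stop("empty sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  est <- vegan::estimateR(round(m))
  data.frame(sample = rownames(m),
             observed = as.numeric(est["S.obs", ]),
             chao1 = as.numeric(est["S.chao1", ]),
             shannon = as.numeric(vegan::diversity(m, index = "shannon")),
             simpson = as.numeric(vegan::diversity(m, index = "simpson")),
             row.names = rownames(m))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), in [0, 1].
#'
#' @param x an [OTUExperiment-class] or taxa-x-samples matrix.
#' @return `dist` object over samples.
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "OTUExperiment")) otuCounts(x) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  empty <- colSums(m) == 0
  if (sum(empty) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(colnames(m)[empty], collapse = ", "))
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling: Gower double-centering of -D^2/2 followed by
#' eigen-decomposition; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. Axes with negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported and by
#' default dropped from the coordinates.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param negativePolicy "drop" (default) keeps only positive axes;
#'   "keep" reports all eigenvalues but still returns real coordinates
#'   for positive axes only.
#' @return list with `points` (samples x axes), `eigenvalues` (all, non-
#'   increasing), `proportion` (share of the positive-eigenvalue sum per
#'   retained axis).
#' @export
pcoaOrdination <- function(d, negativePolicy = c("drop", "keep")) {
  negativePolicy <- match.arg(negativePolicy)
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(m)
  B <- -0.5 * m^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  B <- B + mean(-0.5 * m^2)  # double centering: (I-11'/n) A (I-11'/n)
  e <- eigen(B, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > max(eig) * 1e-10)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig[pos]),
                                                 length(pos))
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_along(pos))
  keep <- if (negativePolicy == "drop") eig[pos] else eig
  list(points = pts, eigenvalues = eig,
       proportion = eig[pos] / sum(eig[pos]),
       negative = sum(eig < 0))
}

#' Analysis of similarity (ANOSIM)
#'
#' Clarke's R = (mean between-group rank - mean within-group rank) /
#' (M/4), M = n(n-1)/2, with ranks over all sample pairs (average ranks
#' for ties); p by permutation of group labels,
#' p = (1 + #{R_null >= R}) / (1 + nPerm). `pairwise = TRUE` additionally
#' runs each pair of groups.
#'
#' @param d `dist` of community dissimilarities.
#' @param groups group label per sample; >= 2 groups with >= 2 samples.
#' @param nPerm permutations (default 999).
#' @param seed optional integer seed.
#' @param pairwise also test every group pair.
#' @return list with `R`, `p`, and if requested `pairwise` (data.frame
#'   group1/group2/R/p).
#' @export
anosimTest <- function(d, groups, nPerm = 999, seed = NULL,
                       pairwise = FALSE) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = nPerm)
  out <- list(R = unname(fit$statistic), p = fit$signif)
  if (pairwise) {
    m <- as.matrix(d)
    lv <- levels(groups)
    pw <- do.call(rbind, lapply(utils::combn(lv, 2, simplify = FALSE),
      function(pr) {
        sel <- groups %in% pr
        f <- vegan::anosim(stats::as.dist(m[sel, sel]),
                           droplevels(groups[sel]), permutations = nPerm)
        data.frame(group1 = pr[1], group2 = pr[2],
                   R = unname(f$statistic), p = f$signif)
      }))
    out$pairwise <- pw
  }
  out
}

# compact letter display from a symmetric matrix of pairwise p-values:
# groups not significantly different at alpha share a letter
.letterDisplay <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  # start from one letter covering everything, then split on each
  # significant pair (insert-and-absorb)
  sets <- list(g)
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    if (pmat[i, j] < alpha) {
      newsets <- list()
      for (s in sets) {
        if (all(c(g[i], g[j]) %in% s)) {
          newsets <- c(newsets, list(setdiff(s, g[i])),
                       list(setdiff(s, g[j])))
        } else newsets <- c(newsets, list(s))
      }
      # absorb subsets
      keep <- rep(TRUE, length(newsets))
      for (a in seq_along(newsets)) for (b in seq_along(newsets))
        if (a != b && keep[a] && all(newsets[[a]] %in% newsets[[b]]) &&
            !identical(sort(newsets[[a]]), sort(newsets[[b]])))
          keep[a] <- FALSE
      sets <- unique(lapply(newsets[keep], sort))
    }
  }
  letters_ <- letters[seq_along(sets)]
  vapply(g, function(gr)
    paste0(letters_[vapply(sets, function(s) gr %in% s, logical(1))],
           collapse = ""),
    character(1))
}

#' One-way group comparison with compact letter display
#'
#' One-way ANOVA across groups plus Tukey HSD pairwise comparisons
#' summarized as letter groupings (groups sharing a letter do not differ
#' at `alpha`), emulating the superscript convention of field tables.
#'
#' @param values numeric response.
#' @param groups group label per value; >= 2 groups with >= 2 values.
#' @param alpha letter-display significance level (default 0.05).
#' @return list with `F`, `p`, `letters` (named by group), `tukey`
#'   (TukeyHSD table).
#' @export
groupCompare <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0))
    stop("zero within-group variance in all groups; F is undefined")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$groups
  lv <- levels(groups)
  pmat <- matrix(1, nlevels(groups), nlevels(groups),
                 dimnames = list(lv, lv))
  for (r in rownames(tk)) {
    pr <- strsplit(r, "-", fixed = TRUE)[[1]]
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tk[r, "p adj"]
  }
  list(F = Fv, p = pv, letters = .letterDisplay(pmat, alpha), tukey = tk)
}
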