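#' Levins' niche breadth
#'
#' For each taxon j, B_j = 1 / sum_i p_ij^2 where p_ij is the taxon's
#' abundance in habitat (sample) i renormalized so sum_i p_ij = 1. B
#' ranges from 1 (confined to a single habitat) to n (perfectly even over
#' all n habitats). Taxa absent everywhere get `NA` with a warning.
#'
#' @param x an [OTUExperiment-class], or a taxa-x-samples abundance
#'   matrix (counts or relative abundances; each taxon's row is
#'   renormalized internally, cf. the per-sample normalization of
#'   [relativeAbundances()]).
#' @return named numeric vector of B values.
#' @export
levinsBreadth <- function(x) {
  m <- if (is(x, "OTUExperiment")) relativeAbundances(x) else as.matrix(x)
  tot <- rowSums(m)
  absent <- tot == 0
  if (any(absent))
    warning(sum(absent), " taxa absent everywhere; B undefined (NA)")
  p <- sweep(m, 1, ifelse(absent, 1, tot), "/")
  b <- 1 / rowSums(p^2)
  b[absent] <- NA_real_
  stats::setNames(b, rownames(m))
}

#' Classify taxa by niche breadth
#'
#' B strictly above `high` is a habitat generalist, strictly below `low` a
#' habitat specialist; everything else (boundaries included) is "other".
#' Default thresholds 1.5 and 8.7 lie in the outlier area of typical B
#' distributions over 13 habitats.
#'
#' @param B named numeric of breadth values ([levinsBreadth()]).
#' @param low,high classification thresholds, `low < high`.
#' @return named factor with levels generalist/specialist/other (`NA` B
#'   propagates).
#' @export
classifyByBreadth <- function(B, low = 1.5, high = 8.7) {
  stopifnot(low < high)
  out <- factor(rep("other", length(B)),
                levels = c("generalist", "specialist", "other"))
  out[B > high] <- "generalist"
  out[B < low] <- "specialist"
  out[is.na(B)] <- NA
  stats::setNames(out, names(B))
}

#' Data-driven breadth thresholds from the outlier area
#'
#' Tukey fences of the B distribution: `Q1 - 1.5 IQR` (floored at 1, the
#' minimum attainable B) and `Q3 + 1.5 IQR` (capped at the number of
#' habitats). Quartiles use the linear-interpolation definition
#' (`stats::quantile` type 7).
#'
#' @param B numeric breadth values (>= 5 non-missing).
#' @param nHabitats cap for the upper fence; defaults to `max(B)` rounded
#'   up.
#' @return numeric `c(low, high)`.
#' @export
breadthOutlierThresholds <- function(B, nHabitats = ceiling(max(B, na.rm = TRUE))) {
  B <- B[!is.na(B)]
  if (length(B) < 5) stop("need at least 5 breadth values")
  if (stats::sd(B) == 0)
    stop("constant breadth distribution has no outlier area")
  q <- stats::quantile(B, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(low = max(1, q[1] - 1.5 * iqr),
    high = min(nHabitats, q[2] + 1.5 * iqr))
}

#' Indicator value (INDVAL) analysis
#'
#' For each taxon and group g: specificity A = mean abundance in g divided
#' by the sum over groups of mean abundances; fidelity F = fraction of
#' g's samples where the taxon is present. IndVal = max over groups of
#' A * F, in [0, 1]; 1 marks a perfect single-group indicator. The
#' p-value comes from random reassignment of samples to groups:
#' p = (1 + #{null >= observed}) / (1 + nPerm).
#'
#' @param x an [OTUExperiment-class] or counts matrix (taxa x samples).
#' @param groups factor/character of group membership per sample (>= 2
#'   groups, each with >= 1 sample).
#' @param nPerm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return data.frame with columns `taxon`, `indval`, `group` (the
#'   maximizing group) and `p`. Taxa absent everywhere get IndVal 0, p 1.
#' @export
indicatorValue <- function(x, groups, nPerm = 999, seed = NULL) {
  m <- if (is(x, "OTUExperiment")) otuCounts(x) else as.matrix(x)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m))
    stop("groups must have one label per sample")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)

  stat <- function(g) {
    gm <- vapply(levels(g), function(lv)
      rowMeans(m[, g == lv, drop = FALSE]), numeric(nrow(m)))
    occ <- vapply(levels(g), function(lv)
      rowMeans(m[, g == lv, drop = FALSE] > 0), numeric(nrow(m)))
    if (nrow(m) == 1) {
      gm <- matrix(gm, 1, dimnames = list(rownames(m), levels(g)))
      occ <- matrix(occ, 1, dimnames = list(rownames(m), levels(g)))
    }
    tot <- rowSums(gm)
    A <- gm / ifelse(tot == 0, 1, tot)
    iv <- A * occ
    list(indval = apply(iv, 1, max),
         group = levels(g)[max.col(iv, ties.method = "first")])
  }
  obs <- stat(groups)
  exceed <- integer(nrow(m))
  for (b in seq_len(nPerm)) {
    null <- stat(sample(groups))
    exceed <- exceed + (null$indval >= obs$indval)
  }
  p <- (1 + exceed) / (1 + nPerm)
  absent <- rowSums(m) == 0
  out <- data.frame(taxon = rownames(m), indval = obs$indval,
                    group = obs$group, p = p, row.names = rownames(m))
  out$indval[absent] <- 0
  out$p[absent] <- 1
  out
}

#' Strict habitat specialists
#'
#' Among the breadth-defined specialists, retains those with a significant
#' (p < `alpha`) IndVal strictly above `minIndval`.
#'
#' @param partition a [NichePartition-class] (or named category factor).
#' @param indval data.frame from [indicatorValue()].
#' @param minIndval IndVal cutoff (default 0.3).
#' @param alpha significance level (default 0.05).
#' @return character vector of strict-specialist taxon ids.
#' @export
strictSpecialists <- function(partition, indval, minIndval = 0.3,
                              alpha = 0.05) {
  cat_ <- if (is(partition, "NichePartition"))
    taxonCategory(partition) else partition
  spec <- names(cat_)[!is.na(cat_) & cat_ == "specialist"]
  iv <- indval[indval$taxon %in% spec, , drop = FALSE]
  iv$taxon[iv$indval > minIndval & iv$p < alpha]
}

#' Niche-breadth partition of a community
#'
#' High-level wrapper: computes Levins' B on the (typically rarefied and
#' rare-filtered) table, classifies generalists/specialists/other by the
#' fixed or data-driven thresholds, and optionally confirms strict
#' specialists with INDVAL.
#'
#' @param x an [OTUExperiment-class].
#' @param groups INDVAL grouping per sample; defaults to the `gradient`
#'   column of `sampleData(x)` when present ("site" uses each sample as
#'   its own group is not meaningful for INDVAL, so gradients are the
#'   default unit).
#' @param low,high breadth thresholds (defaults 1.5 / 8.7).
#' @param autoThresholds derive thresholds from the outlier area of the B
#'   distribution ([breadthOutlierThresholds()]) instead.
#' @param runIndval run INDVAL to flag strict specialists (default TRUE
#'   when `groups` are available).
#' @param nPerm,seed INDVAL permutation settings.
#' @param minIndval,alpha strict-specialist rule.
#' @return a [NichePartition-class].
#' @export
nichePartition <- function(x, groups = NULL, low = 1.5, high = 8.7,
                           autoThresholds = FALSE, runIndval = !is.null(groups) ||
                             "gradient" %in% colnames(sampleData(x)),
                           nPerm = 999, seed = NULL, minIndval = 0.3,
                           alpha = 0.05) {
  B <- levinsBreadth(x)
  keep <- !is.na(B)
  B <- B[keep]
  if (autoThresholds) {
    thr <- breadthOutlierThresholds(B, nHabitats = ncol(x))
    low <- thr[["low"]]; high <- thr[["high"]]
  }
  cat_ <- classifyByBreadth(B, low, high)
  iv <- DataFrame(taxon = character(), indval = numeric(),
                  group = character(), p = numeric())
  strict <- character()
  if (runIndval) {
    if (is.null(groups)) groups <- sampleData(x)$gradient
    ivdf <- indicatorValue(x[names(B), ], groups, nPerm = nPerm,
                           seed = seed)
    strict <- strictSpecialists(cat_, ivdf, minIndval, alpha)
    iv <- DataFrame(ivdf)
  }
  new("NichePartition", taxa = names(B), breadth = unname(B),
      category = cat_, thresholds = c(low, high), indval = iv,
      strict = strict)
}

#' Split an OTUExperiment into niche-breadth subcommunities
#'
#' @param x an [OTUExperiment-class] containing the partitioned taxa.
#' @param partition a [NichePartition-class] computed on `x`.
#' @return named list of OTUExperiment: `all`, `generalist`, `specialist`,
#'   `other`; the three subcommunities partition the taxa of `all`.
#' @export
subcommunities <- function(x, partition) {
  cat_ <- taxonCategory(partition)
  x <- x[names(cat_), ]
  list(all = x,
       generalist = x[names(cat_)[cat_ == "generalist"], ],
       specialist = x[names(cat_)[cat_ == "specialist"], ],
       other = x[names(cat_)[cat_ == "other"], ])
}
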