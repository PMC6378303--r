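#' Stochastically assemble a community from the regional pool
#'
#' Null-model draw: each sample receives its observed total number of
#' individuals, drawn multinomially from the regional species pool (all
#' samples summed) with probability proportional to each taxon's regional
#' relative abundance. Per-sample totals are preserved exactly and the
#' pool is identical for every draw; per-sample richness is free to vary
#' (individual-based null). `method = "richness"` offers the
#' richness-preserving variant: each sample keeps its observed richness,
#' occupants are drawn weighted by regional occurrence frequency, and the
#' sample's individuals are then distributed multinomially among them.
#'
#' @param x an [OTUExperiment-class].
#' @param seed optional integer seed.
#' @param method "abundance" (default) or "richness".
#' @return an [OTUExperiment-class] of the same shape.
#' @export
nullAssemble <- function(x, seed = NULL,
                         method = c("abundance", "richness")) {
  method <- match.arg(method)
  m <- otuCounts(x)
  if (nrow(m) == 0 || ncol(m) == 0 || sum(m) == 0)
    stop("empty table cannot be null-assembled")
  if (!is.null(seed)) set.seed(seed)
  pool <- rowSums(m) / sum(m)
  totals <- colSums(m)
  out <- m
  # columns are drawn in sample-name order so that, for a fixed seed, each
  # sample's null draw does not depend on column ordering
  colorder <- order(colnames(m))
  if (method == "abundance") {
    for (i in colorder)
      out[, i] <- stats::rmultinom(1, totals[i], pool)[, 1]
  } else {
    occ <- rowMeans(m > 0)
    richness <- colSums(m > 0)
    for (i in colorder) {
      out[, i] <- 0
      k <- min(richness[i], sum(occ > 0))
      if (k == 0) next
      members <- sample(which(occ > 0), k, prob = occ[occ > 0])
      # every member gets one individual; the rest go multinomially by
      # regional relative abundance
      out[members, i] <- 1
      extra <- totals[i] - k
      if (extra > 0)
        out[members, i] <- out[members, i] +
          stats::rmultinom(1, extra, pool[members])[, 1]
    }
  }
  y <- x
  assays(y)$counts <- out
  y
}

#' Beta-diversity null deviation
#'
#' For every sample pair, the observed beta diversity (Bray-Curtis by
#' default) is compared with its expectation over `nNull` stochastically
#' assembled communities ([nullAssemble()]); the relative deviation
#' `(beta_obs - beta_null_mean) / beta_obs` is near 0 when assembly is
#' statistically indistinguishable from random draws from the regional
#' pool (stochastic assembly) and grows positive when communities are
#' more differentiated than the null expects (deterministic, niche-based
#' assembly). Pairs with `beta_obs = 0` are flagged `NA`.
#'
#' @param x an [OTUExperiment-class] (a full community or one
#'   subcommunity).
#' @param nNull number of null assemblies (>= 1; 999 for final runs).
#' @param seed optional integer seed.
#' @param metric beta-diversity metric passed to [vegan::vegdist()]
#'   (default "bray").
#' @param method null-model variant, see [nullAssemble()].
#' @param group optional label stored with the result.
#' @return a [BetaNullDeviation-class].
#' @export
betaNullDeviation <- function(x, nNull = 999, seed = NULL,
                              metric = "bray",
                              method = c("abundance", "richness"),
                              group = "") {
  method <- match.arg(method)
  if (nNull < 1) stop("nNull must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- otuCounts(x)
  obs <- as.matrix(vegan::vegdist(t(m), method = metric))
  acc <- matrix(0, ncol(m), ncol(m))
  acc2 <- matrix(0, ncol(m), ncol(m))
  for (b in seq_len(nNull)) {
    nm <- otuCounts(nullAssemble(x, method = method))
    dn <- as.matrix(vegan::vegdist(t(nm), method = metric))
    acc <- acc + dn
    acc2 <- acc2 + dn^2
  }
  mu <- acc / nNull
  sdv <- sqrt(pmax(acc2 / nNull - mu^2, 0))
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  beta_obs <- obs[idx]
  dev <- ifelse(beta_obs > 0, (beta_obs - mu[idx]) / beta_obs, NA_real_)
  pairs <- data.frame(sample_i = colnames(m)[idx[, 1]],
                      sample_j = colnames(m)[idx[, 2]],
                      beta_obs = beta_obs,
                      beta_null_mean = mu[idx],
                      beta_null_sd = sdv[idx],
                      deviation = dev)
  new("BetaNullDeviation", pairs = pairs, nNull = nNull, metric = metric,
      group = group)
}

#' Null deviation for every niche-breadth subcommunity
#'
#' Runs [betaNullDeviation()] on the full community and on the
#' generalist/specialist/other sub-tables from a [NichePartition-class]
#' (taxon subsets of the same rarefied table; counts are not
#' re-rarefied).
#'
#' @param x an [OTUExperiment-class].
#' @param partition a [NichePartition-class] on `x`'s taxa.
#' @param nNull,seed,metric,method as in [betaNullDeviation()].
#' @return named list of [BetaNullDeviation-class] objects
#'   (all/generalist/specialist/other).
#' @export
subcommunityNullDeviation <- function(x, partition, nNull = 999,
                                      seed = NULL, metric = "bray",
                                      method = "abundance") {
  subs <- subcommunities(x, partition)
  seeds <- if (is.null(seed)) rep(list(NULL), length(subs))
           else as.list(seed + seq_along(subs))
  out <- Map(function(tab, nm, sd_) {
    tab <- tab[, colSums(otuCounts(tab)) > 0]  # sites without this
    if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)  # subcommunity
    betaNullDeviation(tab, nNull = nNull, seed = sd_, metric = metric,
                      method = method, group = nm)
  }, subs, names(subs), seeds)
  out[!vapply(out, is.null, logical(1))]
}

#' Compare null-deviation values across groups
#'
#' One-way ANOVA (with Tukey letters) across collections of deviation
#' values, e.g. the four subcommunities.
#'
#' @param deviations named list of numeric deviation vectors, or a list
#'   of [BetaNullDeviation-class] objects.
#' @return as [groupCompare()].
#' @export
compareDeviationGroups <- function(deviations) {
  vals <- lapply(deviations, function(d) {
    v <- if (is(d, "BetaNullDeviation")) deviationPairs(d)$deviation else d
    v[!is.na(v)]
  })
  if (any(lengths(vals) < 2)) stop("every group needs >= 2 deviations")
  groupCompare(unlist(vals, use.names = FALSE),
               rep(names(vals), lengths(vals)))
}
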