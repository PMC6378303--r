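#' Hellinger transformation
#'
#' Square root of relative abundances per sample; makes community data
#' suitable for linear (RDA-based) methods.
#'
#' @param x an [OTUExperiment-class] or taxa-x-samples matrix.
#' @return samples x taxa matrix (response orientation).
#' @export
hellinger <- function(x) {
  m <- if (is(x, "OTUExperiment")) otuCounts(x) else as.matrix(x)
  vegan::decostand(t(m), method = "hellinger")
}

.asExplanatory <- function(X) {
  X <- as.data.frame(X)
  X[] <- lapply(X, as.numeric)
  X
}

.wrapConstrained <- function(fit, method, pvalue = NA_real_) {
  sc <- vegan::scores(fit, display = c("sites", "bp"),
                      choices = seq_len(max(1, length(fit$CCA$eig))))
  new("ConstrainedOrdination", method = method,
      constrainedEig = unname(fit$CCA$eig),
      unconstrainedEig = unname(fit$CA$eig),
      totalInertia = fit$tot.chi,
      r2 = fit$CCA$tot.chi / fit$tot.chi,
      siteScores = as.matrix(sc$sites),
      variableScores = as.matrix(sc$biplot),
      pvalue = pvalue)
}

#' Redundancy analysis (RDA)
#'
#' Multivariate least squares of the (column-centred) response on the
#' standardized explanatory variables followed by eigen-analysis of the
#' fitted values; R2 is the fitted share of total variance. Collinear
#' explanatory columns are dropped (with vegan's aliasing warning).
#'
#' @param Y response matrix, samples x variables (typically
#'   [hellinger()]-transformed composition).
#' @param X explanatory data.frame/matrix.
#' @param nPerm if > 0, overall significance by permutation test.
#' @param seed optional integer seed for the permutation test.
#' @return a [ConstrainedOrdination-class].
#' @export
rdaFit <- function(Y, X, nPerm = 0, seed = NULL) {
  X <- .asExplanatory(X)
  fit <- vegan::rda(as.matrix(Y) ~ ., data = X)
  p <- NA_real_
  if (nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- stats::anova(fit, permutations = nPerm)$`Pr(>F)`[1]
  }
  .wrapConstrained(fit, "rda", p)
}

#' Canonical correspondence analysis (CCA)
#'
#' Chi-square standardized response (correspondence-analysis residuals)
#' regressed on the explanatory variables with row-mass weights; total
#' inertia equals the contingency chi-square statistic divided by the
#' grand total.
#'
#' @inheritParams rdaFit
#' @param Y non-negative response matrix (samples x taxa) with positive
#'   row and column sums.
#' @return a [ConstrainedOrdination-class].
#' @export
ccaFit <- function(Y, X, nPerm = 0, seed = NULL) {
  Y <- as.matrix(Y)
  if (any(rowSums(Y) <= 0) || any(colSums(Y) <= 0))
    stop("CCA requires positive row and column sums")
  X <- .asExplanatory(X)
  fit <- vegan::cca(Y ~ ., data = X)
  p <- NA_real_
  if (nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- stats::anova(fit, permutations = nPerm)$`Pr(>F)`[1]
  }
  .wrapConstrained(fit, "cca", p)
}

#' Ezekiel's adjusted R2
#'
#' `1 - (1 - r2) (n - 1) / (n - p - 1)`; unbiased under the null, may be
#' negative, and is the currency in which variation-partitioning
#' fractions are expressed.
#'
#' @param r2 unadjusted R2.
#' @param n number of samples.
#' @param p number of explanatory variables.
#' @return adjusted R2.
#' @export
adjustedR2 <- function(r2, n, p) {
  if (n - p - 1 < 1) stop("need n - p - 1 >= 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Variation partitioning between environment and space
#'
#' Decomposes community variance into pure environmental (E|S), pure
#' spatial (S|E), shared, and unexplained fractions from the adjusted R2
#' of three RDA models (env-only, spatial-only, joint):
#' `pure_env = R2adj(joint) - R2adj(spatial)`,
#' `pure_spatial = R2adj(joint) - R2adj(env)`,
#' `shared = R2adj(env) + R2adj(spatial) - R2adj(joint)`,
#' `unexplained = 1 - R2adj(joint)`. The testable pure fractions get
#' permutation p-values from partial RDA (reduced-model residual
#' permutation); the shared fraction is not testable and never receives
#' one. Fractions may be negative (adjusted R2) and always sum to 1.
#' Both explanatory sets are expected to be forward-selected upstream.
#'
#' @param Y response matrix, samples x variables (e.g. [hellinger()]).
#' @param Xenv,Xspatial explanatory sets; either (not both) may be empty
#'   (`NULL` or zero columns).
#' @param nPerm permutations for the fraction tests (default 999; 0
#'   skips).
#' @param seed optional integer seed.
#' @return a [VariancePartition-class].
#' @export
variationPartition <- function(Y, Xenv, Xspatial, nPerm = 999,
                               seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  hasE <- !is.null(Xenv) && NCOL(Xenv) > 0
  hasS <- !is.null(Xspatial) && NCOL(Xspatial) > 0
  if (!hasE && !hasS) stop("both explanatory sets are empty")
  r2a <- function(X) {
    fit <- suppressWarnings(vegan::rda(Y ~ ., data = .asExplanatory(X)))
    unname(vegan::RsquareAdj(fit)$adj.r.squared)
  }
  ab <- if (hasE) r2a(Xenv) else 0      # env model explains a + b
  bc <- if (hasS) r2a(Xspatial) else 0  # spatial model explains b + c
  abc <- if (hasE && hasS)
    r2a(cbind(.asExplanatory(Xenv), .asExplanatory(Xspatial)))
  else max(ab, bc)
  if (anyNA(c(ab, bc, abc)))
    stop("too many explanatory variables for n = ", n,
         " samples; forward-select or reduce the sets before VPA")
  fr <- c(pure_env = abc - bc, pure_spatial = abc - ab,
          shared = ab + bc - abc, unexplained = 1 - abc)
  pv <- numeric(0)
  if (nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    test <- function(X, Z) {
      dat <- cbind(.asExplanatory(X), .asExplanatory(Z))
      fml <- stats::as.formula(paste(
        "Y ~", paste(colnames(.asExplanatory(X)), collapse = "+"),
        "+ Condition(",
        paste(colnames(.asExplanatory(Z)), collapse = "+"), ")"))
      fit <- suppressWarnings(vegan::rda(fml, data = dat))
      stats::anova(fit, permutations = nPerm)$`Pr(>F)`[1]
    }
    full <- function(X) {
      fit <- suppressWarnings(vegan::rda(Y ~ ., data = .asExplanatory(X)))
      stats::anova(fit, permutations = nPerm)$`Pr(>F)`[1]
    }
    if (hasE && hasS) {
      pv <- c(pure_env = test(Xenv, Xspatial),
              pure_spatial = test(Xspatial, Xenv),
              full = full(cbind(.asExplanatory(Xenv),
                                .asExplanatory(Xspatial))))
    } else if (hasE) {
      pv <- c(pure_env = full(Xenv))
    } else {
      pv <- c(pure_spatial = full(Xspatial))
    }
  }
  new("VariancePartition", fractions = fr, pvalues = pv,
      r2adj = c(env = ab, spatial = bc, joint = abc))
}
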