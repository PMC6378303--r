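test_that("RDA recovers exact and null fits", {
  set.seed(2)
  n <- 10
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  B <- matrix(rnorm(2 * 4), 2, 4)
  Ylin <- as.matrix(X) %*% B
  fit <- rdaFit(Ylin, X)
  expect_equal(fit@r2, 1, tolerance = 1e-10)

  # response orthogonal to X by explicit residualization
  Y <- matrix(rnorm(n * 3), n, 3)
  Yorth <- qr.resid(qr(cbind(1, as.matrix(X))), Y)
  fit0 <- rdaFit(Yorth, X)
  expect_lt(fit0@r2, 1e-10)

  # fitted SS equals columnwise least-squares model SS
  Y2 <- matrix(rnorm(n * 5), n, 5)
  fit2 <- rdaFit(Y2, X)
  ss <- sum(vapply(seq_len(ncol(Y2)), function(j) {
    m <- lm(Y2[, j] ~ x1 + x2, data = X)
    sum((fitted(m) - mean(Y2[, j]))^2)
  }, numeric(1)))
  tot <- sum(scale(Y2, scale = FALSE)^2)
  expect_equal(fit2@r2, ss / tot, tolerance = 1e-8)
  expect_equal(sum(fit2@constrainedEig) + sum(fit2@unconstrainedEig),
               fit2@totalInertia, tolerance = 1e-8)
})

test_that("CCA matches the chi-square identity on a contingency toy", {
  set.seed(4)
  Y <- matrix(rpois(20, 8) + 1, 5, 4)
  X <- data.frame(x = rnorm(5))
  fit <- ccaFit(Y, X)
  chi2 <- suppressWarnings(chisq.test(Y)$statistic)
  expect_equal(fit@totalInertia, unname(chi2) / sum(Y), tolerance = 1e-8)
  # one explanatory column -> exactly one constrained axis
  expect_equal(length(fit@constrainedEig), 1)
  expect_error(ccaFit(rbind(Y, 0), X), "positive")
})

test_that("Ezekiel adjustment is exact", {
  expect_equal(adjustedR2(0.5, 20, 3), 0.40625)
  expect_equal(adjustedR2(0.31, 12, 0), 0.31)
  expect_equal(adjustedR2(1, 9, 4), 1)
  expect_error(adjustedR2(0.5, 5, 4), "n - p - 1")
  expect_lt(adjustedR2(0.05, 10, 5), 0)  # may be negative
})

test_that("variation partitioning algebra holds", {
  set.seed(9)
  n <- 13
  Y <- matrix(rnorm(n * 6), n, 6)
  Xe <- data.frame(e1 = rnorm(n), e2 = rnorm(n))
  Xs <- data.frame(s1 = rnorm(n), s2 = rnorm(n))

  vp <- variationPartition(Y, Xe, Xs, nPerm = 99, seed = 1)
  expect_lt(abs(sum(vp@fractions) - 1), 1e-8)
  expect_false("shared" %in% names(vp@pvalues))
  expect_true(all(c("pure_env", "pure_spatial") %in% names(vp@pvalues)))

  # identical explanatory sets: pure fractions vanish
  Xs2 <- Xe
  colnames(Xs2) <- c("s1", "s2")
  vp2 <- variationPartition(Y, Xe, Xs2, nPerm = 0)
  expect_lt(abs(vp2@fractions[["pure_env"]]), 1e-10)
  expect_lt(abs(vp2@fractions[["pure_spatial"]]), 1e-10)

  # spatial set empty reduces to the env-only model
  vp3 <- variationPartition(Y, Xe, NULL, nPerm = 0)
  expect_equal(vp3@fractions[["shared"]], 0)
  expect_equal(vp3@fractions[["pure_spatial"]], 0)
  expect_equal(vp3@fractions[["pure_env"]], vp3@r2adj[["env"]])

  expect_error(variationPartition(Y, NULL, NULL), "empty")
})

test_that("env-structured, spatially random data give pure_env >> pure_spatial", {
  wins <- 0
  nrep <- 50
  # smooth, strong environmental turnover (specialist niches spanning a
  # few sites) with spatially random site placement and no dispersal
  # limitation: all signal is environmental
  for (r in seq_len(nrep)) {
    x <- simulateMetacommunity(
      smallConfig(nSpecialist = 80, nGeneralist = 40, nNeutral = 60,
                  sigmaSpecialist = 0.3, dispersalDecay = 0,
                  layout = "random", depth = 2000),
      seed = 4000 + r)
    Y <- hellinger(x)
    md <- sampleData(x)
    Xe <- md[, c("elevation_m", "pH", "ST"), drop = FALSE]
    pc <- pcnmVectors(geoDistance(x))
    Xs <- as.data.frame(pc$vectors)[, seq_len(min(3, ncol(pc$vectors))),
                                    drop = FALSE]
    vp <- variationPartition(Y, Xe, Xs, nPerm = 0)
    if (vp@fractions[["pure_env"]] > vp@fractions[["pure_spatial"]])
      wins <- wins + 1
  }
  # one-sided sign test against p = 0.5
  expect_lt(binom.test(wins, nrep, alternative = "greater")$p.value, 0.01)
})

test_that("variation partitioning agrees with an independent reference", {
  set.seed(77)
  n <- 13
  Y <- matrix(rnorm(n * 5), n, 5)
  Xe <- data.frame(e1 = rnorm(n))
  Xs <- data.frame(s1 = rnorm(n))
  vp <- variationPartition(Y, Xe, Xs, nPerm = 0)
  ref <- vegan::varpart(Y, as.matrix(Xe), as.matrix(Xs))
  ind <- ref$part$indfract$Adj.R.square  # rows: X1|X2, X2|X1, shared, resid
  expect_equal(unname(vp@fractions[c("pure_env", "pure_spatial", "shared",
                                     "unexplained")]),
               ind, tolerance = 1e-8)
})
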