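test_that("alpha diversity matches closed forms", {
  x <- makeTable(cbind(S1 = c(5, 5, 5, 5)))
  a <- alphaDiversity(x)
  expect_equal(a$observed, 4)
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 0.75)
  expect_equal(a$chao1, 4)

  # bias-corrected Chao1: S = 10, F1 = 4, F2 = 2 -> 12
  counts <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  a2 <- alphaDiversity(makeTable(cbind(S1 = counts)))
  expect_equal(a2$chao1, 12)

  # single-taxon degenerate sample
  a3 <- alphaDiversity(makeTable(cbind(S1 = c(9, 0))))
  expect_equal(a3$shannon, 0)
  expect_equal(a3$simpson, 0)

  expect_error(alphaDiversity(makeTable(cbind(S1 = c(1, 1), S2 = c(0, 0)))),
               "S2")
})

test_that("alpha diversity inequalities hold on random samples", {
  x <- randomTable(60, 8, lambda = 2, seed = 5)
  a <- alphaDiversity(x)
  expect_true(all(a$chao1 >= a$observed - 1e-9))
  expect_true(all(a$shannon <= log(a$observed) + 1e-9))
  expect_true(all(a$simpson >= 0 & a$simpson < 1))
})

test_that("Bray-Curtis follows its formula", {
  x <- makeTable(cbind(S1 = c(2, 0, 0), S2 = c(1, 1, 0),
                       S3 = c(2, 0, 0), S4 = c(0, 0, 7)))
  d <- as.matrix(brayCurtis(x))
  expect_equal(d["S1", "S2"], 0.5)    # (|2-1|+1)/(3+1)
  expect_equal(d["S1", "S3"], 0)      # identical
  expect_equal(d["S1", "S4"], 1)      # disjoint
  expect_true(all(d >= 0 & d <= 1))
  expect_error(brayCurtis(makeTable(cbind(S1 = c(0, 0), S2 = c(0, 0)))),
               "all-zero")
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(3)
  pts <- cbind(runif(4, 0, 10), runif(4, 0, 10))
  d <- dist(pts)
  ord <- pcoaOrdination(d)
  rec <- dist(ord$points)
  expect_lt(max(abs(as.vector(rec) - as.vector(d))), 1e-8)

  # trace identity when all eigenvalues >= 0
  m <- as.matrix(d)
  B <- -0.5 * m^2
  J <- diag(4) - 1 / 4
  expect_equal(sum(ord$eigenvalues[ord$eigenvalues > 0]),
               sum(diag(J %*% B %*% J)), tolerance = 1e-8)

  # coincident samples land on identical coordinates
  m5 <- rbind(cbind(m, m[, 1]), c(m[1, ], 0))
  ord2 <- pcoaOrdination(as.dist(m5))
  expect_lt(max(abs(ord2$points[1, ] - ord2$points[5, ])), 1e-8)

  bad <- m; bad[1, 2] <- 99
  expect_error(pcoaOrdination(bad), "symmetric")
})

test_that("PCoA agrees with an independent eigen-oracle", {
  skip_if_not_installed("ape")
  x <- randomTable(30, 7, seed = 11)
  d <- brayCurtis(x)
  ours <- pcoaOrdination(d)
  ref <- ape::pcoa(d)
  k <- min(ncol(ours$points), ncol(ref$vectors))
  # Procrustes-free check: axis-wise match up to sign
  for (i in seq_len(k))
    expect_lt(min(sum((ours$points[, i] - ref$vectors[, i])^2),
                  sum((ours$points[, i] + ref$vectors[, i])^2)), 1e-10)
})

test_that("ANOSIM separates groups and respects the permutation floor", {
  # two tight, well-separated clusters -> all between > all within -> R = 1
  set.seed(41)
  pts <- rbind(matrix(rnorm(14, 0, 0.01), 7), matrix(rnorm(14, 9, 0.01), 7))
  d <- dist(pts)
  g <- rep(c("A", "B"), each = 7)
  a <- anosimTest(d, g, nPerm = 999, seed = 1)
  expect_equal(a$R, 1)
  expect_equal(a$p, 1 / 1000)

  expect_error(anosimTest(d, c(rep("A", 9), "B")), ">= 2 samples")

  # rank-based: invariant under monotone transform of distances
  a2 <- anosimTest(d^2, g, nPerm = 99, seed = 1)
  expect_equal(a2$R, a$R)

  # pairwise mode covers each group pair
  g3 <- c(rep("A", 4), rep("B", 3), rep("C", 3))
  d3 <- dist(matrix(rnorm(20), 10))
  a3 <- anosimTest(d3, g3, nPerm = 99, seed = 2, pairwise = TRUE)
  expect_equal(nrow(a3$pairwise), 3)
  expect_true(all(abs(a3$pairwise$R) <= 1))
})

test_that("group comparison reduces to known identities", {
  # equal group means with internal spread -> F = 0
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("A", "B", "C"), each = 3)
  gc0 <- groupCompare(v, g)
  expect_equal(gc0$F, 0)
  expect_equal(unname(nchar(gc0$letters)), c(1, 1, 1))
  expect_equal(length(unique(gc0$letters)), 1)

  # two groups: F equals the squared pooled t statistic
  set.seed(8)
  v2 <- c(rnorm(6), rnorm(6, 1))
  g2 <- rep(c("A", "B"), each = 6)
  gc2 <- groupCompare(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(gc2$F, unname(tt$statistic)^2)
  expect_equal(gc2$p, tt$p.value)

  # clearly separated groups get distinct letters
  v3 <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  g3 <- rep(c("A", "B", "C"), each = 5)
  expect_equal(length(unique(groupCompare(v3, g3)$letters)), 3)

  expect_error(groupCompare(rep(1, 6), rep(c("A", "B"), each = 3)),
               "within-group variance")
})
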