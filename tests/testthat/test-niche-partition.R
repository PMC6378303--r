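test_that("Levins' breadth hits its closed forms and bounds", {
  p13 <- matrix(1, 1, 13)
  expect_equal(unname(levinsBreadth(p13)), 13)
  one <- matrix(c(0, 0, 5, 0), 1, 4)
  expect_equal(unname(levinsBreadth(one)), 1)
  half <- matrix(c(0.5, 0.5, 0, 0), 1, 4)
  expect_equal(unname(levinsBreadth(half)), 2)

  # brute-force 1 / sum p^2 oracle on random profiles
  set.seed(42)
  m <- matrix(rexp(200 * 10), 200, 10)
  b <- levinsBreadth(m)
  oracle <- apply(m, 1, function(r) {
    p <- r / sum(r)
    1 / sum(p^2)
  })
  expect_lt(max(abs(b - oracle)), 1e-12)
  expect_true(all(b >= 1 - 1e-12 & b <= 10 + 1e-12))

  # absent taxon flagged NA
  expect_warning(b0 <- levinsBreadth(rbind(c(1, 1), c(0, 0))), "absent")
  expect_true(is.na(b0[2]))
})

test_that("breadth classification uses strict inequalities", {
  B <- c(a = 9.0, b = 1.2, c = 8.7, d = 1.5, e = 5)
  got <- classifyByBreadth(B, low = 1.5, high = 8.7)
  expect_equal(as.character(got),
               c("generalist", "specialist", "other", "other", "other"))
  expect_error(classifyByBreadth(B, low = 9, high = 1))
})

test_that("outlier-area thresholds follow Tukey fences (type-7 quartiles)", {
  v <- c(1, 2, 3, 4, 100)
  # direct type-7 quantile oracle: q(p) at h = (n-1) p + 1 with linear
  # interpolation
  type7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  q1 <- type7(v, 0.25); q3 <- type7(v, 0.75)
  expected_low <- max(1, q1 - 1.5 * (q3 - q1))
  expected_high <- min(5, q3 + 1.5 * (q3 - q1))
  got <- breadthOutlierThresholds(v, nHabitats = 5)
  expect_equal(unname(got), c(expected_low, expected_high))

  expect_error(breadthOutlierThresholds(rep(3, 10)), "constant")
  expect_error(breadthOutlierThresholds(c(1, 2)), "at least 5")

  # clamping: fences stay within [1, nHabitats]
  set.seed(1)
  for (i in 1:20) {
    b <- runif(30, 1, 13)
    f <- breadthOutlierThresholds(b, nHabitats = 13)
    expect_gte(f[["low"]], 1)
    expect_lte(f[["high"]], 13)
  }
})

test_that("INDVAL matches its closed forms", {
  g <- rep(c("A", "B", "C"), each = 4)
  # perfect indicator of group A
  m <- rbind(perfect = c(rep(5, 4), rep(0, 8)),
             flat = rep(7, 12),
             absent = rep(0, 12))
  iv <- indicatorValue(makeTable(m), g, nPerm = 199, seed = 1)
  expect_equal(iv["perfect", "indval"], 1)
  # identical abundance in every sample over g groups -> 1/g
  expect_equal(iv["flat", "indval"], 1 / 3)
  expect_equal(iv["absent", "indval"], 0)
  expect_equal(iv["absent", "p"], 1)

  # minimum achievable p with nPerm = 999 (design large enough that no
  # permutation reproduces the perfect indicator)
  g21 <- rep(c("A", "B", "C"), each = 7)
  m21 <- matrix(c(rep(5, 7), rep(0, 14)), 1, 21,
                dimnames = list("perfect", paste0("s", 1:21)))
  iv999 <- indicatorValue(m21, g21, nPerm = 999, seed = 2)
  expect_equal(min(iv999$p), 1 / 1000)
  expect_true(all(iv$p >= 1 / 200))  # floor at nPerm = 199

  # scale invariance: multiplying one taxon's counts by a constant
  m2 <- m; m2[1, ] <- m2[1, ] * 17
  iv2 <- indicatorValue(makeTable(m2), g, nPerm = 199, seed = 1)
  expect_equal(iv2$indval, iv$indval)

  expect_error(indicatorValue(makeTable(m), rep("A", 12)), "2 groups")
})

test_that("strict specialists require significant IndVal > 0.3", {
  cat_ <- factor(c(x1 = "specialist", x2 = "specialist",
                   x3 = "generalist"),
                 levels = c("generalist", "specialist", "other"))
  names(cat_) <- c("x1", "x2", "x3")
  iv <- data.frame(taxon = c("x1", "x2", "x3"),
                   indval = c(0.5, 0.2, 0.9),
                   p = c(0.01, 0.001, 0.001))
  got <- strictSpecialists(cat_, iv)
  expect_equal(got, "x1")    # x2 fails indval, x3 is not a specialist
})

test_that("nichePartition wrapper produces a coherent partition", {
  x <- simulateMetacommunity(smallConfig(), seed = 12)
  xf <- filterRare(x)
  part <- nichePartition(xf, groups = sampleData(xf)$gradient,
                         nPerm = 99, seed = 1)
  expect_s4_class(part, "NichePartition")
  expect_setequal(part@taxa, rownames(xf))
  expect_true(all(taxonBreadth(part) >= 1 &
                  taxonBreadth(part) <= ncol(xf) + 1e-9))
  expect_true(all(strictSpecialistIds(part) %in%
                  names(taxonCategory(part))[taxonCategory(part) ==
                                             "specialist"]))
  # subcommunities partition the taxa exactly
  subs <- subcommunities(xf, part)
  ids <- c(rownames(subs$generalist), rownames(subs$specialist),
           rownames(subs$other))
  expect_setequal(ids, rownames(subs$all))
  expect_equal(length(ids), nrow(subs$all))

  # auto thresholds come from the outlier area and are used verbatim
  part2 <- nichePartition(xf, autoThresholds = TRUE, runIndval = FALSE)
  expect_equal(unname(nicheThresholds(part2)),
               unname(breadthOutlierThresholds(levinsBreadth(xf),
                                               nHabitats = ncol(xf))))
})
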