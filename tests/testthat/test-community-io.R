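test_that("TSV OTU tables round-trip bit-identically and validate", {
  m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
              dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
  x <- OTUExperiment(m)
  f <- tempfile(fileext = ".tsv")
  writeOtuTable(x, f)
  y <- readOtuTable(f)
  expect_identical(otuCounts(y), otuCounts(x) * 1.0)
  f2 <- tempfile(fileext = ".tsv")
  writeOtuTable(y, f2)
  expect_identical(readLines(f), readLines(f2))

  # all-zero taxon is retained on read; filtering is explicit
  m0 <- rbind(m, OTU3 = c(0L, 0L))
  writeOtuTable(OTUExperiment(m0), f)
  expect_equal(nrow(readOtuTable(f)), 3)

  # negative and non-numeric cells error with the offending location
  writeLines(c("#OTU_ID\tS1\tS2", "OTU1\t3\t0", "OTU2\t-1\t2"), f)
  expect_error(readOtuTable(f), "OTU2")
  writeLines(c("#OTU_ID\tS1\tS2", "OTU1\t3\tx", "OTU2\t1\t2"), f)
  expect_error(readOtuTable(f), "S2")
  writeLines(c("#OTU_ID\tS1\tS2", "OTU1\t3\t0", "OTU1\t1\t2"), f)
  expect_error(readOtuTable(f), "duplicate")
})

test_that("OTUExperiment validity catches bad counts", {
  expect_error(OTUExperiment(matrix(-1, 2, 2)), "negative")
  expect_error(OTUExperiment(matrix(1.5, 2, 2)), "integer")
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("S1", "S2")))
  expect_error(OTUExperiment(m), "unique")
})

test_that("relative abundances column-normalize exactly", {
  x <- makeTable(cbind(c(2, 2), c(1, 0)))
  p <- relativeAbundances(x)
  expect_equal(p[, 1], c(OTU1 = 0.5, OTU2 = 0.5))
  expect_equal(p[, 2], c(OTU1 = 1, OTU2 = 0))

  set.seed(7)
  big <- makeTable(matrix(rpois(500, 3) + 1, 50, 10))
  expect_true(all(abs(colSums(relativeAbundances(big)) - 1) < 1e-12))

  bad <- makeTable(cbind(S1 = c(1, 2), S2 = c(0, 0)))
  expect_error(relativeAbundances(bad), "S2")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  x <- makeTable(cbind(S1 = c(30, 70), S2 = c(10, 10)))
  # depth equal to a sample's total leaves it unchanged
  r <- rarefyCounts(x, depth = 20, seed = 1,
                    dropBelowDepth = TRUE)
  expect_equal(unname(otuCounts(r)[, "S2"]), c(10, 10))
  expect_equal(unname(colSums(otuCounts(r))), c(20, 20))

  # depth 1 forces a single read
  r1 <- rarefyCounts(x, depth = 1, seed = 2)
  expect_true(all(colSums(otuCounts(r1)) == 1))
  expect_true(all(colSums(otuCounts(r1) > 0) == 1))

  # hypergeometric-mean oracle: sample (8000, 2000) to 1000 reads
  x2 <- makeTable(cbind(S1 = c(8000, 2000)))
  draws <- vapply(1:500, function(s)
    otuCounts(rarefyCounts(x2, 1000, seed = s))[1, 1], numeric(1))
  sd_hyper <- sqrt(1000 * 0.8 * 0.2 * (10000 - 1000) / (10000 - 1))
  expect_lt(abs(mean(draws) - 800), 3 * sd_hyper / sqrt(500))

  # shallow samples drop with warning, or error on request
  expect_warning(r2 <- rarefyCounts(x, depth = 50, seed = 1), "S2")
  expect_equal(colnames(r2), "S1")
  expect_error(rarefyCounts(x, depth = 50, dropBelowDepth = FALSE), "S2")
  expect_error(rarefyCounts(x, depth = 1e6), "all samples")

  # taxon identity set preserved; reproducible under seed
  expect_identical(rownames(r), rownames(x))
  expect_identical(otuCounts(rarefyCounts(x, 20, seed = 9)),
                   otuCounts(rarefyCounts(x, 20, seed = 9)))
})

test_that("rare-taxon filter removes strictly-below-threshold taxa", {
  # taxon exactly at threshold is retained
  m <- rbind(rare = c(1, 1), common = c(49999, 49999))
  colnames(m) <- c("S1", "S2")
  x <- OTUExperiment(m)
  thr <- mean(relativeAbundances(x)["rare", ])  # exactly its own mean
  f <- filterRare(x, threshold = thr)
  expect_true("rare" %in% rownames(f))
  f2 <- filterRare(x, threshold = thr * (1 + 1e-9))
  expect_false("rare" %in% rownames(f2))
  expect_identical(S4Vectors::metadata(f2)$removed_taxa, "rare")

  # all-zero taxon always removed
  x0 <- makeTable(rbind(c(5, 5), c(0, 0)))
  expect_false("OTU2" %in% rownames(filterRare(x0)))

  # constructed 3764-taxon fixture: 956 taxa below 2e-5, 2808 retained
  nrare <- 956; ncommon <- 2808; nsamp <- 13
  m <- matrix(0, nrare + ncommon, nsamp)
  for (i in seq_len(nrare)) m[i, 1 + (i %% nsamp)] <- 1
  m[(nrare + 1):(nrare + ncommon), ] <- 100
  big <- makeTable(m)
  # brute-force mean relative abundance oracle
  p <- sweep(m, 2, colSums(m), "/")
  expect_equal(sum(rowMeans(p) < 2e-5), nrare)
  fb <- filterRare(big, 2e-5)
  expect_equal(nrow(fb), ncommon)

  # idempotent
  expect_equal(nrow(filterRare(fb, 2e-5)), nrow(fb))
})

test_that("rarefied relative abundances stay normalized", {
  x <- randomTable(40, 6, lambda = 50, seed = 3)
  r <- rarefyCounts(x, depth = min(colSums(otuCounts(x))), seed = 4)
  expect_true(all(abs(colSums(relativeAbundances(r)) - 1) < 1e-12))
})

test_that("metadata reading and attachment enforce the sample join", {
  md <- data.frame(sample_id = c("S1", "S2"), elevation_m = c(100, 200),
                   x_m = c(0, 10), y_m = c(0, 0),
                   gradient = c("LEG", "HEG"), pH = c(6, 7))
  f <- tempfile()
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readSampleMetadata(f)
  expect_equal(got$elevation_m, c(100, 200))

  x <- makeTable(matrix(1:6, 2, 3))  # S1..S3
  expect_error(attachMetadata(x, got), "S3")
  x2 <- makeTable(matrix(1:4, 2, 2))
  expect_equal(sampleData(attachMetadata(x2, got))$pH, c(6, 7))

  write.table(md[, -2], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleMetadata(f), "elevation_m")
})
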