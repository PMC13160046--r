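test_that("MTX directory round-trip preserves counts and metadata", {
  tc <- tinyTimeCourse(compartments = TRUE)
  dir <- withr::local_tempdir()
  writeTimeCourse(tc, dir)
  tc2 <- loadTimeCourse(dir, timepointKey = "timepoint",
                        compartmentKey = "compartment")
  expect_s4_class(tc2, "TimeCourse")
  expect_equal(length(timepoints(tc2)), 3)
  expect_equal(as.matrix(SummarizedExperiment::assay(tc2, "counts")),
               as.matrix(SummarizedExperiment::assay(tc, "counts")))
  expect_equal(tc2$timepoint, tc$timepoint)
  expect_equal(tc2$compartment, tc$compartment)
})

test_that("loading fails informatively on bad metadata", {
  tc <- tinyTimeCourse()
  dir <- withr::local_tempdir()
  writeTimeCourse(tc, dir)
  expect_error(loadTimeCourse(dir, timepointKey = "day"), "day")
  md <- read.csv(file.path(dir, "metadata.csv"))
  md$timepoint <- letters[seq_len(nrow(md))]
  write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  expect_error(loadTimeCourse(dir), "non-numeric")
  expect_error(loadTimeCourse(tempfile()), "directory")
})

test_that("cell filter applies strict thresholds and matches brute force", {
  set.seed(7)
  counts <- matrix(rpois(30 * 100, 60), 30, 100)
  rownames(counts) <- c(sprintf("g%02d", 1:28), "mt-a", "mt-b")
  colnames(counts) <- sprintf("c%03d", 1:100)
  # engineer boundary cells
  counts[, 1] <- 0; counts[1, 1] <- 1499          # below count threshold
  counts[, 2] <- 0; counts[1, 2] <- 1500          # exactly at threshold: kept
  counts[29:30, 3] <- 2000                        # mito heavy
  tc <- TimeCourse(counts, timepoint = rep(0, 100))
  out <- filterCells(tc, maxMitoFrac = 0.10, minCounts = 1500)
  expect_false("c001" %in% colnames(out))
  expect_true("c002" %in% colnames(out))
  expect_false("c003" %in% colnames(out))
  # per-cell brute-force oracle
  keep <- vapply(seq_len(ncol(counts)), function(i) {
    tot <- sum(counts[, i])
    mito <- sum(counts[29:30, i]) / tot
    tot >= 1500 && mito <= 0.10
  }, logical(1))
  expect_identical(colnames(out), colnames(counts)[keep])
  # all-pass input returns identical object
  clean <- TimeCourse(matrix(200, 10, 5,
                             dimnames = list(sprintf("g%d", 1:10),
                                             sprintf("c%d", 1:5))),
                      timepoint = rep(0, 5))
  expect_identical(colnames(filterCells(clean)), colnames(clean))
  expect_error(filterCells(normalizeLog1p(clean)), "normalized")
})

test_that("gene filter keeps genes detected in >= minCells cells", {
  counts <- matrix(0, 4, 6)
  counts[1, 1] <- 5                # 1 cell: removed
  counts[2, 1:2] <- 5              # 2 cells: kept
  counts[3, ] <- 3                 # all cells: kept
  counts[4, 3] <- 1                # 1 cell: removed
  rownames(counts) <- sprintf("g%d", 1:4)
  colnames(counts) <- sprintf("c%d", 1:6)
  tc <- TimeCourse(counts, timepoint = rep(c(0, 1), each = 3))
  out <- filterGenes(tc, minCells = 2)
  expect_identical(rownames(out), c("g2", "g3"))
  # random sparse fixture vs column-sum oracle
  set.seed(11)
  sp <- matrix(rbinom(50 * 20, 1, 0.1) * rpois(50 * 20, 3), 50, 20)
  rownames(sp) <- sprintf("r%02d", 1:50); colnames(sp) <- sprintf("c%02d", 1:20)
  tc2 <- TimeCourse(sp, timepoint = rep(0, 20))
  expect_identical(rownames(filterGenes(tc2, 2)),
                   rownames(sp)[rowSums(sp > 0) >= 2])
})

test_that("normalization scales to target sum then log1p, and is guarded", {
  counts <- matrix(c(1, 3), 2, 1,
                   dimnames = list(c("a", "b"), "c1"))
  tc <- TimeCourse(counts, timepoint = 0)
  out <- normalizeLog1p(tc, targetSum = 4)
  expect_equal(as.numeric(SummarizedExperiment::assay(out, "logcounts")),
               c(log(2), log(4)))
  expect_true(isNormalized(out))
  expect_error(normalizeLog1p(out), "already")
  # row sums of expm1 equal target sum
  tc2 <- tinyTimeCourse()
  n2 <- normalizeLog1p(tc2, 1e6)
  back <- expm1(as.matrix(SummarizedExperiment::assay(n2, "logcounts")))
  expect_lt(max(abs(colSums(back) - 1e6)) / 1e6, 1e-6)
  # zero-count cell errors
  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  z[1, 1] <- 5
  expect_error(normalizeLog1p(TimeCourse(z, c(0, 0))), "zero total")
})

test_that("HVG ranking prefers planted variable genes, never constants", {
  set.seed(5)
  n <- 60
  gmu <- 10^runif(80, 0.4, 2)     # background means span two decades
  counts <- matrix(rpois(80 * n, rep(gmu, n)), 80, n)
  # planted overdispersed genes: Poisson background is the trend, these are
  # bimodal across cells at mid-range means
  counts[1:5, ] <- rpois(5 * n, 30) *
    rep(sample(c(0, 2), n, replace = TRUE), each = 5)
  counts[6, ] <- 7                                       # constant gene
  rownames(counts) <- sprintf("g%02d", 1:80)
  colnames(counts) <- sprintf("c%02d", 1:n)
  tc <- normalizeLog1p(TimeCourse(counts, rep(0, n)))
  top <- selectHVG(tc, 10)
  expect_true(all(sprintf("g%02d", 1:5) %in% top))
  expect_false("g06" %in% top)
  expect_warning(all80 <- selectHVG(tc, 100), "all genes")
  expect_equal(length(all80), 80)
})

test_that("PCA basis is exact on low-rank data with a clean eigen-spectrum", {
  set.seed(3)
  W <- matrix(rnorm(40 * 3), 40, 3) %*% matrix(rnorm(3 * 25), 3, 25)
  counts <- matrix(rpois(25 * 40, 30), 25, 40)   # genes x cells
  rownames(counts) <- sprintf("g%02d", 1:25)
  colnames(counts) <- sprintf("c%02d", 1:40)
  tc <- normalizeLog1p(TimeCourse(counts, rep(c(0, 1), each = 20)))
  b <- fitBasis(tc, "global_pca", nComponents = 10)
  expect_equal(b@nComponents, 10L)
  expect_true(all(diff(b@sdev) <= 1e-8))        # nonincreasing spectrum
  # reconstruction is exact when all components are kept
  bf <- fitBasis(tc, "global_pca", nComponents = 25)
  X <- t(as.matrix(SummarizedExperiment::assay(tc, "logcounts")))
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(bf@coords %*% t(bf@rotation) - Xc)), 1e-8)
  expect_error(fitBasis(tc, "global_pca", nComponents = 100), "exceeds")
  expect_error(fitBasis(tc, "local_pca", nComponents = 5), "timepointPair")
  bl <- fitBasis(tc, "local_pca", nComponents = 5, timepointPair = c(0, 1))
  expect_equal(nrow(bl@coords), 40)
  # determinism
  b2 <- fitBasis(tc, "global_pca", nComponents = 10)
  expect_identical(b@coords, b2@coords)
})
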