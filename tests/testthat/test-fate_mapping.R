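test_that("barycentric projection is an exact conditional expectation", {
  X <- matrix(rnorm(12), 4, 3)
  idm <- new("RowStochasticMap", P = diag(4),
             sourceIds = sprintf("s%d", 1:4), targetIds = sprintf("t%d", 1:4),
             sourceTime = 0, targetTime = 1, provenance = "direct")
  expect_equal(unname(barycentricProject(idm, X)), X)
  unif <- randomStochasticMap(3, 4, seed = 1)
  unif@P[] <- 1 / 4
  proj <- barycentricProject(unif, X)
  expect_equal(unname(proj), matrix(colMeans(X), 3, 3, byrow = TRUE))
  # brute-force double-loop expectation oracle
  rsm <- randomStochasticMap(5, 4, seed = 2)
  proj <- barycentricProject(rsm, X)
  oracle <- matrix(0, 5, 3)
  for (i in 1:5) for (k in 1:3)
    oracle[i, k] <- sum(rsm@P[i, ] * X[, k])
  expect_lt(max(abs(proj - oracle)), 1e-10)
  # convexity: projected values within the target range per dimension
  expect_true(all(proj <= rep(apply(X, 2, max), each = 5) + 1e-12))
  expect_true(all(proj >= rep(apply(X, 2, min), each = 5) - 1e-12))
  expect_error(barycentricProject(rsm, X[1:3, ]), "target cells")
})

test_that("expression projection matches column extraction of the full projection", {
  tc <- normalizeLog1p(tinyTimeCourse(nGenes = 15, cellsPerDay = 8,
                                      days = c(0, 1)))
  tgt <- colnames(tc)[tc$timepoint == 1]
  rsm <- randomStochasticMap(8, 8, seed = 3)
  rsm@targetIds <- tgt
  pe <- projectExpression(rsm, tc, c("g03", "g07"))
  full <- barycentricProject(
    rsm, t(as.matrix(SummarizedExperiment::assay(tc, "logcounts")[, tgt])))
  expect_equal(pe, full[, c("g03", "g07")])
  expect_error(projectExpression(rsm, tc, "nope"), "unknown gene")
})

test_that("trajectory correlations separate self, null and constant cases", {
  set.seed(41)
  n <- 200
  third <- matrix(rpois(30 * n, 25), 30, n)
  counts <- cbind(third, third, third)  # later snapshots duplicate the first
  rownames(counts) <- sprintf("g%02d", 1:30)
  colnames(counts) <- sprintf("c%03d", seq_len(3 * n))
  counts[30, ] <- 0       # constant (zero) gene at every timepoint
  tc <- normalizeLog1p(TimeCourse(counts, rep(c(0, 1, 2), each = n)))
  cells <- split(colnames(tc), tc$timepoint)
  mkMap <- function(P, s, t) {
    dimnames(P) <- list(cells[[as.character(s)]], cells[[as.character(t)]])
    asTransportMap(P, s, t)
  }
  idMaps <- list("0->1" = mkMap(diag(n), 0, 1), "1->2" = mkMap(diag(n), 1, 2))
  res <- trajectoryGeneCorrelations(tc, idMaps)
  expect_true(all(abs(res$median[sprintf("g%02d", 1:29)] - 1) < 1e-12))
  expect_true(all(is.na(res$rho["g30", ])))   # constant columns excluded
  expect_true(is.na(res$median[["g30"]]))     # never zero-filled
  # permuted couplings on iid genes give near-zero medians
  set.seed(42)
  permMaps <- list("0->1" = mkMap(diag(n)[sample(n), ], 0, 1),
                   "1->2" = mkMap(diag(n)[sample(n), ], 1, 2))
  resp <- trajectoryGeneCorrelations(tc, permMaps)
  expect_lt(max(abs(resp$median), na.rm = TRUE), 0.2)
  # invariance under strictly monotone transforms of the expression scale
  X <- SummarizedExperiment::assay(tc, "logcounts")
  SummarizedExperiment::assay(tc, "logcounts") <- exp(X / 3)
  resm <- trajectoryGeneCorrelations(tc, permMaps)
  expect_equal(resp$rho[1:29, ], resm$rho[1:29, ], tolerance = 1e-10)
})

test_that("fate propensities and entropy match direct computation", {
  rsm <- randomStochasticMap(6, 9, seed = 5)
  labels <- rep(c("a", "b", "c"), each = 3)
  fp <- fatePropensities(rsm, labels)
  expect_lt(max(abs(rowSums(fp$Q) - 1)), 1e-8)
  oracle <- sapply(seq_len(6), function(i) {
    q <- tapply(rsm@P[i, ], labels, sum)
    -sum(ifelse(q > 0, q * log(q), 0))
  })
  expect_lt(max(abs(fp$entropy - oracle)), 1e-12)
  expect_true(all(fp$entropy >= 0 & fp$entropy <= log(3) + 1e-12))
  # deterministic fate: one-hot rows, zero entropy
  det <- rsm; det@P[] <- 0; det@P[, 1] <- 1
  fpd <- fatePropensities(det, labels)
  expect_equal(unname(fpd$entropy), rep(0, 6))
  # uniform over k equal clusters: maximum entropy log k
  unif <- rsm; unif@P[] <- 1 / 9
  expect_equal(unname(fatePropensities(unif, labels)$entropy),
               rep(log(3), 6), tolerance = 1e-12)
  expect_error(fatePropensities(rsm, c(labels[-1], NA)), "labels")
})

test_that("consistency is calibrated at 0 for product and 1 for lossless flows", {
  set.seed(6)
  b <- runif(8); b <- b / sum(b)
  P <- outer(rep(1 / 5, 5), b)          # product coupling
  rsm <- rowNormalize(asTransportMap(P))
  labels <- rep(c("x", "y"), each = 4)
  fp <- fatePropensities(rsm, labels)
  freqs <- tapply(b, labels, sum)
  cons <- fateConsistency(fp, freqs)
  expect_lt(abs(cons$mean), 1e-10)
  # cluster-preserving deterministic coupling
  det <- diag(8)
  fpd <- fatePropensities(rowNormalize(asTransportMap(det)), labels)
  consd <- fateConsistency(fpd, rep(0.5, 2))
  expect_identical(consd$mean, 1)
  # anti-concentrated coupling on unequal clusters goes negative: every
  # cell's propensity is (1/2, 1/2) over clusters with frequencies (7/8, 1/8)
  lab2 <- c(rep("big", 7), "small")
  anti <- matrix(0.5 / 7, 8, 8); anti[, 8] <- 0.5
  fpa <- fatePropensities(rowNormalize(asTransportMap(anti)), lab2)
  consa <- fateConsistency(fpa, c(big = 7 / 8, small = 1 / 8))
  expect_lt(consa$mean, 0)
  expect_true(consa$mean <= 1)
  one <- fatePropensities(rowNormalize(asTransportMap(det)), rep("a", 8))
  expect_error(fateConsistency(one, c(a = 1)), "undefined")
})

test_that("egress probabilities count exactly the cross-compartment mass", {
  rsm <- randomStochasticMap(4, 6, seed = 7)
  sc <- c("spleen", "spleen", "siIEL", "siIEL")
  tcmp <- c(rep("spleen", 3), rep("siIEL", 3))
  eg <- egressProbabilities(rsm, sc, tcmp)
  oracle <- c(sum(rsm@P[1, 4:6]), sum(rsm@P[2, 4:6]),
              sum(rsm@P[3, 1:3]), sum(rsm@P[4, 1:3]))
  expect_equal(eg$egress, oracle)
  # within-compartment-only coupling: zero egress; cross-only: one
  within <- rsm; within@P[] <- 0
  within@P[1:2, 1:3] <- 1 / 3; within@P[3:4, 4:6] <- 1 / 3
  expect_equal(egressProbabilities(within, sc, tcmp)$egress, rep(0, 4))
  cross <- rsm; cross@P[] <- 0
  cross@P[1:2, 4:6] <- 1 / 3; cross@P[3:4, 1:3] <- 1 / 3
  expect_equal(egressProbabilities(cross, sc, tcmp)$egress, rep(1, 4))
  expect_error(egressProbabilities(rsm, sc[1:2], tcmp), "align")
})

test_that("backward membership equals a brute-force path enumeration", {
  # 3 timepoints with 3, 2, 2 cells and hand-built couplings
  set.seed(8)
  P1 <- matrix(runif(6, 0.1, 1), 3, 2)
  dimnames(P1) <- list(paste0("a", 1:3), paste0("b", 1:2))
  P2 <- matrix(runif(4, 0.1, 1), 2, 2)
  dimnames(P2) <- list(paste0("b", 1:2), paste0("c", 1:2))
  maps <- list("0->1" = asTransportMap(P1, 0, 1),
               "1->2" = asTransportMap(P2, 1, 2))
  comps <- c(a1 = "T", a2 = "S", a3 = "T", b1 = "T", b2 = "S",
             c1 = "T", c2 = "T")
  arr <- arrivalTimes(maps, comps, 2, "T")
  memb <- attr(arr, "membership")
  # brute force: backward transitions are transposed-then-normalized steps
  B2 <- t(P2) / rowSums(t(P2))         # c -> b
  B1 <- t(P1) / rowSums(t(P1))         # b -> a
  q1 <- B2 %*% as.numeric(comps[c("b1", "b2")] == "T")
  q0 <- (B2 %*% B1 / rowSums(B2 %*% B1)) %*%
    as.numeric(comps[c("a1", "a2", "a3")] == "T")
  expect_equal(unname(memb[, "1"]), as.numeric(q1), tolerance = 1e-12)
  expect_equal(unname(memb[, "0"]), as.numeric(q0), tolerance = 1e-12)
  expect_true(all(memb >= 0 & memb <= 1))
  expect_true(all(arr$arrival >= 0 & arr$arrival <= 2))
})

test_that("arrival times degenerate correctly on step-function membership", {
  # backward chain fully inside the tissue from t0 onward: arrival = t0
  mkDet <- function(s, t, n, src, tgt) {
    P <- diag(n); dimnames(P) <- list(src, tgt)
    asTransportMap(P, s, t)
  }
  src0 <- paste0("x", 1:2); src1 <- paste0("y", 1:2); src2 <- paste0("z", 1:2)
  maps <- list("0->1" = mkDet(0, 1, 2, src0, src1),
               "1->2" = mkDet(1, 2, 2, src1, src2))
  compsIn <- setNames(rep("T", 6), c(src0, src1, src2))
  arr <- arrivalTimes(maps, compsIn, 2, "T")
  expect_equal(arr$arrival, rep(0, 2))
  # single-step entry at the final interval: arrival = last pre-query timepoint
  compsLate <- setNames(c("S", "S", "S", "S", "T", "T"),
                        c(src0, src1, src2))
  arr2 <- arrivalTimes(maps, compsLate, 2, "T")
  expect_equal(arr2$arrival, rep(1, 2))
  expect_error(arrivalTimes(maps, compsLate, 2, "Q"), "no query cells")
})
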