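test_that("cost matrix reproduces closed forms and a brute-force oracle", {
  expect_equal(costMatrix(matrix(1, 1, 1), matrix(1, 1, 1)),
               matrix(0, 1, 1), ignore_attr = TRUE)
  expect_equal(as.numeric(costMatrix(matrix(0, 1, 1), matrix(c(3, 4), 2, 1))),
               c(3, 4))
  set.seed(2)
  A <- matrix(rnorm(5 * 4), 5, 4); B <- matrix(rnorm(7 * 4), 7, 4)
  D <- costMatrix(A, B)
  oracle <- matrix(0, 5, 7)
  for (i in 1:5) for (j in 1:7) oracle[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  expect_lt(max(abs(D - oracle)), 1e-10)
  expect_error(costMatrix(A, matrix(0, 3, 5)), "mismatch")
})

test_that("Sinkhorn solves degenerate and zero-cost cases exactly", {
  tm <- solveUOT(matrix(2.5, 1, 1), 1, 1, solverConfig(1, 1, 1))
  expect_equal(as.numeric(coupling(tm)), 1, tolerance = 1e-8)
  # zero cost, balanced uniform: independence coupling a b^T
  a <- rep(1 / 4, 4); b <- rep(1 / 6, 6)
  tm <- solveUOT(matrix(0, 4, 6), a, b, solverConfig(0.5, 1, 1))
  expect_lt(max(abs(coupling(tm) - outer(a, b))), 1e-10)
  # large epsilon approaches the independence coupling on any cost
  set.seed(4)
  C <- matrix(runif(12), 3, 4)
  a <- rep(1 / 3, 3); b <- rep(1 / 4, 4)
  tm <- solveUOT(C, a, b, solverConfig(1e6, 1, 1, tol = 1e-10))
  expect_lt(max(abs(coupling(tm) - outer(a, b))), 1e-6)
})

test_that("balanced Sinkhorn matches the exact LP oracle within 1%", {
  skip_if_not_installed("boot")
  set.seed(10)
  for (rep in 1:5) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    C <- matrix(runif(m * n), m, n)
    a <- runif(m); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    tm <- solveUOT(C, a, b, solverConfig(1e-3, 1, 1, maxIters = 2e5,
                                         tol = 1e-9))
    # transportation LP via simplex: min c'x, row/col sum constraints
    A3 <- rbind(t(sapply(seq_len(m), function(i)
             as.numeric(rep(seq_len(m), n) == i))),
           t(sapply(seq_len(n), function(j)
             as.numeric(rep(seq_len(n), each = m) == j))))
    lp <- boot::simplex(a = as.vector(C), A3 = A3[-(m + n), ],
                        b3 = c(a, b)[-(m + n)], maxi = FALSE)
    expect_lt(abs(tm@cost - lp$value) / max(lp$value, 1e-12), 0.01)
    P <- coupling(tm)
    expect_lt(max(abs(rowSums(P) - a)), 1e-6)
    expect_lt(max(abs(colSums(P) - b)), 1e-6)
  }
})

test_that("couplings are deterministic, nonnegative and finite", {
  set.seed(6)
  C <- matrix(runif(20), 4, 5)
  a <- rep(0.25, 4); b <- rep(0.2, 5)
  t1 <- solveUOT(C, a, b, solverConfig(0.05, 0.9, 0.9))
  t2 <- solveUOT(C, a, b, solverConfig(0.05, 0.9, 0.9))
  expect_identical(coupling(t1), coupling(t2))
  expect_true(all(coupling(t1) >= 0), all(is.finite(coupling(t1))))
})

test_that("marginal deviation shrinks monotonically as tau approaches 1", {
  set.seed(8)
  C <- matrix(runif(36), 6, 6)
  a <- runif(6); a <- a / sum(a); b <- runif(6); b <- b / sum(b)
  dev <- sapply(c(0.9, 0.99, 0.999), function(tau) {
    P <- coupling(solveUOT(C, a, b, solverConfig(0.05, tau, tau,
                                                 tol = 1e-10)))
    sum(abs(rowSums(P) - a)) + sum(abs(colSums(P) - b))
  })
  expect_true(all(diff(dev) < 0))
})

test_that("row normalization, transposition and chaining obey their algebra", {
  expect_equal(transitionMatrix(rowNormalize(asTransportMap(
    matrix(c(2, 2), 1, 2)))), matrix(0.5, 1, 2), ignore_attr = TRUE)
  set.seed(12)
  P <- matrix(runif(30, 0.1, 1), 5, 6)
  rsm <- rowNormalize(asTransportMap(P))
  expect_lt(max(abs(rowSums(transitionMatrix(rsm)) - 1)), 1e-12)
  # already-stochastic input is unchanged
  S <- matrix(runif(12), 3, 4); S <- S / rowSums(S)
  expect_equal(transitionMatrix(rowNormalize(asTransportMap(S))), S,
               ignore_attr = TRUE)
  # zero row errors with the cell named
  Pz <- P; Pz[2, ] <- 0
  expect_error(rowNormalize(asTransportMap(Pz)), "s2")
  # transpose rule: shape, stochasticity, involution on positive couplings
  tmap <- transposeMap(asTransportMap(P))
  expect_equal(dim(transitionMatrix(tmap)), c(6L, 5L))
  expect_lt(max(abs(rowSums(transitionMatrix(tmap)) - 1)), 1e-12)
  # transposing the transposed raw coupling recovers the original
  # row-normalized map on strictly positive couplings
  back <- transitionMatrix(transposeMap(asTransportMap(t(P))))
  expect_lt(max(abs(back - transitionMatrix(rowNormalize(
    asTransportMap(P))))), 1e-10)
  Pc <- P; Pc[, 3] <- 0
  expect_error(transposeMap(asTransportMap(Pc)), "zero")
  # symmetric coupling: transpose equals itself pre-normalization
  Sy <- crossprod(matrix(runif(16), 4, 4))
  expect_equal(t(Sy), Sy)
  # chaining: identity, stochasticity, associativity
  m1 <- randomStochasticMap(4, 5, seed = 1)
  id <- new("RowStochasticMap", P = diag(5),
            sourceIds = m1@targetIds, targetIds = m1@targetIds,
            sourceTime = 1, targetTime = 1, provenance = "direct")
  expect_equal(transitionMatrix(chainMaps(m1, id)), transitionMatrix(m1),
               ignore_attr = TRUE)
  m2 <- randomStochasticMap(5, 3, seed = 2, s = 1, t = 2)
  m3 <- randomStochasticMap(3, 6, seed = 3, s = 2, t = 3)
  left <- transitionMatrix(chainMaps(chainMaps(m1, m2), m3))
  right <- transitionMatrix(chainMaps(m1, chainMaps(m2, m3)))
  expect_lt(max(abs(left - right)), 1e-10)
  expect_lt(max(abs(rowSums(left) - 1)), 1e-10)
  expect_error(chainMaps(m1, m3), "disagree")
})

test_that("time-course fitting produces one map per adjacent pair", {
  tc <- normalizeLog1p(tinyTimeCourse(nGenes = 30, cellsPerDay = 15,
                                      days = c(0, 2)))
  maps <- fitTimecourseMaps(tc, nComponents = 5)
  expect_length(maps, 1)
  expect_s4_class(maps[[1]], "TransportMap")
  expect_error(fitTimecourseMaps(tc, nComponents = 20), "smaller local PCA")
})

test_that("balanced coupling recovers a planted drift direction", {
  set.seed(21)
  n <- 80; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  drift <- c(3, 0, 0, 0, 0)
  Y <- X + matrix(drift, n, d, byrow = TRUE) + matrix(rnorm(n * d, 0, 0.2), n, d)
  C <- costMatrix(X, Y)
  tm <- solveUOT(C, rep(1 / n, n), rep(1 / n, n),
                 solverConfig(0.05, 1, 1, scaleCost = TRUE))
  rsm <- rowNormalize(tm)
  disp <- colMeans(barycentricProject(rsm, Y) - X)
  cosine <- sum(disp * drift) / sqrt(sum(disp^2) * sum(drift^2))
  expect_gt(cosine, 0.9)
})
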