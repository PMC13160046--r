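#' Pairwise Euclidean cost matrix
#'
#' Exact pairwise Euclidean distances between two coordinate sets (rows are
#' cells), typically 50-component local-PCA coordinates of the two timepoints
#' being coupled.
#'
#' @param sourceCoords m x d matrix.
#' @param targetCoords n x d matrix (same d).
#' @return m x n nonnegative distance matrix.
#' @export
costMatrix <- function(sourceCoords, targetCoords) {
  sourceCoords <- as.matrix(sourceCoords)
  targetCoords <- as.matrix(targetCoords)
  if (ncol(sourceCoords) != ncol(targetCoords))
    stop("coordinate dimensionality mismatch: ", ncol(sourceCoords), " vs ",
         ncol(targetCoords))
  s2 <- rowSums(sourceCoords^2)
  t2 <- rowSums(targetCoords^2)
  d2 <- outer(s2, t2, "+") - 2 * tcrossprod(sourceCoords, targetCoords)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  dimnames(D) <- list(rownames(sourceCoords), rownames(targetCoords))
  D
}

#' Sinkhorn solver configuration
#'
#' Bundles the entropic regularization strength and the unbalancedness
#' parameters. The soft-marginal weights are \code{lambda = epsilon * tau /
#' (1 - tau)}; \code{tau = 1} makes that side's marginal constraint hard
#' (balanced).
#'
#' @param epsilon entropic regularization (> 0).
#' @param tauA,tauB unbalancedness in (0, 1]; defaults are the
#'   single-compartment presets.
#' @param maxIters iteration budget.
#' @param tol convergence tolerance on marginal residuals (balanced sides)
#'   or dual-potential change (unbalanced sides).
#' @param scaleCost divide the cost matrix by its mean before solving
#'   (reported costs stay on the original scale). Off by default so the
#'   standard epsilon presets act on raw local-PCA distances.
#' @return A list of class "SolverConfig".
#' @export
solverConfig <- function(epsilon = 0.01, tauA = 0.95, tauB = 0.9995,
                         maxIters = 10000L, tol = 1e-6, scaleCost = FALSE) {
  stopifnot(epsilon > 0, tauA > 0, tauA <= 1, tauB > 0, tauB <= 1, tol > 0)
  structure(list(epsilon = epsilon, tauA = tauA, tauB = tauB,
                 maxIters = as.integer(maxIters), tol = tol,
                 scaleCost = isTRUE(scaleCost)),
            class = "SolverConfig")
}

#' Solve entropic unbalanced optimal transport
#'
#' Log-domain Sinkhorn iterations for the objective
#' \deqn{\min_{P \ge 0} \langle P, C\rangle - \epsilon H(P)
#'   + \lambda_a KL(P 1 \| a) + \lambda_b KL(P^\top 1 \| b)}
#' with \eqn{\tau = \lambda / (\lambda + \epsilon)}. Zero-mass prior entries
#' are dropped before solving and restored as zero rows/columns.
#'
#' @param C m x n finite cost matrix.
#' @param a,b nonnegative prior marginals with positive total mass.
#' @param config a \code{\link{solverConfig}}.
#' @param sourceTime,targetTime timepoints (days) recorded on the result.
#' @return A \linkS4class{TransportMap}. Non-convergence within the budget is
#'   flagged and warned about, never silent.
#' @export
solveUOT <- function(C, a, b, config = solverConfig(),
                     sourceTime = 0, targetTime = 1) {
  C <- as.matrix(C)
  if (any(!is.finite(C))) stop("cost matrix must be finite")
  if (length(a) != nrow(C) || length(b) != ncol(C))
    stop("marginal lengths must match cost dimensions")
  if (any(a < 0) || any(b < 0) || sum(a) <= 0 || sum(b) <= 0)
    stop("marginals must be nonnegative with positive total mass")
  srcIds <- rownames(C) %||% sprintf("s%d", seq_len(nrow(C)))
  tgtIds <- colnames(C) %||% sprintf("t%d", seq_len(ncol(C)))

  ia <- which(a > 0); ib <- which(b > 0)
  Cs <- C[ia, ib, drop = FALSE]
  scale <- if (config$scaleCost) mean(Cs) else 1
  if (scale <= 0) scale <- 1
  fit <- cpp_sinkhorn_uot(Cs / scale, a[ia], b[ib], config$epsilon,
                          config$tauA, config$tauB, config$maxIters,
                          config$tol)
  if (isTRUE(fit$error))
    stop("Sinkhorn scaling produced non-finite values; ",
         "try a larger epsilon")
  if (!fit$converged)
    warning(sprintf("Sinkhorn did not converge in %d iterations (residual %.3g)",
                    config$maxIters, fit$residual))
  P <- matrix(0, nrow(C), ncol(C), dimnames = list(srcIds, tgtIds))
  P[ia, ib] <- fit$P
  new("TransportMap", coupling = P,
      sourceIds = srcIds, targetIds = tgtIds,
      sourceTime = sourceTime, targetTime = targetTime,
      a = as.numeric(a), b = as.numeric(b),
      epsilon = config$epsilon, tauA = config$tauA, tauB = config$tauB,
      converged = fit$converged, iterations = as.integer(fit$iterations),
      cost = sum(P * C), residual = fit$residual)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @describeIn coupling The raw nonnegative coupling matrix.
#' @param x a \linkS4class{TransportMap}.
#' @export
setMethod("coupling", "TransportMap", function(x) x@coupling)

#' @describeIn transitionMatrix The row-stochastic matrix.
#' @param x a \linkS4class{RowStochasticMap}.
#' @export
setMethod("transitionMatrix", "RowStochasticMap", function(x) x@P)

#' Row-normalize a coupling into per-cell transition distributions
#'
#' \eqn{\hat P = diag(P 1)^{-1} P}, so that every row sums to 1 and row i is
#' the distribution of cell i's descendants at the target timepoint.
#'
#' @param tm a \linkS4class{TransportMap}.
#' @return A \linkS4class{RowStochasticMap}.
#' @export
rowNormalize <- function(tm) {
  P <- tm@coupling
  rs <- rowSums(P)
  if (any(rs <= 0))
    stop("zero coupling row for source cell(s): ",
         paste(utils::head(tm@sourceIds[rs <= 0], 5), collapse = ", "))
  new("RowStochasticMap", P = P / rs,
      sourceIds = tm@sourceIds, targetIds = tm@targetIds,
      sourceTime = tm@sourceTime, targetTime = tm@targetTime,
      provenance = "direct")
}

#' Backward transition map via the transpose rule
#'
#' For s > t the transition map is the transpose of the raw forward coupling,
#' row-normalized afterwards: ancestors instead of descendants.
#'
#' @param tm the forward \linkS4class{TransportMap} (s < t).
#' @return A \linkS4class{RowStochasticMap} mapping t -> s.
#' @export
transposeMap <- function(tm) {
  P <- t(tm@coupling)
  rs <- rowSums(P)
  if (any(rs <= 0))
    stop("zero coupling column for target cell(s): ",
         paste(utils::head(tm@targetIds[rs <= 0], 5), collapse = ", "))
  new("RowStochasticMap", P = P / rs,
      sourceIds = tm@targetIds, targetIds = tm@sourceIds,
      sourceTime = tm@targetTime, targetTime = tm@sourceTime,
      provenance = "transposed")
}

#' Chain transition maps across non-adjacent timepoints
#'
#' Under the Markov assumption, \eqn{\hat P_{s,t} = \hat P_{s,r} \hat
#' P_{r,t}}. The product of row-stochastic matrices is row-stochastic; it is
#' re-normalized to absorb floating-point drift.
#'
#' @param m1,m2 \linkS4class{RowStochasticMap}s with matching inner cells.
#' @return A \linkS4class{RowStochasticMap} from \code{m1}'s source to
#'   \code{m2}'s target.
#' @export
chainMaps <- function(m1, m2) {
  if (ncol(m1@P) != nrow(m2@P))
    stop("inner dimensions disagree: ", ncol(m1@P), " vs ", nrow(m2@P))
  P <- m1@P %*% m2@P
  P <- P / rowSums(P)
  new("RowStochasticMap", P = P,
      sourceIds = m1@sourceIds, targetIds = m2@targetIds,
      sourceTime = m1@sourceTime, targetTime = m2@targetTime,
      provenance = "chained")
}

#' Equal-size compartment subsampling
#'
#' At every timepoint where both compartments are present, subsamples the
#' larger compartment (without replacement) to the size of the smaller, so
#' that nonconstant compartment sample sizes cannot masquerade as migration.
#'
#' @param tc a \linkS4class{TimeCourse} with compartment labels.
#' @param seed RNG seed for the subsample.
#' @return Subsampled \linkS4class{TimeCourse}.
#' @export
subsampleEqualCompartments <- function(tc, seed = 1L) {
  if (is.null(tc$compartment)) stop("TimeCourse has no compartment labels")
  set.seed(seed)
  keep <- logical(ncol(tc))
  for (tp in timepoints(tc)) {
    at <- which(tc$timepoint == tp)
    comps <- split(at, tc$compartment[at])
    if (length(comps) < 2) { keep[at] <- TRUE; next }
    nmin <- min(lengths(comps))
    for (idx in comps)
      keep[if (length(idx) > nmin) sample(idx, nmin) else idx] <- TRUE
  }
  tc[, keep]
}

#' Fit transport maps across all adjacent timepoint pairs
#'
#' For T timepoints, fits T-1 unbalanced entropic transport maps. Costs are
#' Euclidean distances in a per-pair local PCA (default 50 components)
#' restricted to the supplied HVG list; source marginals come from
#' \linkS4class{GrowthPrior}s (uniform if absent), target marginals are
#' uniform.
#'
#' @param tc a normalized \linkS4class{TimeCourse}.
#' @param priors optional named list of \linkS4class{GrowthPrior}s, one per
#'   source timepoint (names are the day values as characters).
#' @param config a \code{\link{solverConfig}}; defaults are the
#'   single-compartment presets (epsilon 0.01, tauA 0.95, tauB 0.9995). Use
#'   \code{solverConfig(0.05, 0.95, 0.95)} for multi-compartment fits after
#'   \code{\link{subsampleEqualCompartments}}.
#' @param hvg HVG list for the local bases (default all genes).
#' @param nComponents local PCA dimensionality.
#' @return Named list of \linkS4class{TransportMap}s ("s->t" day labels).
#' @note Costs are divided by their mean before solving (the epsilon/tau
#'   presets are calibrated to unit-mean costs and would otherwise not
#'   transfer across datasets); reported costs stay on the original scale.
#'   Pass a config with \code{scaleCost = FALSE} to override.
#' @export
fitTimecourseMaps <- function(tc, priors = NULL,
                              config = solverConfig(scaleCost = TRUE),
                              hvg = NULL, nComponents = 50L) {
  tps <- timepoints(tc)
  if (length(tps) < 2) stop("need at least two timepoints")
  counts <- table(factor(tc$timepoint, levels = tps))
  if (any(counts < nComponents + 1))
    stop("timepoint(s) ", paste(names(counts)[counts < nComponents + 1],
                                collapse = ", "),
         " have fewer than nComponents+1 cells; use a smaller local PCA")
  maps <- list()
  for (k in seq_len(length(tps) - 1)) {
    s <- tps[k]; t <- tps[k + 1]
    basis <- fitBasis(tc, "local_pca", nComponents = nComponents, hvg = hvg,
                      timepointPair = c(s, t))
    src <- colnames(tc)[tc$timepoint == s]
    tgt <- colnames(tc)[tc$timepoint == t]
    C <- costMatrix(basis@coords[src, , drop = FALSE],
                    basis@coords[tgt, , drop = FALSE])
    a <- rep(1 / length(src), length(src))
    key <- as.character(s)
    if (!is.null(priors) && key %in% names(priors)) {
      pr <- priors[[key]]
      if (!identical(pr@cellIds, src))
        pr_a <- pr@a[match(src, pr@cellIds)]
      else pr_a <- pr@a
      if (anyNA(pr_a)) stop("growth prior at day ", s,
                            " does not cover all source cells")
      a <- pr_a
    }
    b <- rep(1 / length(tgt), length(tgt))
    maps[[sprintf("%g->%g", s, t)]] <-
      solveUOT(C, a, b, config, sourceTime = s, targetTime = t)
  }
  maps
}
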