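#' Barycentric projection of target features
#'
#' \eqn{\tilde Y_{s\to t} = \hat P_{s,t} X_t}: each source cell's expected
#' feature vector at the target timepoint under the coupling. Every row is a
#' convex combination of target rows.
#'
#' @param rsm a \linkS4class{RowStochasticMap}.
#' @param targetFeatures n x d matrix of per-target-cell features.
#' @return m x d matrix of projected features.
#' @export
barycentricProject <- function(rsm, targetFeatures) {
  targetFeatures <- as.matrix(targetFeatures)
  if (ncol(rsm@P) != nrow(targetFeatures))
    stop("map has ", ncol(rsm@P), " target cells but features have ",
         nrow(targetFeatures), " rows")
  out <- rsm@P %*% targetFeatures
  rownames(out) <- rsm@sourceIds
  out
}

#' Predicted next-timepoint expression for named genes
#'
#' Convenience wrapper of \code{\link{barycentricProject}} restricted to
#' named genes of a normalized \linkS4class{TimeCourse}.
#'
#' @param rsm a \linkS4class{RowStochasticMap}.
#' @param tc the normalized \linkS4class{TimeCourse} holding the target
#'   cells.
#' @param genes gene ids to project.
#' @return m x length(genes) matrix of predicted expression.
#' @export
projectExpression <- function(rsm, tc, genes) {
  missing <- setdiff(genes, rownames(tc))
  if (length(missing))
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  Xt <- t(asDense(logExprs(tc[genes, rsm@targetIds])))
  barycentricProject(rsm, Xt)
}

## columnwise Spearman between two matrices with matched columns;
## constant columns give NA
colSpearman <- function(A, B) {
  ra <- apply(A, 2, rank)
  rb <- apply(B, 2, rank)
  ra <- sweep(ra, 2, colMeans(ra))
  rb <- sweep(rb, 2, colMeans(rb))
  den <- sqrt(colSums(ra^2) * colSums(rb^2))
  num <- colSums(ra * rb)
  ifelse(den > 0, num / den, NA_real_)
}

#' Trajectory gene correlations
#'
#' For every adjacent interval, computes the per-gene Spearman correlation
#' between observed expression at the source timepoint and its barycentric
#' projection from the target timepoint, over the source cells. Genes whose
#' expression tracks its own projection are stably propagated along the
#' inferred trajectories (lineage-stable), unlike transiently spiking genes.
#' Intervals where either column is constant are dropped from that gene's
#' median (not zero-filled).
#'
#' @param tc normalized \linkS4class{TimeCourse}.
#' @param maps named list of adjacent-pair \linkS4class{TransportMap}s from
#'   \code{\link{fitTimecourseMaps}}.
#' @param genes gene ids to score (e.g. the HVG list).
#' @param topK size of the selected top set (by median correlation,
#'   gene-id tie-break).
#' @return list with \code{rho} (genes x intervals matrix), \code{median}
#'   (named vector) and \code{top} (character vector of topK gene ids).
#' @export
trajectoryGeneCorrelations <- function(tc, maps, genes = rownames(tc),
                                       topK = 100) {
  genes <- intersect(genes, rownames(tc))
  rho <- matrix(NA_real_, length(genes), length(maps),
                dimnames = list(genes, names(maps)))
  for (k in seq_along(maps)) {
    tm <- maps[[k]]
    rsm <- rowNormalize(tm)
    Xs <- t(asDense(logExprs(tc[genes, tm@sourceIds])))
    Xt <- t(asDense(logExprs(tc[genes, tm@targetIds])))
    proj <- barycentricProject(rsm, Xt)
    rho[, k] <- colSpearman(Xs, proj)
  }
  med <- apply(rho, 1, stats::median, na.rm = TRUE)
  ord <- order(-med, names(med))
  top <- names(med)[ord][seq_len(min(topK, sum(!is.na(med))))]
  list(rho = rho, median = med, top = top)
}

#' Fate propensities and fate entropy
#'
#' \eqn{\tilde Q_{s\to t} = \hat P_{s,t} C_t} with \eqn{C_t} the one-hot
#' cluster matrix at the target timepoint: per-cell probabilities over the k
#' target clusters, whose rows sum to 1. The per-cell Shannon entropy (nats,
#' with \eqn{0 \log 0 := 0}) quantifies fate uncertainty.
#'
#' @param rsm a \linkS4class{RowStochasticMap}.
#' @param targetLabels cluster labels of the target cells (same order as the
#'   map columns); NA labels are an error.
#' @return list with \code{Q} (m x k matrix), \code{entropy} (per-cell,
#'   nats) and \code{clusters} (level names).
#' @export
fatePropensities <- function(rsm, targetLabels) {
  if (length(targetLabels) != ncol(rsm@P))
    stop("one label per target cell required")
  if (anyNA(targetLabels)) stop("target cells without labels")
  Ct <- oneHot(targetLabels)
  Q <- rsm@P %*% Ct
  rownames(Q) <- rsm@sourceIds
  H <- -rowSums(ifelse(Q > 0, Q * log(Q), 0))
  list(Q = Q, entropy = H, clusters = colnames(Ct))
}

#' Fate consistency
#'
#' Normalizes fate entropy by the expected entropy of a completely random
#' trajectory, \eqn{H_0 = -\sum_k p_k \log p_k} with \eqn{p_k} the target
#' cluster frequencies: consistency \eqn{= 1 - H / H_0}. Values near 1 mean
#' clusters partition flows smoothly; values below 0 mean the clustering is
#' less informative than drawing target clusters at random.
#'
#' @param propensity result of \code{\link{fatePropensities}}.
#' @param targetFreqs cluster frequencies at the target timepoint (named;
#'   defaults to the column means of \code{Q}, which equal the frequencies
#'   when the map is built against the full target snapshot).
#' @return list with \code{percell}, \code{mean} and \code{H0}.
#' @export
fateConsistency <- function(propensity, targetFreqs = NULL) {
  if (is.null(targetFreqs)) targetFreqs <- colMeans(propensity$Q)
  p <- targetFreqs / sum(targetFreqs)
  H0 <- -sum(ifelse(p > 0, p * log(p), 0))
  if (H0 == 0)
    stop("null entropy is zero (single occupied cluster); ",
         "consistency undefined")
  percell <- 1 - propensity$entropy / H0
  list(percell = percell, mean = mean(percell), H0 = H0)
}

#' Per-cell compartment egress probabilities
#'
#' For each source cell, the probability under the transition map of its
#' descendants lying in the other compartment at the target timepoint. Stay
#' and egress probabilities sum to 1 per cell.
#'
#' @param rsm a \linkS4class{RowStochasticMap} for one interval.
#' @param sourceCompartments,targetCompartments compartment labels aligned
#'   with the map rows and columns.
#' @return data.frame with \code{cell}, \code{compartment} and \code{egress}
#'   columns; attribute "summary" holds mean and SEM per source compartment.
#' @export
egressProbabilities <- function(rsm, sourceCompartments, targetCompartments) {
  if (length(sourceCompartments) != nrow(rsm@P) ||
      length(targetCompartments) != ncol(rsm@P))
    stop("compartment labels must align with the map dimensions")
  if (anyNA(sourceCompartments) || anyNA(targetCompartments))
    stop("missing compartment labels")
  eg <- vapply(seq_len(nrow(rsm@P)), function(i)
    sum(rsm@P[i, targetCompartments != sourceCompartments[i]]), numeric(1))
  out <- data.frame(cell = rsm@sourceIds, compartment = sourceCompartments,
                    egress = eg)
  s <- do.call(rbind, lapply(split(out$egress, out$compartment), function(v)
    data.frame(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))))
  s$compartment <- rownames(s)
  attr(out, "summary") <- s
  out
}

#' Arrival-time estimation for tissue-localized cells
#'
#' For each query cell (at \code{queryTimepoint} in
#' \code{queryCompartment}), chains transition maps backward via the
#' transpose rule and computes \eqn{q_t}, the probability that its ancestor
#' at timepoint t already lay in the query compartment. After a monotone
#' (isotonic, non-decreasing toward the query) adjustment, the increments
#' \eqn{\Delta q_t} act as per-step entry probabilities; the arrival time is
#' their expectation \eqn{\sum_t t \Delta q_t / \sum_t \Delta q_t} (or the
#' maximum-increment step with \code{method = "mode"}). Estimates lie in
#' \code{[first timepoint, queryTimepoint]}.
#'
#' @param maps named list of forward adjacent-pair
#'   \linkS4class{TransportMap}s.
#' @param compartments named character vector mapping cell ids to
#'   compartments (all cells of the fitted time course).
#' @param queryTimepoint the day whose tissue cells are queried.
#' @param queryCompartment the tissue compartment.
#' @param method "expectation" (default) or "mode".
#' @return data.frame with \code{cell}, \code{arrival}, and the backward
#'   membership curve as attribute "membership" (cells x timepoints).
#' @export
arrivalTimes <- function(maps, compartments, queryTimepoint,
                         queryCompartment, method = c("expectation", "mode")) {
  method <- match.arg(method)
  srcT <- vapply(maps, function(m) m@sourceTime, numeric(1))
  tgtT <- vapply(maps, function(m) m@targetTime, numeric(1))
  ord <- order(srcT)
  maps <- maps[ord]; srcT <- srcT[ord]; tgtT <- tgtT[ord]
  qi <- which(tgtT == queryTimepoint)
  if (length(qi) != 1)
    stop("no adjacent-pair map targets timepoint ", queryTimepoint)
  queryCells <- maps[[qi]]@targetIds
  inComp <- compartments[queryCells] == queryCompartment
  if (!any(inComp)) stop("no query cells in compartment ", queryCompartment)
  queryCells <- queryCells[inComp]

  tps <- c(srcT[seq_len(qi)], queryTimepoint)
  ## backward membership at each earlier timepoint
  Qmat <- matrix(NA_real_, length(queryCells), length(tps),
                 dimnames = list(queryCells, as.character(tps)))
  Qmat[, length(tps)] <- 1   # the query cell is in the compartment now
  back <- NULL
  for (k in rev(seq_len(qi))) {
    step <- transposeMap(maps[[k]])          # t_{k+1} -> t_k
    back <- if (is.null(back)) step else chainMaps(back, step)
    memb <- as.numeric(compartments[back@targetIds] == queryCompartment)
    Qmat[, k] <- (back@P[queryCells, , drop = FALSE] %*% memb)[, 1]
  }
  ## increment over (t_{k-1}, t_k] is attributed to the interval start; the
  ## first observation's mass was already in the compartment by t_1
  attT <- c(tps[1], tps[-length(tps)])
  arrival <- vapply(seq_len(nrow(Qmat)), function(i) {
    q <- Qmat[i, ]
    qi_fit <- stats::isoreg(seq_along(q), q)$yf   # non-decreasing toward query
    inc <- diff(c(0, qi_fit))
    if (sum(inc) <= 0) return(tps[length(tps)])
    if (method == "expectation") sum(attT * inc) / sum(inc)
    else attT[which.max(inc)]
  }, numeric(1))
  out <- data.frame(cell = queryCells, arrival = arrival)
  attr(out, "membership") <- Qmat
  out
}
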