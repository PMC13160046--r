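oneHot <- function(labels) {
  f <- factor(labels)
  M <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  M
}

#' Fate-flow inflow/outflow matrices for a middle timepoint
#'
#' For sequential timepoints r < s < t with one-hot cluster matrices and
#' row-stochastic maps, \eqn{F^{in}_s = C_s^\top \hat P_{s,r} C_r} and
#' \eqn{F^{out}_s = C_s^\top \hat P_{s,t} C_t}. Inflows and outflows are kept
#' separate so proliferation and death do not cancel in the diagram.
#' \code{F_out[i, j]} is the expected number of cluster-i cells at s flowing
#' to cluster j at t; the total mass equals the number of cells at s.
#'
#' @param labelsR,labelsS,labelsT cluster labels at r, s, t (aligned with
#'   the map dimensions); NA labels are an error.
#' @param mapSR backward \linkS4class{RowStochasticMap} s -> r (transpose
#'   rule).
#' @param mapST forward \linkS4class{RowStochasticMap} s -> t.
#' @return list with matrices \code{F_in} (k_s x k_r) and \code{F_out}
#'   (k_s x k_t).
#' @export
fateFlow <- function(labelsR, labelsS, labelsT, mapSR, mapST) {
  if (anyNA(labelsR) || anyNA(labelsS) || anyNA(labelsT))
    stop("unlabeled cells present")
  Cs <- oneHot(labelsS); Cr <- oneHot(labelsR); Ct <- oneHot(labelsT)
  if (nrow(Cs) != nrow(mapSR@P) || ncol(mapSR@P) != nrow(Cr))
    stop("dimension mismatch between labels and the s->r map")
  if (nrow(Cs) != nrow(mapST@P) || ncol(mapST@P) != nrow(Ct))
    stop("dimension mismatch between labels and the s->t map")
  list(F_in = t(Cs) %*% mapSR@P %*% Cr,
       F_out = t(Cs) %*% mapST@P %*% Ct)
}

#' Flatten flow matrices into Sankey link records
#'
#' Produces (source node, target node, mass) records for a flow matrix,
#' optionally attaching a per-node color value (e.g. supercell gene set
#' score means). Masses are preserved exactly; nodes are ordered by
#' descending mass with a stable id tie-break. Links below
#' \code{threshold} are pruned (default 0: keep all).
#'
#' @param flow a flow matrix (source clusters x target clusters).
#' @param sourcePrefix,targetPrefix node name prefixes (e.g. day labels).
#' @param colorValues optional named vector of per-node color values.
#' @param threshold minimum mass to keep a link.
#' @return data.frame with \code{source}, \code{target}, \code{mass} (and
#'   \code{source_color}/\code{target_color} when supplied).
#' @export
sankeyExport <- function(flow, sourcePrefix = "s", targetPrefix = "t",
                         colorValues = NULL, threshold = 0) {
  src <- paste0(sourcePrefix, ":", rownames(flow) %||% seq_len(nrow(flow)))
  tgt <- paste0(targetPrefix, ":", colnames(flow) %||% seq_len(ncol(flow)))
  rec <- expand.grid(si = seq_len(nrow(flow)), ti = seq_len(ncol(flow)))
  out <- data.frame(source = src[rec$si], target = tgt[rec$ti],
                    mass = flow[cbind(rec$si, rec$ti)])
  if (!is.null(colorValues)) {
    out$source_color <- unname(colorValues[out$source])
    out$target_color <- unname(colorValues[out$target])
  }
  if (threshold > 0) out <- out[out$mass >= threshold, ]
  nodeMass <- c(tapply(out$mass, out$source, sum),
                tapply(out$mass, out$target, sum))
  ord <- order(-out$mass, out$source, out$target)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "nodes") <- names(sort(-nodeMass))
  out
}

#' Write Sankey links as CSV or nodes/links JSON
#'
#' @param records data.frame from \code{\link{sankeyExport}}.
#' @param path output file.
#' @param format "csv" or "json" (nodes/links schema).
#' @return \code{path}, invisibly.
#' @export
writeSankey <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    nodes <- unique(c(records$source, records$target))
    links <- data.frame(source = match(records$source, nodes) - 1L,
                        target = match(records$target, nodes) - 1L,
                        value = records$mass)
    jsonlite::write_json(list(nodes = data.frame(name = nodes), links = links),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

## entropic OT cost with uniform marginals (balanced)
sinkhornCost <- function(XA, XB, epsilon, tol = 1e-9, maxIters = 100000L) {
  C <- costMatrix(as.matrix(XA), as.matrix(XB))
  a <- rep(1 / nrow(C), nrow(C)); b <- rep(1 / ncol(C), ncol(C))
  fit <- cpp_sinkhorn_uot(C, a, b, epsilon, 1, 1, maxIters, tol)
  if (isTRUE(fit$error)) stop("Sinkhorn failed; try a larger epsilon")
  fit$cost
}

#' Debiased Sinkhorn earth mover's distance
#'
#' Entropic OT cost between two cell populations with uniform marginals and
#' Euclidean costs; the entropic bias (which makes the plain Sinkhorn
#' self-distance positive) is removed by subtracting half of each
#' self-distance:
#' \deqn{EMD_{unb}(A, B) = EMD(A, B) - \tfrac12 EMD(A, A) - \tfrac12 EMD(B, B)}
#' so the self-distance is exactly zero and the value is symmetric. The
#' divergence is not a metric; no triangle inequality is implied.
#'
#' @param XA,XB cells x features matrices (same feature space, e.g. PCA
#'   coordinates).
#' @param epsilon entropic regularization (default 1).
#' @return list with \code{value} (debiased), \code{cross}, \code{selfA},
#'   \code{selfB} and \code{epsilon}.
#' @export
emd <- function(XA, XB, epsilon = 1.0) {
  if (nrow(XA) == 0 || nrow(XB) == 0) stop("empty population")
  cross <- sinkhornCost(XA, XB, epsilon)
  selfA <- sinkhornCost(XA, XA, epsilon)
  selfB <- sinkhornCost(XB, XB, epsilon)
  list(value = cross - 0.5 * selfA - 0.5 * selfB,
       cross = cross, selfA = selfA, selfB = selfB, epsilon = epsilon)
}

#' Bootstrapped earth mover's distance
#'
#' Subsamples \code{nCells} cells from each population (with replacement,
#' and a warning, when a population is smaller) and repeats the debiased
#' Sinkhorn EMD \code{nBoot} times; reproducible under the seed.
#'
#' @param XA,XB cells x features matrices.
#' @param nCells cells per draw (default 100).
#' @param nBoot number of draws (default 10).
#' @param seed RNG seed.
#' @param epsilon entropic regularization.
#' @return list with \code{draws} (numeric vector), \code{value} (their
#'   mean), and the sampling settings.
#' @export
emdBootstrap <- function(XA, XB, nCells = 100, nBoot = 10, seed = 0L,
                         epsilon = 1.0) {
  if (nBoot < 1) stop("nBoot must be at least 1")
  replaceA <- nrow(XA) < nCells; replaceB <- nrow(XB) < nCells
  if (replaceA || replaceB)
    warning("population smaller than nCells; sampling with replacement")
  set.seed(seed)
  draws <- vapply(seq_len(nBoot), function(i) {
    ia <- sample.int(nrow(XA), nCells, replace = replaceA)
    ib <- sample.int(nrow(XB), nCells, replace = replaceB)
    emd(XA[ia, , drop = FALSE], XB[ib, , drop = FALSE], epsilon)$value
  }, numeric(1))
  list(draws = draws, value = mean(draws), nCells = nCells, nBoot = nBoot,
       seed = seed, epsilon = epsilon)
}
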