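#' Fit a Nystroem Gaussian-kernel approximator at one timepoint
#'
#' Low-rank approximation of the Gaussian RBF kernel over a timepoint's
#' cells: d landmark cells are drawn uniformly at random (fixed seed), and
#' the feature map \eqn{\phi(x) = k(x, L) W^{-1/2}} (with W the landmark
#' Gram matrix, pseudo-inverse square root) makes feature inner products
#' approximate kernel values. The bandwidth is the median inter-cell
#' Euclidean distance at the timepoint.
#'
#' @param coords cells x features coordinate matrix for the timepoint.
#' @param d feature dimension (lowered with a warning when fewer cells).
#' @param seed RNG seed for the landmark draw.
#' @param timepoint day recorded on the object.
#' @return A \linkS4class{KernelApproximator}.
#' @export
fitKernelFeatures <- function(coords, d = 50L, seed = 0L, timepoint = NA_real_) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < d) {
    warning("only ", n, " cells; lowering kernel dimension from ", d)
    d <- n
  }
  h <- stats::median(stats::dist(coords))
  if (!is.finite(h) || h <= 0)
    stop("degenerate timepoint: zero median inter-cell distance")
  set.seed(seed)
  L <- coords[sample.int(n, d), , drop = FALSE]
  W <- exp(-costMatrix(L, L)^2 / (2 * h^2))
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-12
  whitening <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
  new("KernelApproximator", timepoint = as.numeric(timepoint), landmarks = L,
      bandwidth = h, whitening = whitening, dim = as.integer(d))
}

#' Map coordinates into Nystroem feature space
#'
#' @param ka a \linkS4class{KernelApproximator}.
#' @param coords cells x features matrix (same feature space as the fit).
#' @return cells x d feature matrix.
#' @export
kernelTransform <- function(ka, coords) {
  K <- exp(-costMatrix(as.matrix(coords), ka@landmarks)^2 /
             (2 * ka@bandwidth^2))
  K %*% ka@whitening
}

#' Trajectory kernel mean embedding (TKME)
#'
#' Embeds every cell by its whole inferred trajectory: per-timepoint Gaussian
#' kernel features are barycentrically projected to each included timepoint
#' through (chained, transposed where backward) row-stochastic transport
#' maps, and concatenated along the feature axis in ascending timepoint
#' order. The block for a cell's own timepoint is its own kernel features.
#' Restricting the included timepoints (default: days > 6) keeps clusters
#' from being confounded by the migration window.
#'
#' @param coords cells x features coordinate matrix (e.g. global PCA) for
#'   all cells of the time course.
#' @param cellTimepoints named numeric vector, day per cell (aligned with
#'   \code{rownames(coords)}).
#' @param maps named list of adjacent-pair \linkS4class{TransportMap}s.
#' @param d kernel feature dimension per timepoint block.
#' @param includeDaysAfter only timepoints strictly greater than this value
#'   contribute blocks (set to \code{-Inf} to include all).
#' @param seed seed for landmark draws.
#' @param standardizeBlocks scale each timepoint block to unit mean column
#'   variance so every projection weighs equally in downstream clustering.
#' @return cells x (blocks * d) matrix; attribute "blockDays" names the
#'   included timepoints.
#' @export
tkmeEmbed <- function(coords, cellTimepoints, maps, d = 50L,
                      includeDaysAfter = 6, seed = 0L,
                      standardizeBlocks = TRUE) {
  coords <- as.matrix(coords)
  tps <- sort(unique(cellTimepoints))
  included <- tps[tps > includeDaysAfter]
  if (length(included) == 0) stop("no timepoints pass the inclusion filter")
  srcT <- vapply(maps, function(m) m@sourceTime, numeric(1))
  maps <- maps[order(srcT)]
  pairKey <- function(s, t) sprintf("%g->%g", s, t)
  for (k in seq_len(length(tps) - 1))
    if (!pairKey(tps[k], tps[k + 1]) %in% names(maps))
      stop("missing transport map for pair ", pairKey(tps[k], tps[k + 1]))

  cellsAt <- split(names(cellTimepoints), cellTimepoints)
  feats <- list()    # own-timepoint kernel features per included timepoint
  kernels <- list()
  for (t in included) {
    idx <- cellsAt[[as.character(t)]]
    ka <- fitKernelFeatures(coords[idx, , drop = FALSE], d = d,
                            seed = seed + match(t, tps), timepoint = t)
    kernels[[as.character(t)]] <- ka
    f <- kernelTransform(ka, coords[idx, , drop = FALSE])
    rownames(f) <- idx
    feats[[as.character(t)]] <- f
  }

  fwd <- lapply(seq_len(length(tps) - 1), function(k)
    rowNormalize(maps[[pairKey(tps[k], tps[k + 1])]]))
  bwd <- lapply(seq_len(length(tps) - 1), function(k)
    transposeMap(maps[[pairKey(tps[k], tps[k + 1])]]))

  dEff <- ncol(feats[[1]])
  Z <- matrix(NA_real_, nrow(coords), length(included) * dEff,
              dimnames = list(rownames(coords), NULL))
  for (i in seq_along(tps)) {
    s <- tps[i]
    src <- cellsAt[[as.character(s)]]
    ## ascending chains
    chain <- NULL
    for (j in seq_along(tps)) {
      t <- tps[j]
      if (j > i) {
        step <- fwd[[j - 1]]
        chain <- if (is.null(chain)) step else chainMaps(chain, step)
        if (t %in% included) {
          col0 <- (match(t, included) - 1) * dEff
          Z[src, col0 + seq_len(dEff)] <-
            barycentricProject(chain, feats[[as.character(t)]])
        }
      }
    }
    chain <- NULL
    for (j in rev(seq_along(tps))) {
      t <- tps[j]
      if (j < i) {
        step <- bwd[[j]]
        chain <- if (is.null(chain)) step else chainMaps(chain, step)
        if (t %in% included) {
          col0 <- (match(t, included) - 1) * dEff
          Z[src, col0 + seq_len(dEff)] <-
            barycentricProject(chain, feats[[as.character(t)]])
        }
      }
    }
    if (s %in% included) {
      col0 <- (match(s, included) - 1) * dEff
      Z[src, col0 + seq_len(dEff)] <- feats[[as.character(s)]][src, ]
    }
  }
  if (standardizeBlocks) {
    for (b in seq_along(included)) {
      cols <- (b - 1) * dEff + seq_len(dEff)
      v <- mean(apply(Z[, cols, drop = FALSE], 2, stats::var))
      if (v > 0) Z[, cols] <- Z[, cols] / sqrt(v)
    }
  }
  attr(Z, "blockDays") <- included
  attr(Z, "kernels") <- kernels
  Z
}

## chunked k-nearest-neighbour indices (brute force, deterministic)
knnIndices <- function(X, k) {
  n <- nrow(X)
  x2 <- rowSums(X^2)
  out <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e7 / n))
  for (st in seq(1, n, by = chunk)) {
    en <- min(st + chunk - 1, n)
    d2 <- outer(x2[st:en], x2, "+") - 2 * tcrossprod(X[st:en, , drop = FALSE], X)
    for (r in seq_len(en - st + 1)) {
      d2[r, st + r - 1] <- Inf
      out[st + r - 1, ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

## shared-nearest-neighbour (Jaccard-weighted, pruned) graph + Leiden, the
## standard single-cell community-detection construction
leidenLabels <- function(X, knn = 15L, resolution = 1, seed = 0L,
                         nIterations = 5L, prune = 1 / 15) {
  n <- nrow(X)
  knn <- min(knn, n - 1L)
  nn <- knnIndices(X, knn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), knn + 1L),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)            # shared-neighbour counts
  J <- S
  J@x <- S@x / (2 * (knn + 1L) - S@x)   # Jaccard overlap per pair
  J@x[J@x < prune] <- 0
  J <- Matrix::drop0(J)
  g <- igraph::graph_from_adjacency_matrix(J, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = nIterations)
  factor(igraph::membership(cl))
}

#' Cluster cells into trajectories
#'
#' Clusters TKME embeddings into discrete trajectories with either Leiden
#' community detection on a kNN graph or k-means (k-means++ style multiple
#' restarts); both are deterministic under the seed.
#'
#' @param Z embedding matrix (cells x features), finite.
#' @param method "leiden" or "kmeans".
#' @param k number of clusters (k-means; required).
#' @param resolution Leiden resolution parameter.
#' @param knn neighbours for the Leiden graph.
#' @param seed RNG seed.
#' @return Factor of per-cell labels, named by cell id.
#' @export
clusterTrajectories <- function(Z, method = c("leiden", "kmeans"), k = NULL,
                                resolution = 1, knn = 15L, seed = 0L) {
  method <- match.arg(method)
  if (any(!is.finite(Z))) stop("embedding contains non-finite values")
  if (method == "kmeans") {
    if (is.null(k)) stop("k is required for k-means")
    if (k > nrow(Z)) stop("k exceeds the number of cells")
    set.seed(seed)
    km <- stats::kmeans(Z, centers = k, nstart = 10, iter.max = 100)
    lab <- factor(km$cluster)
  } else {
    lab <- leidenLabels(Z, knn = knn, resolution = resolution, seed = seed)
  }
  names(lab) <- rownames(Z)
  lab
}

#' Timepoint-local supercells
#'
#' Leiden clustering of one timepoint's cells on their PCA coordinates (kNN
#' graph, 15 neighbours, resolution 1 by default), the coarse nodes used in
#' fate-flow Sankey diagrams.
#'
#' @param coords cells x components PCA coordinates at one timepoint.
#' @param kNN neighbours (lowered with a warning when cells are few).
#' @param resolution Leiden resolution.
#' @param seed RNG seed.
#' @return Factor of per-cell supercell labels.
#' @export
supercells <- function(coords, kNN = 15L, resolution = 1, seed = 0L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < kNN + 1) {
    warning("fewer cells than kNN + 1; lowering kNN")
    kNN <- max(1L, nrow(coords) - 1L)
  }
  lab <- leidenLabels(coords, knn = kNN, resolution = resolution, seed = seed)
  names(lab) <- rownames(coords)
  lab
}

#' Per-interval fate consistency of a clustering
#'
#' Applies \code{\link{fateConsistency}} to a fixed cell clustering at every
#' adjacent interval of the fitted maps: high values mean the clusters
#' partition the inferred flows smoothly along the whole trajectory.
#'
#' @param labels named factor of per-cell cluster labels (all cells).
#' @param maps named list of adjacent-pair \linkS4class{TransportMap}s.
#' @return data.frame with one row per interval (\code{interval},
#'   \code{consistency}); attribute "mean" is the overall mean.
#' @export
trajectoryClusterConsistency <- function(labels, maps) {
  res <- lapply(names(maps), function(nm) {
    tm <- maps[[nm]]
    rsm <- rowNormalize(tm)
    tl <- as.character(labels[tm@targetIds])
    if (length(unique(tl)) < 2)   # single occupied target cluster: undefined
      return(data.frame(interval = nm, consistency = NA_real_))
    prop <- fatePropensities(rsm, tl)
    freqs <- table(factor(tl))
    cons <- fateConsistency(prop, targetFreqs = as.numeric(freqs) / sum(freqs))
    data.frame(interval = nm, consistency = cons$mean)
  })
  out <- do.call(rbind, res)
  if (all(is.na(out$consistency)))
    stop("consistency undefined at every interval (single occupied cluster)")
  attr(out, "mean") <- mean(out$consistency, na.rm = TRUE)
  out
}
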