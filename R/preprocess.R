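#' Filter cells by library size and mitochondrial fraction
#'
#' Removes cells with total counts below \code{minCounts} or mitochondrial
#' read fraction above \code{maxMitoFrac}. Thresholds are strict: cells with
#' exactly \code{minCounts} reads or exactly \code{maxMitoFrac} mitochondrial
#' fraction are kept. Mitochondrial genes are identified by name prefix
#' (default \code{"mt-"}, mouse).
#'
#' @param tc a raw-count \linkS4class{TimeCourse}.
#' @param maxMitoFrac maximum tolerated mitochondrial fraction.
#' @param minCounts minimum per-cell total counts.
#' @param mitoPrefix gene-name prefix marking mitochondrial genes
#'   (case-insensitive).
#' @return Filtered \linkS4class{TimeCourse}.
#' @export
filterCells <- function(tc, maxMitoFrac = 0.10, minCounts = 1500,
                        mitoPrefix = "mt-") {
  if (isNormalized(tc))
    stop("filterCells requires raw counts; input is already normalized")
  X <- rawCounts(tc)
  totals <- Matrix::colSums(X)
  mito <- startsWith(tolower(rownames(tc)), tolower(mitoPrefix))
  mitoFrac <- if (any(mito)) Matrix::colSums(X[mito, , drop = FALSE]) /
    pmax(totals, 1) else rep(0, ncol(tc))
  keep <- totals >= minCounts & mitoFrac <= maxMitoFrac
  out <- tc[, keep]
  out$total_counts <- totals[keep]
  out$mito_fraction <- mitoFrac[keep]
  out
}

#' Filter genes by detection across cells
#'
#' Keeps a gene iff it is detected (count > 0) in at least \code{minCells}
#' cells, pooled across all timepoints, so the shared gene index stays
#' consistent in every snapshot.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param minCells minimum number of detecting cells.
#' @return Filtered \linkS4class{TimeCourse}.
#' @export
filterGenes <- function(tc, minCells = 2) {
  X <- rawCounts(tc)
  detected <- Matrix::rowSums(X > 0)
  tc[detected >= minCells, ]
}

#' Library-size normalization and log1p transform
#'
#' Scales each cell to \code{targetSum} total counts, then applies
#' \code{log(1 + x)}. The result is stored as the "logcounts" assay and the
#' normalization flag is set; applying twice is an error.
#'
#' @param tc a raw-count \linkS4class{TimeCourse}.
#' @param targetSum per-cell total after scaling (default 1e6, CPM).
#' @return Normalized \linkS4class{TimeCourse}.
#' @export
normalizeLog1p <- function(tc, targetSum = 1e6) {
  if (isNormalized(tc)) stop("TimeCourse is already normalized")
  X <- rawCounts(tc)
  totals <- Matrix::colSums(X)
  if (any(totals == 0))
    stop("cells with zero total counts present (", sum(totals == 0),
         "); filter them first")
  scaled <- X %*% Matrix::Diagonal(x = targetSum / totals)
  colnames(scaled) <- colnames(X)
  SummarizedExperiment::assay(tc, "logcounts") <- log1p(scaled)
  S4Vectors::metadata(tc)$normalized <- TRUE
  S4Vectors::metadata(tc)$target_sum <- targetSum
  tc
}

#' Select highly variable genes
#'
#' Variance-of-standardized-counts ranking: per-gene count mean and variance
#' are computed, a loess trend of log10 variance on log10 mean supplies the
#' expected standard deviation, counts are z-scored against the trend with
#' clipping at sqrt(n cells), and genes are ranked by the variance of the
#' clipped z-scores. Ties break on gene id for a deterministic ordering.
#'
#' @param tc a normalized \linkS4class{TimeCourse} (ranking itself uses the
#'   raw counts assay).
#' @param nTop number of genes to select.
#' @param span loess span for the mean-variance trend.
#' @return Character vector of selected gene ids (ranked).
#' @export
selectHVG <- function(tc, nTop = 3000, span = 0.3) {
  if (!isNormalized(tc))
    stop("selectHVG expects a normalized TimeCourse")
  X <- asDense(rawCounts(tc))
  n <- ncol(X)
  mu <- rowMeans(X)
  v <- apply(X, 1, stats::var)
  std_var <- rep(0, nrow(X))
  use <- mu > 0 & v > 0
  if (sum(use) >= 10) {
    fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    Z <- (X[use, , drop = FALSE] - mu[use]) / sd_exp
    Z[Z > clip] <- clip
    Z[Z < -clip] <- -clip
    std_var[use] <- apply(Z, 1, stats::var)
  } else {
    std_var <- v
  }
  names(std_var) <- rownames(X)
  ord <- order(-std_var, names(std_var))
  if (nTop > length(ord)) {
    warning("nTop exceeds the number of genes; returning all genes")
    nTop <- length(ord)
  }
  names(std_var)[ord][seq_len(nTop)]
}

#' Fit a PCA embedding basis
#'
#' Centered (unscaled) PCA on log-normalized expression restricted to an HVG
#' set. \code{kind = "local_pca"} restricts to the cells of one adjacent pair
#' of timepoints (inheriting the parent HVG list), the per-pair cost basis
#' for transport fitting; \code{kind = "global_pca"} uses all cells.
#'
#' @param tc a normalized \linkS4class{TimeCourse}.
#' @param kind "global_pca" or "local_pca".
#' @param nComponents components to retain (defaults: 30 global, 50 local).
#' @param hvg gene ids to restrict to (default all genes).
#' @param timepointPair numeric length-2 vector of days (required for
#'   local_pca).
#' @return An \linkS4class{EmbeddingBasis}.
#' @export
fitBasis <- function(tc, kind = c("global_pca", "local_pca"),
                     nComponents = NULL, hvg = NULL, timepointPair = NULL) {
  kind <- match.arg(kind)
  if (is.null(nComponents))
    nComponents <- if (kind == "global_pca") 30L else 50L
  nComponents <- as.integer(nComponents)
  if (kind == "local_pca") {
    if (is.null(timepointPair) || length(timepointPair) != 2)
      stop("local_pca requires a timepointPair of length 2")
    tc <- tc[, tc$timepoint %in% timepointPair]
  }
  if (is.null(hvg)) hvg <- rownames(tc)
  hvg <- intersect(hvg, rownames(tc))
  X <- t(asDense(logExprs(tc[hvg, ])))     # cells x genes
  if (nComponents > min(dim(X)))
    stop("nComponents (", nComponents, ") exceeds min(cells, genes) = ",
         min(dim(X)))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  # deterministic sign convention: largest-|loading| entry positive
  for (j in seq_len(nComponents)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  coords <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(coords) <- colnames(tc)
  new("EmbeddingBasis", kind = kind, nComponents = nComponents,
      rotation = sv$v[, seq_len(nComponents), drop = FALSE], center = ctr,
      coords = coords, cellIds = colnames(tc), hvg = hvg,
      sdev = sv$d[seq_len(nComponents)] / sqrt(max(1, nrow(X) - 1)))
}
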