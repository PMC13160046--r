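#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' TimeCourse: timepoint-labeled single-cell expression data
#'
#' A \code{TimeCourse} extends
#' \linkS4class{SingleCellExperiment}: cells are columns, genes are
#' rows, and \code{colData} carries a numeric \code{timepoint} (days) and an
#' optional \code{compartment} label per cell. A metadata flag records whether
#' counts-per-target-sum log1p normalization has been applied; operations that
#' require one scale check it.
#'
#' @slot .Data inherited \code{SingleCellExperiment} representation.
#' @export
setClass("TimeCourse", contains = "SingleCellExperiment")

setValidity("TimeCourse", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"timepoint" %in% colnames(cd))
    return("colData must contain a numeric 'timepoint' column")
  tp <- cd$timepoint
  if (!is.numeric(tp) || anyNA(tp) || any(!is.finite(tp)))
    return("'timepoint' must be finite numeric (days)")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  if (ncol(object) > 0 && anyDuplicated(colnames(object)))
    return("cell ids (colnames) must be unique")
  TRUE
})

#' Transport map between two timepoints
#'
#' Nonnegative coupling matrix returned by the unbalanced entropic Sinkhorn
#' solver, together with its prior marginals, solver settings and convergence
#' diagnostics. Rows index source cells, columns target cells.
#'
#' @slot coupling numeric matrix, m source cells by n target cells, >= 0.
#' @slot sourceIds,targetIds cell identifiers.
#' @slot sourceTime,targetTime timepoints in days, sourceTime < targetTime.
#' @slot a,b prior source and target marginals.
#' @slot epsilon,tauA,tauB solver hyperparameters; the KL weights are
#'   lambda = epsilon * tau / (1 - tau).
#' @slot converged logical convergence flag; \code{residual} the final
#'   marginal (balanced) or potential-change (unbalanced) residual.
#' @slot iterations Sinkhorn iterations used.
#' @slot cost transport cost \code{sum(P * C)} on the original cost scale.
#' @export
setClass("TransportMap", representation(
  coupling = "matrix",
  sourceIds = "character", targetIds = "character",
  sourceTime = "numeric", targetTime = "numeric",
  a = "numeric", b = "numeric",
  epsilon = "numeric", tauA = "numeric", tauB = "numeric",
  converged = "logical", iterations = "integer",
  cost = "numeric", residual = "numeric"))

setValidity("TransportMap", function(object) {
  P <- object@coupling
  if (any(!is.finite(P)) || any(P < 0))
    return("coupling must be finite and nonnegative")
  if (nrow(P) != length(object@sourceIds) || ncol(P) != length(object@targetIds))
    return("coupling dimensions must match source/target ids")
  if (length(object@a) != nrow(P) || length(object@b) != ncol(P))
    return("marginal lengths must match coupling dimensions")
  if (object@sourceTime >= object@targetTime)
    return("sourceTime must precede targetTime")
  TRUE
})

#' Row-stochastic transition map
#'
#' A coupling renormalized so every row sums to 1; rows are per-cell
#' transition distributions. \code{provenance} records how it was derived
#' (direct, transposed, or chained).
#'
#' @slot P numeric matrix with unit row sums.
#' @slot sourceIds,targetIds cell identifiers.
#' @slot sourceTime,targetTime timepoints in days (either order: backward maps
#'   from the transpose rule have sourceTime > targetTime).
#' @slot provenance character description of derivation.
#' @export
setClass("RowStochasticMap", representation(
  P = "matrix",
  sourceIds = "character", targetIds = "character",
  sourceTime = "numeric", targetTime = "numeric",
  provenance = "character"))

setValidity("RowStochasticMap", function(object) {
  P <- object@P
  if (any(!is.finite(P)) || any(P < 0)) return("P must be finite, nonnegative")
  if (nrow(P) > 0 && max(abs(rowSums(P) - 1)) > 1e-8)
    return("every row of P must sum to 1 within 1e-8")
  TRUE
})

#' Growth prior for source marginals
#'
#' Per-cell growth factors derived from clipped proliferation-minus-apoptosis
#' gene set score differentials, and the normalized source marginal they
#' induce. With calibrated sigma the largest per-day growth factor equals
#' \code{gmax}.
#'
#' @slot cellIds cell identifiers.
#' @slot timepoint source timepoint (days); \code{dt} interval length in days.
#' @slot delta clipped score differentials.
#' @slot sigma scaling factor (> 0).
#' @slot g per-cell growth factors \code{exp(delta * dt / sigma)}.
#' @slot a normalized source marginal (sums to 1).
#' @slot gmax per-day growth-factor cap used for calibration.
#' @export
setClass("GrowthPrior", representation(
  cellIds = "character", timepoint = "numeric", dt = "numeric",
  delta = "numeric", sigma = "numeric", g = "numeric", a = "numeric",
  gmax = "numeric"))

setValidity("GrowthPrior", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (any(object@g <= 0)) return("growth factors must be positive")
  if (abs(sum(object@a) - 1) > 1e-12) return("source marginal must sum to 1")
  if (length(object@g) != length(object@a) ||
      length(object@g) != length(object@cellIds))
    return("delta, g, a and cellIds must have equal length")
  TRUE
})

#' PCA embedding basis
#'
#' Centered principal-component basis fitted either globally or locally to a
#' pair of adjacent timepoints (local bases inherit the parent HVG set).
#'
#' @slot kind "global_pca" or "local_pca".
#' @slot nComponents number of components retained.
#' @slot rotation gene loadings (genes x components).
#' @slot center per-gene centering vector.
#' @slot coords per-cell coordinates (cells x components).
#' @slot cellIds cell identifiers for \code{coords} rows.
#' @slot hvg the highly-variable-gene list the basis is restricted to.
#' @slot sdev singular-value-derived component standard deviations.
#' @export
setClass("EmbeddingBasis", representation(
  kind = "character", nComponents = "integer",
  rotation = "matrix", center = "numeric",
  coords = "matrix", cellIds = "character",
  hvg = "character", sdev = "numeric"))

#' Nystroem kernel approximator for one timepoint
#'
#' Low-rank Gaussian RBF feature map fitted on a timepoint's cells; feature
#' inner products approximate kernel values. Bandwidth is the median
#' inter-cell Euclidean distance at the timepoint.
#'
#' @slot timepoint the timepoint (days).
#' @slot landmarks landmark coordinates (d landmarks x features).
#' @slot bandwidth RBF bandwidth (> 0).
#' @slot whitening d x d matrix mapping kernel evaluations to features
#'   (pseudo-inverse square root of the landmark Gram matrix).
#' @slot dim feature dimension d.
#' @export
setClass("KernelApproximator", representation(
  timepoint = "numeric", landmarks = "matrix", bandwidth = "numeric",
  whitening = "matrix", dim = "integer"))

setMethod("show", "TimeCourse", function(object) {
  tp <- sort(unique(object$timepoint))
  cat("TimeCourse:", nrow(object), "genes x", ncol(object), "cells\n")
  cat("  timepoints (days):", paste(tp, collapse = ", "), "\n")
  if (!is.null(object$compartment))
    cat("  compartments:", paste(sort(unique(object$compartment)),
                                 collapse = ", "), "\n")
  cat("  normalized:", isNormalized(object), "\n")
})

setMethod("show", "TransportMap", function(object) {
  cat(sprintf("TransportMap %g -> %g days: %d x %d cells\n",
              object@sourceTime, object@targetTime,
              nrow(object@coupling), ncol(object@coupling)))
  cat(sprintf("  epsilon=%g tauA=%g tauB=%g | cost=%.4g | %s (%d iters, residual %.2e)\n",
              object@epsilon, object@tauA, object@tauB, object@cost,
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
})

setMethod("show", "RowStochasticMap", function(object) {
  cat(sprintf("RowStochasticMap %g -> %g days: %d x %d [%s]\n",
              object@sourceTime, object@targetTime,
              nrow(object@P), ncol(object@P), object@provenance))
})

setMethod("show", "GrowthPrior", function(object) {
  cat(sprintf("GrowthPrior at day %g (dt=%g): %d cells, sigma=%.4g, g in [%.3g, %.3g]\n",
              object@timepoint, object@dt, length(object@g), object@sigma,
              min(object@g), max(object@g)))
})
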