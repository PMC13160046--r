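#' Construct a TimeCourse from a counts matrix and cell metadata
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   nonnegative counts. Must have row (gene) and column (cell) names.
#' @param timepoint numeric vector of days, one per cell.
#' @param compartment optional character vector, one per cell (e.g. "spleen",
#'   "siIEL").
#' @param colData optional extra per-cell columns (data.frame).
#' @param normalized logical; set TRUE only when \code{counts} already holds
#'   log1p-normalized values (stored as the "logcounts" assay instead).
#' @return A \linkS4class{TimeCourse}.
#' @export
TimeCourse <- function(counts, timepoint, compartment = NULL, colData = NULL,
                       normalized = FALSE) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
  timepoint <- as.numeric(timepoint)
  if (length(timepoint) != ncol(counts))
    stop("'timepoint' must have one entry per cell")
  cd <- S4Vectors::DataFrame(timepoint = timepoint, row.names = colnames(counts))
  if (!is.null(compartment)) {
    if (length(compartment) != ncol(counts))
      stop("'compartment' must have one entry per cell")
    cd$compartment <- as.character(compartment)
  }
  if (!is.null(colData)) {
    for (nm in setdiff(colnames(colData), colnames(cd))) cd[[nm]] <- colData[[nm]]
  }
  assays <- if (normalized) list(counts = counts, logcounts = counts)
            else list(counts = counts)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = assays, colData = cd)
  S4Vectors::metadata(sce)$normalized <- isTRUE(normalized)
  new("TimeCourse", sce)
}

#' @describeIn timepoints Sorted unique timepoints (days) present in the data.
#' @param x a \linkS4class{TimeCourse}.
#' @export
setMethod("timepoints", "TimeCourse", function(x) sort(unique(x$timepoint)))

#' @describeIn snapshot Subset a TimeCourse to one timepoint (and optionally
#'   one compartment).
#' @param x a \linkS4class{TimeCourse}.
#' @param timepoint a single day value present in \code{timepoints(x)}.
#' @param compartment optional compartment label.
#' @export
setMethod("snapshot", "TimeCourse", function(x, timepoint, compartment = NULL) {
  keep <- x$timepoint == timepoint
  if (!any(keep)) stop("no cells at timepoint ", timepoint)
  if (!is.null(compartment)) {
    if (is.null(x$compartment)) stop("TimeCourse has no compartment labels")
    keep <- keep & x$compartment == compartment
  }
  x[, keep]
})

#' @describeIn isNormalized Whether log1p normalization has been applied.
#' @param x a \linkS4class{TimeCourse}.
#' @export
setMethod("isNormalized", "TimeCourse", function(x)
  isTRUE(S4Vectors::metadata(x)$normalized))

## internal: dense raw counts / normalized expression
rawCounts <- function(tc) SummarizedExperiment::assay(tc, "counts")

logExprs <- function(tc) {
  if (!isNormalized(tc))
    stop("operation requires log1p-normalized data; run normalizeLog1p() first")
  SummarizedExperiment::assay(tc, "logcounts")
}

asDense <- function(m) as.matrix(m)

#' Load a TimeCourse from standard on-disk formats
#'
#' Reads a 10x-style directory holding \code{matrix.mtx} (MatrixMarket, genes
#' x cells), \code{features.tsv} (or \code{genes.tsv}), \code{barcodes.tsv},
#' and a cell metadata CSV (default \code{metadata.csv}, one row per barcode,
#' in barcode order) carrying at least the timepoint column.
#'
#' @param path directory containing the files above.
#' @param timepointKey name of the numeric timepoint column in the metadata.
#' @param compartmentKey optional name of the compartment column.
#' @param metadataFile metadata CSV filename within \code{path}.
#' @return A \linkS4class{TimeCourse} with cells split by timepoint.
#' @export
loadTimeCourse <- function(path, timepointKey = "timepoint",
                           compartmentKey = NULL,
                           metadataFile = "metadata.csv") {
  if (!dir.exists(path)) stop("not a readable directory: ", path)
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("matrix.mtx not found in ", path)
  feats <- file.path(path, c("features.tsv", "genes.tsv"))
  feats <- feats[file.exists(feats)][1]
  if (is.na(feats)) stop("features.tsv/genes.tsv not found in ", path)
  bc <- file.path(path, "barcodes.tsv")
  if (!file.exists(bc)) stop("barcodes.tsv not found in ", path)
  meta <- file.path(path, metadataFile)
  if (!file.exists(meta)) stop(metadataFile, " not found in ", path)

  m <- Matrix::readMM(mtx)
  genes <- utils::read.delim(feats, header = FALSE)[[1]]
  cells <- utils::read.delim(bc, header = FALSE)[[1]]
  md <- utils::read.csv(meta, check.names = FALSE)
  if (nrow(md) != length(cells))
    stop("metadata rows (", nrow(md), ") do not match barcodes (",
         length(cells), ")")
  if (!timepointKey %in% colnames(md))
    stop("timepoint column '", timepointKey, "' absent from metadata")
  tp <- md[[timepointKey]]
  if (anyNA(suppressWarnings(as.numeric(tp))))
    stop("timepoint column '", timepointKey, "' contains non-numeric or ",
         "missing values")
  dimnames(m) <- list(as.character(genes), as.character(cells))
  comp <- NULL
  if (!is.null(compartmentKey)) {
    if (!compartmentKey %in% colnames(md))
      stop("compartment column '", compartmentKey, "' absent from metadata")
    comp <- as.character(md[[compartmentKey]])
  }
  TimeCourse(methods::as(m, "CsparseMatrix"), as.numeric(tp), compartment = comp,
             colData = md[setdiff(colnames(md),
                                  c(timepointKey, compartmentKey))])
}

#' Write a TimeCourse to a 10x-style directory
#'
#' Inverse of \code{\link{loadTimeCourse}}: writes \code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv} and \code{metadata.csv}.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeTimeCourse <- function(tc, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(rawCounts(tc), sparse = TRUE),
                              "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(tc), file.path(path, "features.tsv"))
  writeLines(colnames(tc), file.path(path, "barcodes.tsv"))
  md <- as.data.frame(SummarizedExperiment::colData(tc))
  utils::write.csv(md, file.path(path, "metadata.csv"), row.names = FALSE)
  invisible(path)
}
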