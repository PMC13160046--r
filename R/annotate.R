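#' Read / write GMT gene set files
#'
#' GMT: one set per line, tab-separated \code{name description gene1 gene2
#' ...}.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(f[-(1:2)]), f[1])
  })
  stats::setNames(lapply(out, `[[`, 1), vapply(out, names, character(1)))
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Composite state scores from pairwise gene lists
#'
#' For every ordered state pair (A, B), a pair score \eqn{s_{A/B}} is the
#' gene set score of the genes up in A versus B; the composite is
#' \eqn{\hat s_A = \sum_{k \ne A} (s_{A/k} - s_{k/A})}, combining up- and
#' down-regulated evidence. Pair lists are inputs (e.g. derived externally
#' from sorted bulk references, or planted by the simulator).
#'
#' @param tc a normalized \linkS4class{TimeCourse} snapshot or full object.
#' @param pairLists named list of gene vectors, names of the form
#'   \code{"A/B"} (genes up in A vs B); every ordered pair over the states
#'   must be present.
#' @param nBins,ctrlSize,seed passed to \code{\link{geneSetScore}}; the
#'   control draw is redrawn per pair with a pair-indexed seed.
#' @return cells x states matrix of composite scores.
#' @export
compositeScores <- function(tc, pairLists, nBins = 25, ctrlSize = 50,
                            seed = 0L) {
  pairs <- strsplit(names(pairLists), "/", fixed = TRUE)
  if (any(lengths(pairs) != 2))
    stop("pair list names must have the form 'A/B'")
  states <- sort(unique(unlist(pairs)))
  for (A in states) for (B in setdiff(states, A))
    if (!paste(A, B, sep = "/") %in% names(pairLists))
      stop("missing pair list ", A, "/", B)
  s <- matrix(0, ncol(tc), length(pairLists),
              dimnames = list(colnames(tc), names(pairLists)))
  for (k in seq_along(pairLists))
    s[, k] <- geneSetScore(tc, pairLists[[k]], nBins = nBins,
                           ctrlSize = ctrlSize, seed = seed + k)
  comp <- matrix(0, ncol(tc), length(states),
                 dimnames = list(colnames(tc), states))
  for (A in states) for (B in setdiff(states, A))
    comp[, A] <- comp[, A] + s[, paste(A, B, sep = "/")] -
      s[, paste(B, A, sep = "/")]
  attr(comp, "pairScores") <- s
  comp
}

#' Assign cell states by masked argmax of composite scores
#'
#' Each cell is assigned the unmasked state with the highest composite
#' score. Masks restrict states to day windows (e.g. naive-like labels only
#' early, memory labels only late); masked scores are recorded as missing
#' and never enter the argmax. Ties break deterministically by state-name
#' order.
#'
#' @param scores cells x states composite score matrix from
#'   \code{\link{compositeScores}}.
#' @param days numeric day per cell (aligned with rows).
#' @param masks named list, state -> \code{c(dayMin, dayMax)} inclusive
#'   window outside which the state is masked; states absent from the list
#'   are never masked.
#' @return factor of per-cell state labels.
#' @export
assignStates <- function(scores, days, masks = list()) {
  if (length(days) != nrow(scores)) stop("one day per cell required")
  states <- colnames(scores)
  lab <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    avail <- states
    for (st in names(masks)) {
      w <- masks[[st]]
      if (days[i] < w[1] || days[i] > w[2]) avail <- setdiff(avail, st)
    }
    if (length(avail) == 0)
      stop("all states masked at day ", days[i])
    v <- scores[i, avail]
    lab[i] <- avail[order(-v, avail)[1]]
  }
  factor(lab, levels = states)
}

#' Windowed dynamic time warping distance
#'
#' Sakoe-Chiba banded DTW between two equal-length series: alignment paths
#' are restricted to \code{|i - j| <= window}, local cost is the squared
#' difference, and the returned distance is the square root of the
#' accumulated cost. Symmetric; zero iff the series are identical.
#'
#' @param a,b numeric series of equal length.
#' @param window band half-width (default 2, suited to coarse timepoint
#'   grids).
#' @return Nonnegative DTW distance.
#' @export
dtwDistance <- function(a, b, window = 2) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("empty series")
  if (n != m) stop("series must have equal length")
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    jlo <- max(1, i - window); jhi <- min(m, i + window)
    for (j in jlo:jhi) {
      D[i + 1, j + 1] <- (a[i] - b[j])^2 +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  sqrt(D[n + 1, m + 1])
}

#' Mean temporal expression profiles
#'
#' Per-gene mean log-normalized expression at each timepoint (optionally
#' within one compartment), the input to temporal gene clustering.
#'
#' @param tc normalized \linkS4class{TimeCourse}.
#' @param genes gene ids (default all).
#' @param compartment optional compartment restriction.
#' @return genes x timepoints matrix.
#' @export
geneProfiles <- function(tc, genes = rownames(tc), compartment = NULL) {
  genes <- intersect(genes, rownames(tc))
  if (!is.null(compartment)) tc <- tc[, tc$compartment == compartment]
  tps <- timepoints(tc)
  out <- vapply(tps, function(t)
    rowMeans(asDense(logExprs(tc[genes, tc$timepoint == t]))),
    numeric(length(genes)))
  dimnames(out) <- list(genes, as.character(tps))
  out
}

#' Cluster temporal profiles with DTW + k-medoids
#'
#' Computes the pairwise windowed DTW distance matrix between per-gene
#' temporal profiles and partitions it with PAM k-medoids; medoids are
#' always member profiles.
#'
#' @param profiles genes x timepoints matrix (e.g. from
#'   \code{\link{geneProfiles}}).
#' @param k number of modules.
#' @param window DTW band half-width.
#' @return list with \code{labels} (named factor), \code{medoids} (gene
#'   ids) and \code{dist} (the DTW distance matrix).
#' @export
kmedoidsModules <- function(profiles, k, window = 2) {
  if (k < 1) stop("k must be at least 1")
  n <- nrow(profiles)
  if (k > n) stop("k exceeds the number of profiles")
  D <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- dtwDistance(profiles[i, ], profiles[j, ], window)
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  labels <- factor(fit$clustering)
  names(labels) <- rownames(profiles)
  list(labels = labels, medoids = rownames(profiles)[fit$id.med], dist = D)
}
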