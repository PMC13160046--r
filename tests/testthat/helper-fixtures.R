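# Small deterministic fixtures shared across test files.

# A tiny raw-count TimeCourse: nGenes x (cells per timepoint), Poisson counts
# around per-gene means, optional compartments alternating per cell.
tinyTimeCourse <- function(nGenes = 20, cellsPerDay = 10, days = c(0, 1, 2),
                           seed = 42, compartments = FALSE, libSize = 5000) {
  set.seed(seed)
  nc <- cellsPerDay * length(days)
  mu <- runif(nGenes, 0.2, 2)
  lambda <- matrix(mu, nGenes, nc) * libSize / sum(mu)
  counts <- matrix(rpois(nGenes * nc, as.vector(lambda)), nGenes, nc)
  rownames(counts) <- sprintf("g%02d", seq_len(nGenes))
  colnames(counts) <- sprintf("c%03d", seq_len(nc))
  comp <- if (compartments) rep(c("spleen", "siIEL"), length.out = nc) else NULL
  TimeCourse(counts, timepoint = rep(days, each = cellsPerDay),
             compartment = comp)
}

# Random row-stochastic map with positive entries.
randomStochasticMap <- function(m, n, seed = 1, s = 0, t = 1) {
  set.seed(seed)
  P <- matrix(runif(m * n, 0.05, 1), m, n)
  P <- P / rowSums(P)
  new("RowStochasticMap", P = P,
      sourceIds = sprintf("s%d", seq_len(m)),
      targetIds = sprintf("t%d", seq_len(n)),
      sourceTime = s, targetTime = t, provenance = "direct")
}

# Wrap a raw coupling matrix as a TransportMap (for algebra tests).
asTransportMap <- function(P, s = 0, t = 1) {
  new("TransportMap", coupling = P,
      sourceIds = rownames(P) %||% sprintf("s%d", seq_len(nrow(P))),
      targetIds = colnames(P) %||% sprintf("t%d", seq_len(ncol(P))),
      sourceTime = s, targetTime = t,
      a = rowSums(P), b = colSums(P),
      epsilon = 1, tauA = 1, tauB = 1, converged = TRUE,
      iterations = 0L, cost = 0, residual = 0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
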