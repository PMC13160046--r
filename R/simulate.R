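#' Simulation configuration for the two-compartment benchmark
#'
#' Defines a ground-truthed CD8-like response: clonal expansion to a peak
#' around day 7 followed by contraction, four fate branches committed at
#' activation (memory-, terminal-, early-effector- and intermediate-like),
#' a bounded spleen-to-tissue migration window on days 3-7 with
#' branch-specific egress schedules (memory-biased early entries,
#' terminal/early-effector-biased late entries), and marker-gene emission
#' for proliferation, apoptosis, residency, circulating, per-branch,
#' lineage-stable and transient-spike programs through a negative-binomial
#' observation model with lognormal library sizes. Snapshots are i.i.d.
#' subsamples per (day, compartment), emulating near-uniform sequencing
#' depth regardless of population size.
#'
#' Demographic rates are per-day piecewise-constant schedules;
#' \code{findInterval} semantics: \code{rates[k]} applies on days in
#' \code{[breaks[k-1], breaks[k])}. Emission reflects the rates of the
#' coming day (pre-apoptotic and proliferative programs precede the
#' demographic events they signal), which is exactly the role growth priors
#' play for the following transport interval.
#'
#' @param ... overrides for any default field.
#' @return A list of class "SimulationConfig".
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    days = c(0, 3, 4, 5, 7, 10, 14, 28),
    nFounders = 300L,
    cellsPerSnapshot = 300L,
    branches = c("memory", "terminal", "earlyeff", "intermediate"),
    branchProbs = c(0.25, 0.25, 0.25, 0.25),
    birthBreaks = c(1, 3, 5, 8), birthRates = c(0.3, 0.5, 0.9, 0.4, 0.05),
    deathBreaks = c(8, 11, 15), deathRates = c(0.05, 0.35, 0.20, 0.08),
    birthMod = c(memory = 0.95, terminal = 1.0, earlyeff = 1.1,
                 intermediate = 1.0),
    deathMod = c(memory = 0.7, terminal = 1.2, earlyeff = 1.35,
                 intermediate = 0.9),
    migrationWindow = c(3, 7),
    egressSplitDay = 4,
    egressEarly = c(memory = 0.30, terminal = 0.06, earlyeff = 0.05,
                    intermediate = 0.22),
    egressLate = c(memory = 0.06, terminal = 0.22, earlyeff = 0.28,
                   intermediate = 0.08),
    returnRate = 0,
    maxTransitions = 1L,
    nHousekeeping = 500L, nMito = 10L,
    nProlif = 60L, nApop = 60L, nResidency = 80L, nCirculating = 80L,
    nMarkerPerBranch = 30L, nLineageStable = 30L, nTransient = 30L,
    libMeanlog = log(12000), libSdlog = 0.25, nbSize = 10,
    maxCells = 50000L)
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, user), class = "SimulationConfig")
}

rateAt <- function(day, breaks, rates) rates[findInterval(day, breaks) + 1]

## branch-differential survival acts during expansion/contraction; late
## memory homeostasis is uniform across branches
effDeathMod <- function(cfg, day, branch) {
  if (day >= cfg$deathBreaks[length(cfg$deathBreaks)])
    rep(1, length(branch))
  else unname(cfg$deathMod[branch])
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Benchmark state-annotation masks
#'
#' Day windows within which each branch label is applied, mirroring how
#' state nomenclature is time-restricted in the field: memory labels only
#' from day 7, terminal from day 5, early-effector up to day 10,
#' intermediate from day 3.
#'
#' @return Named list of \code{c(dayMin, dayMax)} windows for
#'   \code{\link{assignStates}}.
#' @export
benchmarkMasks <- function() list(
  memory = c(7, Inf), terminal = c(5, Inf),
  earlyeff = c(0, 10), intermediate = c(3, Inf))

## deterministic gene model given the RNG state
buildGeneModel <- function(cfg) {
  prog <- c(rep("housekeeping", cfg$nHousekeeping),
            rep("mito", cfg$nMito),
            rep("proliferation", cfg$nProlif),
            rep("apoptosis", cfg$nApop),
            rep("residency", cfg$nResidency),
            rep("circulating", cfg$nCirculating),
            unlist(lapply(cfg$branches, function(b)
              rep(paste0("marker.", b), cfg$nMarkerPerBranch))),
            rep("lineage_stable", cfg$nLineageStable),
            rep("transient_spike", cfg$nTransient))
  n <- length(prog)
  idx <- stats::ave(seq_len(n), prog, FUN = seq_along)
  gene <- ifelse(prog == "mito", sprintf("mt-g%02d", idx),
                 sprintf("%s_g%03d", sub("\\.", "_", prog), idx))
  base <- stats::runif(n, 0.4, 1.6)
  ## neutral background spans the full expression range so binned control
  ## draws are dominated by non-program genes at every level
  hk <- prog == "housekeeping"
  base[hk] <- stats::rlnorm(sum(hk), log(1.2), 0.7)
  base[prog == "mito"] <- 2.4
  ## well-expressed growth programs: score noise must not drown the
  ## between-timepoint signal the marginals are calibrated on
  base[prog %in% c("proliferation", "apoptosis")] <- 1.6
  ## compartment programs start low so their pooled means bin with the
  ## mid-level background rather than with the growth programs
  base[prog %in% c("residency", "circulating")] <- 0.3
  spikeDay <- rep(NA_real_, n)
  tr <- which(prog == "transient_spike")
  spikeDay[tr] <- sample(cfg$days[-1], length(tr), replace = TRUE)
  data.frame(gene = gene, program = prog, base = base, spikeDay = spikeDay,
             stringsAsFactors = FALSE)
}

## emit a negative-binomial count snapshot for a set of cells at one day
emitCounts <- function(gm, cfg, day, branch, comp, arrival, u,
                       nextBirth, nextDeath) {
  n <- length(branch)
  mult <- matrix(1, nrow(gm), n)
  act <- min(1, day / 2)
  ramp <- clamp01((day - 1) / 4)
  res <- ifelse(comp == "siIEL", clamp01(0.2 + (day - arrival) / 3), 0)
  circ <- act * (1 - res)
  pr <- gm$program
  mult[pr == "proliferation", ] <-
    rep(1 + 4 * nextBirth / 0.9, each = sum(pr == "proliferation"))
  mult[pr == "apoptosis", ] <-
    rep(1 + 4 * nextDeath / 0.45, each = sum(pr == "apoptosis"))
  mult[pr == "residency", ] <- rep(1 + 7 * res, each = sum(pr == "residency"))
  mult[pr == "circulating", ] <-
    rep(1 + 4 * circ, each = sum(pr == "circulating"))
  for (b in cfg$branches) {
    rows <- pr == paste0("marker.", b)
    mult[rows, ] <- rep(1 + 2.5 * ramp * (branch == b), each = sum(rows))
  }
  mult[pr == "lineage_stable", ] <-
    rep(0.25 + 2.5 * u, each = sum(pr == "lineage_stable"))
  trRows <- which(pr == "transient_spike")
  mult[trRows, ] <- 1 + 5 * as.numeric(gm$spikeDay[trRows] == day)
  lambda <- gm$base * mult
  lib <- stats::rlnorm(n, cfg$libMeanlog, cfg$libSdlog)
  mu <- sweep(lambda, 2, lib / colSums(lambda), "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                               size = cfg$nbSize), nrow(gm), n)
  rownames(cnt) <- gm$gene
  cnt
}

#' Simulate a ground-truthed two-compartment time course
#'
#' Runs the branching birth-death-migration process of
#' \code{\link{simulationConfig}} day by day and emits count snapshots at
#' the configured days. Per-cell ground truth records lineage, committed
#' branch, compartment, tissue arrival day and the demographic rates of the
#' coming day; the population series records the true total and per-branch
#' sizes every day.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param seed RNG seed; identical seeds give bitwise-identical output.
#' @return list with \code{tc} (raw-count \linkS4class{TimeCourse}),
#'   \code{truth} (list: \code{cells} data.frame, \code{population}
#'   data.frame, \code{geneModel}, \code{config}).
#' @export
simulateTimecourse <- function(cfg = simulationConfig(), seed = 1L) {
  set.seed(seed)
  gm <- buildGeneModel(cfg)
  nF <- cfg$nFounders
  branch <- sample(cfg$branches, nF, replace = TRUE, prob = cfg$branchProbs)
  u <- stats::runif(nF)
  comp <- rep("spleen", nF)
  arrival <- rep(NA_real_, nF)
  lineage <- seq_len(nF)
  transitions <- integer(nF)

  maxDay <- max(cfg$days)
  branchCounts <- function()
    as.integer(table(factor(branch, levels = cfg$branches)))
  pop <- list(c(0, nF, branchCounts()))
  snaps <- list(); truthRows <- list(); cellCounter <- 0L

  takeSnapshot <- function(day) {
    for (cp in unique(comp)) {
      idx <- which(comp == cp)
      k <- min(cfg$cellsPerSnapshot, length(idx))
      if (k == 0) next
      pick <- if (length(idx) > k) sample(idx, k) else idx
      nb <- rateAt(day + 1, cfg$birthBreaks, cfg$birthRates) *
        cfg$birthMod[branch[pick]]
      nd <- rateAt(day + 1, cfg$deathBreaks, cfg$deathRates) *
        effDeathMod(cfg, day + 1, branch[pick])
      cnt <- emitCounts(gm, cfg, day, branch[pick], comp[pick],
                        arrival[pick], u[pick], nb, nd)
      ids <- sprintf("d%g_%s_%06d", day, cp,
                     cellCounter + seq_along(pick))
      cellCounter <<- cellCounter + length(pick)
      colnames(cnt) <- ids
      snaps[[length(snaps) + 1]] <<- list(
        counts = cnt, day = day, comp = cp, ids = ids)
      truthRows[[length(truthRows) + 1]] <<- data.frame(
        cell = ids, day = day, compartment = cp, branch = branch[pick],
        lineage = lineage[pick], arrival = arrival[pick],
        nextBirth = unname(nb), nextDeath = unname(nd),
        gTrueNext = unname((2 - exp(-nb)) * exp(-nd)))
    }
  }

  if (0 %in% cfg$days) takeSnapshot(0)

  for (d in seq_len(maxDay)) {
    b <- rateAt(d, cfg$birthBreaks, cfg$birthRates) * cfg$birthMod[branch]
    dd <- rateAt(d, cfg$deathBreaks, cfg$deathRates) * effDeathMod(cfg, d, branch)
    survive <- stats::runif(length(branch)) >= (1 - exp(-dd))
    branch <- branch[survive]; u <- u[survive]; comp <- comp[survive]
    arrival <- arrival[survive]; lineage <- lineage[survive]
    transitions <- transitions[survive]
    if (length(branch) == 0)
      stop("population went extinct before the final day; ",
           "lower the death rates")
    b <- b[survive]
    divide <- stats::runif(length(branch)) < (1 - exp(-b))
    if (any(divide)) {
      branch <- c(branch, branch[divide]); u <- c(u, u[divide])
      comp <- c(comp, comp[divide]); arrival <- c(arrival, arrival[divide])
      lineage <- c(lineage, lineage[divide])
      transitions <- c(transitions, transitions[divide])
    }
    if (length(branch) > cfg$maxCells)
      stop("population exceeded maxCells; lower the birth rates")
    if (d > cfg$migrationWindow[1] && d <= cfg$migrationWindow[2]) {
      rate <- if (d <= cfg$egressSplitDay) cfg$egressEarly else cfg$egressLate
      canGo <- comp == "spleen" & transitions < cfg$maxTransitions
      go <- canGo & stats::runif(length(branch)) < rate[branch]
      comp[go] <- "siIEL"; arrival[go] <- d
      transitions[go] <- transitions[go] + 1L
      if (cfg$returnRate > 0) {
        canBack <- comp == "siIEL" & transitions < cfg$maxTransitions &
          arrival < d
        back <- canBack & stats::runif(length(branch)) < cfg$returnRate
        comp[back] <- "spleen"; transitions[back] <- transitions[back] + 1L
      }
    }
    pop[[length(pop) + 1]] <- c(d, length(branch), branchCounts())
    if (d %in% cfg$days) takeSnapshot(d)
  }

  counts <- do.call(cbind, lapply(snaps, `[[`, "counts"))
  dayv <- unlist(lapply(snaps, function(s) rep(s$day, length(s$ids))))
  compv <- unlist(lapply(snaps, function(s) rep(s$comp, length(s$ids))))
  tc <- TimeCourse(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "CsparseMatrix"),
                   timepoint = dayv, compartment = compv)
  popdf <- as.data.frame(do.call(rbind, pop))
  colnames(popdf) <- c("day", "N", cfg$branches)
  list(tc = tc,
       truth = list(cells = do.call(rbind, truthRows), population = popdf,
                    geneModel = gm, config = cfg))
}

#' Planted program gene lists
#'
#' Returns the gene lists matching the simulator's emission model
#' (proliferation, apoptosis, residency, circulating, per-branch markers,
#' lineage-stable, transient-spike). The lists partition their gene ids.
#'
#' @param truth the \code{truth} element of \code{\link{simulateTimecourse}}.
#' @return Named list of character vectors.
#' @export
plantedGeneSets <- function(truth) {
  gm <- truth$geneModel
  progs <- setdiff(unique(gm$program), c("housekeeping", "mito"))
  stats::setNames(lapply(progs, function(p) gm$gene[gm$program == p]), progs)
}

#' Planted pairwise state gene lists
#'
#' Builds ordered-pair lists \code{"A/B"} (genes up in branch A versus
#' branch B) from the planted branch markers, the input format of
#' \code{\link{compositeScores}}.
#'
#' @param truth the \code{truth} element of \code{\link{simulateTimecourse}}.
#' @return Named list of character vectors keyed "A/B".
#' @export
plantedPairLists <- function(truth) {
  gm <- truth$geneModel
  branches <- truth$config$branches
  out <- list()
  for (A in branches) for (B in setdiff(branches, A))
    out[[paste(A, B, sep = "/")]] <- gm$gene[gm$program == paste0("marker.", A)]
  out
}

#' Default ground-truthed benchmark
#'
#' A fixed small benchmark: 8 days (0, 3, 4, 5, 7, 10, 14, 28), two
#' compartments, four fate branches, migration window days 3-7, about 300
#' sampled cells per (day, compartment) and 600 genes. Reproducible bitwise
#' under a fixed seed.
#'
#' @param seed RNG seed.
#' @return As \code{\link{simulateTimecourse}}, plus \code{sets} (planted
#'   program lists) and \code{pairs} (planted pairwise lists).
#' @export
defaultBenchmark <- function(seed = 1L) {
  sim <- simulateTimecourse(simulationConfig(), seed = seed)
  sim$sets <- plantedGeneSets(sim$truth)
  sim$pairs <- plantedPairLists(sim$truth)
  sim$masks <- benchmarkMasks()
  sim
}
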