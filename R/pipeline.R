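#' Pipeline run configuration
#'
#' All stage parameters with their defaults, including the transport presets
#' for the three model variants: "spleen" and "siIEL" (single compartment:
#' epsilon 0.01, tauA 0.95, tauB 0.9995) and "combined" (two compartments
#' with equal-size subsampling: epsilon 0.05, tauA 0.95, tauB 0.95).
#' Unknown keys are rejected.
#'
#' @param preset "spleen", "siIEL" or "combined".
#' @param ... overrides for any default field.
#' @return A list of class "RunConfig".
#' @export
runConfig <- function(preset = c("spleen", "siIEL", "combined"), ...) {
  preset <- match.arg(preset)
  combined <- preset == "combined"
  cfg <- list(
    preset = preset,
    maxMitoFrac = 0.10, minCounts = 1500, minCellsPerGene = 2,
    targetSum = 1e6, nHVG = 3000,
    epsilon = if (combined) 0.05 else 0.01,
    tauA = 0.95, tauB = if (combined) 0.95 else 0.9995,
    maxIters = 10000L, tol = 1e-6,
    localComponents = 50L, globalComponents = 30L,
    prolifGenes = NULL, apopGenes = NULL, gmax = 8,
    N0 = 1000,
    kernelDim = 50L, afterDay = 6,
    clusterMethod = "leiden", k = 4L, resolution = 1, knn = 15L,
    topKGenes = 100L,
    queryDay = NULL, queryCompartment = "siIEL",
    seed = 1L)
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  structure(utils::modifyList(cfg, user, keep.null = FALSE),
            class = "RunConfig")
}

#' Run the end-to-end fate-mapping pipeline
#'
#' Orchestrates preprocess (filters, normalization, HVG, global PCA), growth
#' marginals, transport-map fitting (with equal-size compartment subsampling
#' for the combined preset), trajectory gene correlations, TKME embedding
#' and clustering, per-interval cluster consistency, population kinetics,
#' and - for the combined preset - egress probabilities and arrival times.
#' All tables are written as CSV under \code{outDir} together with a
#' machine-readable provenance manifest (package version, seed, config, file
#' hashes); a rerun with the same seed reproduces identical hashes.
#'
#' @param tc a raw-count \linkS4class{TimeCourse}.
#' @param config a \code{\link{runConfig}}.
#' @param outDir output directory (created).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
runPipeline <- function(tc, config = runConfig(), outDir = tempfile("fateflow_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$prolifGenes) || is.null(config$apopGenes))
    stop("config must provide prolifGenes and apopGenes")

  ## --- preprocess ---
  tc <- filterCells(tc, config$maxMitoFrac, config$minCounts)
  tc <- filterGenes(tc, config$minCellsPerGene)
  tc <- normalizeLog1p(tc, config$targetSum)
  hvg <- selectHVG(tc, min(config$nHVG, nrow(tc)))
  if (config$preset == "combined") {
    if (is.null(tc$compartment))
      stop("combined preset requires compartment labels")
    tc <- subsampleEqualCompartments(tc, seed = config$seed)
  }
  gb <- fitBasis(tc, "global_pca",
                 nComponents = min(config$globalComponents,
                                   length(hvg), ncol(tc)) , hvg = hvg)

  ## --- marginals ---
  priors <- timecourseGrowthPriors(tc, config$prolifGenes, config$apopGenes,
                                   gmax = config$gmax, seed = config$seed)
  popn <- populationSizes(priors, N0 = config$N0)

  ## --- transport maps ---
  sc <- solverConfig(config$epsilon, config$tauA, config$tauB,
                     config$maxIters, config$tol, scaleCost = TRUE)
  maps <- fitTimecourseMaps(tc, priors = priors, config = sc, hvg = hvg,
                            nComponents = min(config$localComponents,
                                              length(hvg)))

  ## --- trajectories ---
  corr <- trajectoryGeneCorrelations(tc, maps, genes = hvg,
                                     topK = config$topKGenes)
  ctp <- stats::setNames(tc$timepoint, colnames(tc))
  Z <- tkmeEmbed(gb@coords, ctp, maps, d = config$kernelDim,
                 includeDaysAfter = config$afterDay, seed = config$seed)
  labels <- clusterTrajectories(Z, method = config$clusterMethod,
                                k = config$k, resolution = config$resolution,
                                knn = config$knn, seed = config$seed)
  cons <- trajectoryClusterConsistency(labels, maps)
  kin <- clusterPopulationKinetics(
    popn, split(as.character(labels), ctp[names(labels)]))

  res <- list(timecourse = tc, hvg = hvg, priors = priors,
              population = popn, maps = maps, correlations = corr,
              embedding = Z, labels = labels, consistency = cons,
              kinetics = kin)

  ## --- migration (combined preset) ---
  if (config$preset == "combined") {
    comps <- stats::setNames(tc$compartment, colnames(tc))
    eg <- lapply(maps, function(m) {
      rsm <- rowNormalize(m)
      egressProbabilities(rsm, comps[m@sourceIds], comps[m@targetIds])
    })
    res$egress <- eg
    qd <- config$queryDay
    if (is.null(qd)) qd <- max(timepoints(tc)[timepoints(tc) <= 7])
    res$arrival <- arrivalTimes(maps, comps, qd, config$queryCompartment)
  }

  ## --- outputs + manifest ---
  paths <- c(
    labels = file.path(outDir, "trajectory_labels.csv"),
    population = file.path(outDir, "population.csv"),
    correlations = file.path(outDir, "gene_correlations.csv"),
    consistency = file.path(outDir, "consistency.csv"),
    kinetics = file.path(outDir, "cluster_kinetics.csv"))
  utils::write.csv(data.frame(cell = names(labels), day = ctp[names(labels)],
                              cluster = as.character(labels)),
                   paths["labels"], row.names = FALSE)
  utils::write.csv(popn, paths["population"], row.names = FALSE)
  utils::write.csv(data.frame(gene = names(corr$median),
                              median_rho = corr$median,
                              top = names(corr$median) %in% corr$top),
                   paths["correlations"], row.names = FALSE)
  utils::write.csv(res$consistency, paths["consistency"], row.names = FALSE)
  utils::write.csv(kin, paths["kinetics"], row.names = FALSE)
  if (config$preset == "combined") {
    p <- file.path(outDir, "egress.csv")
    eg <- do.call(rbind, lapply(names(res$egress), function(nm)
      cbind(interval = nm, res$egress[[nm]])))
    utils::write.csv(eg, p, row.names = FALSE)
    paths["egress"] <- p
    p <- file.path(outDir, "arrival.csv")
    utils::write.csv(res$arrival, p, row.names = FALSE)
    paths["arrival"] <- p
  }
  manifest <- list(
    package = "fateflow",
    version = as.character(utils::packageVersion("fateflow")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config),
                                     c("prolifGenes", "apopGenes"))],
    n_cells = ncol(tc), n_genes = nrow(tc),
    cells_per_timepoint = as.list(table(tc$timepoint)),
    files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$paths <- c(paths, manifest = file.path(outDir, "manifest.json"))
  invisible(res)
}
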