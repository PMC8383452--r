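#' Run the full small-area analysis pipeline
#'
#' Orchestrates, per risk level, the study workflow: crude SIR table
#' (always) -> Global Moran permutation test -> if significant (the
#' clustering gate), Local Moran / LISA and the Kulldorff scan -> BYM null
#' model and one-covariate ("unconditional") ecological models (always),
#' each with a convergence-diagnostics report. All randomness funnels
#' through \code{seed}; re-running with the same inputs reproduces every
#' output.
#'
#' @param region A [StudyRegion-class] or a path to the area-attribute CSV.
#' @param outDir Output directory (created if needed).
#' @param levels Risk levels to analyse (default all four).
#' @param radiusKm Distance band for both the Moran weights and the CAR
#'   adjacency (default 120).
#' @param nPerm Moran permutations (default 999).
#' @param alpha Significance level of the clustering gate (default 0.05).
#' @param maxPopFraction Named per-level maximum scan-window population
#'   fraction; defaults 0.30 for metastatic and 0.25 otherwise.
#' @param nReps Scan Monte-Carlo replicates (default 999).
#' @param covariates rowData columns used (one model per covariate);
#'   default \code{"phys_density"}.
#' @param mcmc List with \code{nChains}, \code{nIterations}, \code{burnIn},
#'   \code{thin}.
#' @param seed Master seed.
#' @param forceClustering Run LISA/scan regardless of the gate.
#' @return Invisibly, a list with per-level results (\code{sir},
#'   \code{moran}, \code{lisa}, \code{scan}, \code{bym} fits and
#'   diagnostics) plus \code{outDir} and the manifest.
#' @examples
#' \donttest{
#' reg <- generateRegion(syntheticScenario(nAreas = 20, seed = 1))
#' run <- runPipeline(reg, tempfile("run"), levels = "high",
#'                    nPerm = 99, nReps = 99,
#'                    mcmc = list(nChains = 2, nIterations = 1500,
#'                                burnIn = 500, thin = 5))
#' summarizeTables(run)
#' }
#' @export
runPipeline <- function(region, outDir, levels = riskLevels(),
                        radiusKm = 120, nPerm = 999, alpha = 0.05,
                        maxPopFraction = c(metastatic = 0.30, high = 0.25,
                                           intermediate = 0.25, low = 0.25),
                        nReps = 999, covariates = "phys_density",
                        mcmc = list(nChains = 3, nIterations = 30000,
                                    burnIn = 10000, thin = 10),
                        seed = 1L, forceClustering = FALSE) {
  if (is.character(region)) region <- readRegionCSV(region)
  stopifnot(is(region, "StudyRegion"))
  if (!length(levels)) stop("no risk levels requested")
  levels <- match.arg(levels, riskLevels(), several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  stageSeeds <- matrix(sample.int(.Machine$integer.max,
                                  4L * length(riskLevels())),
                      nrow = 4L,
                      dimnames = list(c("moran", "lisa", "scan", "bym"),
                                      riskLevels()))
  keep <- populations(region) > 0
  W <- spatialWeights(region, radiusKm = radiusKm)
  adj <- binaryAdjacency(W)
  pop <- populations(region)[keep]
  ids <- areaIds(region)[keep]
  xy <- centroids(region)[keep, , drop = FALSE]
  rownames(xy) <- ids
  results <- list()
  for (lv in levels) {
    res <- list()
    obs <- as.numeric(assay(region, "counts")[keep, lv])
    expd <- expectedCounts(pop, obs)
    sir <- crudeSIR(obs, expd)
    res$sir <- sirTable(region, lv)
    writeSIRTable(res$sir, file.path(outDir, paste0("sir_", lv, ".csv")))
    res$moran <- globalMoranTest(sir, W, nPerm = nPerm,
                                 seed = stageSeeds["moran", lv])
    gate <- res$moran@pseudoP <= alpha || forceClustering
    res$gateOpen <- gate
    if (gate) {
      res$lisa <- lisaClassify(sir, W, nPerm = nPerm, alpha = alpha,
                               seed = stageSeeds["lisa", lv])
      writeLisaTable(res$lisa, file.path(outDir, paste0("lisa_", lv, ".csv")),
                     global = res$moran)
      win <- enumerateWindows(xy, pop, maxPopFraction[[lv]], ids = ids)
      res$scan <- kulldorffScan(obs, expd, win, nReps = nReps,
                                seed = stageSeeds["scan", lv])
      writeScanTable(res$scan, file.path(outDir, paste0("scan_", lv, ".csv")))
      writeClusterCirclesGeoJSON(res$scan, region,
                                 file.path(outDir,
                                           paste0("scan_", lv, ".geojson")))
    }
    ## BYM null model + one model per covariate (never gated)
    res$bym <- runBYM(obs, expd, adj, nChains = mcmc$nChains,
                      nIterations = mcmc$nIterations, burnIn = mcmc$burnIn,
                      thin = mcmc$thin, seed = stageSeeds["bym", lv])
    res$bymDiagnostics <- diagnosticsReport(res$bym)
    writeDiagnostics(res$bymDiagnostics,
                     file.path(outDir, paste0("diagnostics_", lv, "_null.csv")))
    sm <- smoothedSIR(res$bym)
    smQ <- apply(res$bym@theta, 2, stats::quantile, c(0.025, 0.975))
    areaTab <- data.frame(area_id = ids, crude_sir = sir,
                          smoothed_sir = sm, cri_lower = smQ[1, ],
                          cri_upper = smQ[2, ])
    utils::write.csv(areaTab, file.path(outDir, paste0("bym_", lv, ".csv")),
                     row.names = FALSE)
    res$bymArea <- areaTab
    res$ecological <- list()
    for (cv in covariates) {
      x <- as.numeric(rowData(region)[[cv]])[keep]
      fit <- runBYM(obs, expd, adj, covariate = x, covariateName = cv,
                    nChains = mcmc$nChains, nIterations = mcmc$nIterations,
                    burnIn = mcmc$burnIn, thin = mcmc$thin,
                    seed = stageSeeds["bym", lv] %% 2147483000L + 1L)
      ir <- irrSummary(fit)
      modelTab <- data.frame(
        parameter = cv, mean = ir$betaMean,
        cri_lower = ir$betaCri[1], cri_upper = ir$betaCri[2],
        irr = ir$irr, irr_lower = ir$cri[1], irr_upper = ir$cri[2],
        significant = ir$significant)
      utils::write.csv(modelTab,
                       file.path(outDir,
                                 paste0("model_", lv, "_", cv, ".csv")),
                       row.names = FALSE)
      writeDiagnostics(diagnosticsReport(fit),
                       file.path(outDir,
                                 paste0("diagnostics_", lv, "_", cv, ".csv")))
      res$ecological[[cv]] <- list(fit = fit, table = modelTab)
    }
    results[[lv]] <- res
  }
  manifest <- list(package = "sirbym",
                   version = as.character(utils::packageVersion("sirbym")),
                   seed = seed, levels = levels, radiusKm = radiusKm,
                   nPerm = nPerm, alpha = alpha, nReps = nReps,
                   maxPopFraction = as.list(maxPopFraction),
                   covariates = covariates, mcmc = mcmc,
                   nAreas = nrow(region))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(levels = results, outDir = outDir, manifest = manifest,
              region = region)
  invisible(out)
}

#' Summary tables for a pipeline run
#'
#' Builds the four report-style tables from a [runPipeline()] result and
#' writes them as CSVs into the run directory: per-level SIR bin counts,
#' Global Moran / LISA cluster counts, crude-vs-smoothed SIR min/max, and
#' the ecological coefficient/IRR/CrI table (flagged "Not significant"
#' exactly when the IRR CrI spans 1).
#'
#' @param run Result of [runPipeline()].
#' @return Named list of data.frames: \code{bins}, \code{moran},
#'   \code{ranges}, \code{ecological}.
#' @export
summarizeTables <- function(run) {
  lv <- names(run$levels)
  bins <- do.call(rbind, lapply(lv, function(l) {
    tb <- table(run$levels[[l]]$sir$bin)
    data.frame(risk_level = l, bin = names(tb), areas = as.integer(tb))
  }))
  moran <- do.call(rbind, lapply(lv, function(l) {
    r <- run$levels[[l]]
    row <- data.frame(risk_level = l, global_moran_I = r$moran@I,
                      pseudo_p = r$moran@pseudoP,
                      significant = r$moran@pseudoP <= run$manifest$alpha)
    counts <- if (!is.null(r$lisa)) table(r$lisa@table$cluster) else
      stats::setNames(rep(NA_integer_, 5), levels(factor(character(),
                                                         .LISA_LABELS)))
    for (nm in .LISA_LABELS) row[[nm]] <- as.integer(counts[[nm]])
    row
  }))
  ranges <- do.call(rbind, lapply(lv, function(l) {
    r <- run$levels[[l]]
    data.frame(risk_level = l,
               crude_min = min(r$bymArea$crude_sir, na.rm = TRUE),
               crude_max = max(r$bymArea$crude_sir, na.rm = TRUE),
               smoothed_min = min(r$bymArea$smoothed_sir),
               smoothed_max = max(r$bymArea$smoothed_sir))
  }))
  ecological <- do.call(rbind, lapply(lv, function(l) {
    do.call(rbind, lapply(run$levels[[l]]$ecological, function(e) {
      cbind(data.frame(risk_level = l), e$table,
            data.frame(label = if (e$table$significant)
              sprintf("%.3f (%.3f to %.3f)", e$table$irr, e$table$irr_lower,
                      e$table$irr_upper) else "Not significant"))
    }))
  }))
  out <- list(bins = bins, moran = moran, ranges = ranges,
              ecological = ecological)
  for (nm in names(out))
    utils::write.csv(out[[nm]],
                     file.path(run$outDir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  out
}
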