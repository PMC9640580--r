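#' Run the end-to-end SCE pipeline on synthetic data
#'
#' Chains the stages of the SCE analysis: simulate a genome and a set of
#' Strand-seq libraries with planted SCEs, localize SCEs per library,
#' remove clonal (recurrent) events, test the pooled calls for feature
#' enrichment with the circular-shift permutation model, and report
#' hotspots. Every stage's record counts, the thresholds in force and
#' the output checksums are collected into a run manifest; re-running
#' with the same seed reproduces the outputs byte-identically.
#'
#' @param outDir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param nLibraries Number of single-cell libraries to simulate.
#' @param genomeSize,gapFraction Genome parameters.
#' @param nSCEsPerLibrary,depth,flipErrorRate,dupRate,mapqLowRate
#'   Library simulation parameters.
#' @param nFeatures,featureLength Feature-track parameters for the
#'   enrichment stage.
#' @param sceParam An [SCEParam-class].
#' @param permParam A [PermParam-class].
#' @return A list with `manifest`, `events` (non-recurrent pooled calls),
#'   `permResult`, `hotspots`, and per-library evaluation against truth.
#' @export
runSCEPipeline <- function(outDir, seed, nLibraries = 10L,
                           genomeSize = 1e8, gapFraction = 0.05,
                           nSCEsPerLibrary = 5L, depth = 200,
                           flipErrorRate = 0.02, dupRate = 0.05,
                           mapqLowRate = 0.05, nFeatures = 50L,
                           featureLength = 1e5,
                           sceParam = SCEParam(),
                           permParam = PermParam()) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    genome <- simulateGenome(1L, genomeSize, gapFraction,
                             seed = childSeed(seed, 0L))
    genomePaths <- writeGenome(genome, outDir)
    track <- simulateFeatureTrack(genome, nFeatures, featureLength,
                                  name = "feature",
                                  seed = childSeed(seed, 1L))
    eventList <- list()
    counts <- list()
    truthBP <- list()
    for (i in seq_len(nLibraries)) {
        libId <- sprintf("lib%03d", i)
        sim <- simulateStrandSeqLibrary(
            genome, nSCEs = nSCEsPerLibrary, depth = depth,
            flipErrorRate = flipErrorRate, dupRate = dupRate,
            mapqLowRate = mapqLowRate,
            seed = childSeed(seed, 1L + i), libraryId = libId)
        res <- callSCEsFromReads(sim$reads, sceParam, libId)
        eventList[[libId]] <- res$events
        counts[[libId]] <- res$counts
        truthBP[[libId]] <- sim$truth$breakpoints
    }
    allEvents <- suppressWarnings(do.call(c, unname(eventList)))
    clonal <- filterClonalEvents(allEvents, nLibraries)
    events <- clonal$nonRecurrent
    eventsPath <- file.path(outDir, "sce_events.bed")
    writeBED(events, eventsPath)
    permResult <- runPermutationTest(
        events, track, genome, permParam,
        seed = childSeed(seed, 10000L), featureName = "feature")
    reportPath <- file.path(outDir, "permtest.tsv")
    utils::write.table(permReport(list(permResult)), reportPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hotspots <- findHotspots(events)
    truthAll <- do.call(rbind, truthBP)
    evalAll <- evaluateSCECalls(events, truthAll)
    manifest <- runManifest(
        config = list(seed = seed, nLibraries = nLibraries,
                      genomeSize = genomeSize,
                      gapFraction = gapFraction,
                      nSCEsPerLibrary = nSCEsPerLibrary,
                      depth = depth, flipErrorRate = flipErrorRate,
                      dupRate = dupRate, mapqLowRate = mapqLowRate,
                      minMapq = sceParam@minMapq,
                      minSupport = sceParam@minSupport,
                      flipWindow = sceParam@flipWindow,
                      segAlpha = sceParam@segAlpha,
                      nPerm = permParam@nPerm,
                      sizeCutoff = permParam@sizeCutoff),
        counts = c(list(plantedSCEs = nrow(truthAll),
                        calledEvents = length(allEvents),
                        clonalEvents = length(clonal$recurrent),
                        nonRecurrentEvents = length(events),
                        hotspots = length(hotspots)),
                   counts),
        files = c(genomePaths, events = eventsPath,
                  permtest = reportPath))
    writeManifest(manifest, file.path(outDir, "manifest.txt"))
    list(manifest = manifest, events = events,
         permResult = permResult, hotspots = hotspots,
         evaluation = evalAll, truth = truthAll)
}

#' Run the deletion/microhomology pipeline on synthetic data
#'
#' Simulates a genome with sequence and a CFS track, plants a deletion
#' cohort with group-specific CFS containment and junction
#' microhomology, recomputes containment and microhomology from the
#' emitted data, and compares the HRD and HRP groups.
#'
#' @param outDir Output directory.
#' @param seed Integer seed.
#' @param genomeSize,nCFS,cfsLength Genome and CFS-track parameters.
#' @param withSequence Plant junctions in sequence and recompute MH from
#'   it (small cohorts), or carry planted MH lengths (large cohorts)?
#' @param ... Passed to [simulateDeletionCohort()].
#' @return A list with `manifest`, the annotated deletion table, and
#'   the [CohortComparison-class] report.
#' @export
runDeletionPipeline <- function(outDir, seed, genomeSize = 2e7,
                                nCFS = 8L, cfsLength = 5e5,
                                withSequence = TRUE, ...) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    genome <- simulateGenome(1L, genomeSize, gapFraction = 0,
                             seed = childSeed(seed, 0L),
                             withSequence = withSequence)
    cfs <- simulateFeatureTrack(genome, nCFS, cfsLength, name = "CFS",
                                seed = childSeed(seed, 1L))
    cfs <- prepareCFSTrack(cfs)
    cohort <- simulateDeletionCohort(genome, cfs,
                                     seed = childSeed(seed, 2L), ...)
    dels <- cohort$deletions
    dels$inCFS <- deletionInCFS(dels, cfs)
    if (withSequence) {
        # keep the planted value and recompute MH from the emitted
        # sequence; the two agree for every non-degenerate junction
        dels$mhPlanted <- dels$mhLength
        dels <- microhomologyLength(cohort$genome, dels)
    }
    comparison <- cohortCompare(dels)
    delPath <- file.path(outDir, "deletions.tsv")
    utils::write.table(dels, delPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- runManifest(
        config = c(list(seed = seed, genomeSize = genomeSize,
                        nCFS = nCFS, cfsLength = cfsLength,
                        mhMin = comparison@mhMin),
                   cohort$truth$params),
        counts = list(nDeletions = nrow(dels),
                      nInCFS = sum(dels$inCFS)),
        files = c(deletions = delPath))
    writeManifest(manifest, file.path(outDir, "manifest.txt"))
    list(manifest = manifest, deletions = dels,
         comparison = comparison, truth = cohort$truth)
}

# Assemble a run manifest: package version, configuration snapshot,
# per-stage record counts and md5 checksums of the written files.
runManifest <- function(config, counts, files) {
    files <- files[file.exists(unlist(files))]
    list(package = as.character(utils::packageVersion("sceScope")),
         config = config,
         counts = counts,
         checksums = tools::md5sum(unlist(files)))
}

writeManifest <- function(manifest, path) {
    flat <- function(x) vapply(x, function(v)
        paste(format(v, scientific = FALSE, trim = TRUE),
              collapse = ","), character(1))
    lines <- c(paste("package:", manifest$package), "[config]",
               paste0(names(manifest$config), ": ",
                      flat(manifest$config)),
               "[counts]",
               paste0(names(manifest$counts), ": ",
                      flat(manifest$counts)),
               "[checksums]",
               paste0(basename(names(manifest$checksums)), ": ",
                      manifest$checksums))
    writeLines(lines, path)
    invisible(path)
}
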