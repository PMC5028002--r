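## Orchestration of the two workflows and fixture materialization.
##
## The macaque arm: structural ratio map -> depth sampling -> top-third
## threshold -> contiguous-region area, optionally validated against a
## histology section series. The human arm: myelin-weighted map
## (mean + 1 SEM, exclusion honoured) -> functional hMT+/MST/V5-MT
## definitions -> overlap tables, permutation nulls and the threshold sweep.

resolveVolume <- function(x) {
  if (is.character(x)) readVolume(x) else x
}

resolveSurface <- function(x) {
  if (is.character(x)) readSurface(x) else x
}

writeReport <- function(report, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outDir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

#' Run the macaque structural workflow
#'
#' Builds the T1w/T2w ratio map from repeat scans, samples it onto the
#' surface (at a fixed depth fraction or the greatest-mean-intensity "auto"
#' choice over the 11-step grid), thresholds with the per-hemisphere
#' top-third rule, and measures the contiguous densely myelinated surface
#' area around a seed vertex. When a histology series is supplied, the
#' per-section myelinated lengths and trapezoid-aggregated area are added,
#' giving the two-method area pair.
#'
#' @param t1w,t2w \linkS4class{BrainVolume} (or lists of repeats, or file
#'   paths).
#' @param surface \linkS4class{CorticalSurface} or GIFTI path.
#' @param seedVertex 1-based vertex at the putative complex.
#' @param rule threshold rule (default \code{topFraction(1/3)}).
#' @param depth "auto" or a fixed depth fraction.
#' @param histology optional list with elements \code{series}
#'   (\linkS4class{SectionSeries} or directory), \code{pialTraces},
#'   \code{whiteTraces}, \code{stainThreshold} and optionally
#'   \code{deepFraction}.
#' @param outDir optional output directory for the JSON/TSV report.
#' @return report list with the chosen depth fraction, threshold, sMRI area,
#'   per-section lengths and histology area (when supplied).
#' @export
runMacaque <- function(t1w, t2w, surface, seedVertex,
                       rule = topFraction(1 / 3), depth = "auto",
                       histology = NULL, outDir = NULL) {
  surface <- resolveSurface(surface)
  t1w <- if (is.list(t1w)) lapply(t1w, resolveVolume) else resolveVolume(t1w)
  t2w <- if (is.list(t2w)) lapply(t2w, resolveVolume) else resolveVolume(t2w)
  ratio <- ratioMap(t1w, t2w)
  depthFraction <- if (identical(depth, "auto"))
    as.numeric(optimalDepthFraction(ratio, surface)) else depth
  map <- sampleToSurface(ratio, surface, depthFraction)
  mask <- thresholdMap(map, rule, surface)
  area <- contiguousRegionArea(mask, surface, seedVertex)
  report <- list(mode = "macaque", depthFraction = depthFraction,
                 threshold = attr(mask, "threshold"),
                 maskSize = maskSize(mask),
                 smriArea = as.numeric(area))
  if (!is.null(histology)) {
    series <- histology$series
    if (is.character(series)) series <- readSectionSeries(series)
    lengths <- seriesMyelinLengths(series, histology$stainThreshold,
                                   histology$pialTraces,
                                   histology$whiteTraces,
                                   deepFraction = histology$deepFraction %||%
                                     0.7)
    report$sectionLengths <- lengths
    report$histArea <- aggregateArea(lengths, series@spacing)
  }
  writeReport(report, outDir, "table1_areas")
  if (!is.null(outDir)) {
    df <- data.frame(measure = c("smriArea",
                                 if (!is.null(report$histArea)) "histArea"),
                     mm2 = c(report$smriArea, report$histArea))
    utils::write.table(df, file.path(outDir, "table1_areas.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  report
}

#' Run the human structural-functional comparison workflow
#'
#' Thresholds the myelin-weighted map at mean + 1 SEM (exclusion mask
#' honoured), defines hMT+ (full-field z-map clusters near the anchor), MST
#' (intersecting ipsilateral clusters, in full) and V5/MT (coherent
#' retinotopic voxels of hMT+ minus MST), then tabulates
#' percent-of-ROI-myelinated for the three ROIs with an intensity-shuffle
#' permutation null for hMT+, the whole-cortex correspondence against an
#' optional second structural map, and the structural x functional
#' threshold-sweep table.
#'
#' @param structMap myelin-weighted \linkS4class{VertexMap} (sampled).
#' @param surface parent \linkS4class{CorticalSurface}.
#' @param zmapFull,zmapIpsi z-stat \linkS4class{BrainVolume}s.
#' @param anchor world coordinate (mm) of the putative complex.
#' @param retino optional list(runs =, period =, coherence = 0.25).
#' @param structMap2 optional second \linkS4class{VertexMap} for
#'   between-scan correspondence.
#' @param rule structural rule (default \code{meanPlusKSEM(1)}).
#' @param cfg \code{\link{clusterConfig}} for the z-maps.
#' @param exclusionMask optional exclusion \linkS4class{IndexMask}.
#' @param depthFraction depth for voxel-to-surface ROI conversion; defaults
#'   to the map's own depth fraction (or 0.5).
#' @param nPerm permutations for the nulls.
#' @param seed RNG seed recorded in the report.
#' @param sweep compute the 4 x 4 threshold sweep (default TRUE).
#' @param outDir optional output directory.
#' @return report list (masks, tables, p-values, resolved config).
#' @export
runHuman <- function(structMap, surface, zmapFull, zmapIpsi, anchor,
                     retino = NULL, structMap2 = NULL,
                     rule = meanPlusKSEM(1), cfg = clusterConfig(),
                     exclusionMask = NULL, depthFraction = NULL,
                     nPerm = 1000L, seed = 0L, sweep = TRUE, outDir = NULL) {
  if (is.null(depthFraction))
    depthFraction <- if (!is.na(structMap@depthFraction))
      structMap@depthFraction else 0.5
  myelinMask <- thresholdMap(structMap, rule, surface, exclusionMask)
  hmt <- defineHMT(zmapFull, cfg, anchor)
  mst <- defineMST(hmt, zmapIpsi, cfg)
  report <- list(mode = "human", seed = seed,
                 rule = unclass(rule), zThreshold = cfg$zThreshold,
                 myelinThreshold = attr(myelinMask, "threshold"),
                 myelinSize = maskSize(myelinMask),
                 hmtSize = maskSize(hmt), mstSize = maskSize(mst))
  v5mt <- NULL
  if (!is.null(retino)) {
    rr <- fourierRetinotopy(retino$runs, retino$period)
    v5mt <- defineV5MT(rr, retino$coherence %||% 0.25, hmt, mst)
    report$v5mtSize <- maskSize(v5mt)
  }
  ## percent-of-ROI-myelinated table (Tables 4-5 analogue), on the surface
  rois <- list(hMT = hmt, MST = mst)
  if (!is.null(v5mt)) rois$V5MT <- v5mt
  overlap <- lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    if (!maskSize(m))
      return(data.frame(roi = nm, nVertices = 0L, pctMyelinated = NA_real_))
    sm <- maskToSurface(m, zmapFull, surface, depthFraction)
    if (!maskSize(sm))
      return(data.frame(roi = nm, nVertices = 0L, pctMyelinated = NA_real_))
    data.frame(roi = nm, nVertices = maskSize(sm),
               pctMyelinated = percent(percentRoiMyelinated(sm, myelinMask)))
  })
  report$table45 <- do.call(rbind, overlap)
  ## permutation null for the hMT+ percent-myelinated
  hmtSurf <- maskToSurface(hmt, zmapFull, surface, depthFraction)
  if (maskSize(hmtSurf)) {
    nullRes <- shuffleNull(structMap, NULL, rule, surface,
                           statistic = "pct_roi", roi = hmtSurf,
                           nPerm = nPerm, seed = seed,
                           exclusionMask = exclusionMask)
    report$pctHmtMyelinated <- nullRes@observed
    report$pctHmtNull <- list(p = nullRes@pValue,
                              nullMean = mean(nullRes@nullPercents),
                              null95 = unname(stats::quantile(
                                nullRes@nullPercents, 0.95)))
  }
  ## between-scan correspondence (Tables 2-3 analogue)
  if (!is.null(structMap2)) {
    m2 <- thresholdMap(structMap2, rule, surface, exclusionMask)
    wc <- wholeCortexCorrespondence(myelinMask, m2)
    nullWc <- shuffleNull(structMap, structMap2, rule, surface,
                          statistic = "whole_cortex", nPerm = nPerm,
                          seed = seed + 1L, exclusionMask = exclusionMask)
    report$table23 <- list(wholeCortex = percent(wc), p = nullWc@pValue,
                           chanceMean = mean(nullWc@nullPercents))
    if (maskSize(hmtSurf)) {
      rc <- roiCorrespondence(myelinMask, m2, hmtSurf)
      report$table23$roiHmt <- percent(rc)
    }
  }
  if (sweep) {
    sweepCfg <- cfg
    if (identical(sweepCfg$minExtent, "permutation"))
      sweepCfg$minExtent <- attr(extractClusters(zmapFull, cfg), "minExtent")
    report$sweep <- thresholdSweep(structMap, zmapFull, surface, anchor,
                                   cfg = sweepCfg,
                                   depthFraction = depthFraction,
                                   exclusionMask = exclusionMask)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$table45, file.path(outDir, "table45_overlap.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$sweep))
      utils::write.table(report$sweep, file.path(outDir, "sweep_fig8.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$table23))
      jsonlite::write_json(report$table23,
                           file.path(outDir, "table23_correspondence.json"),
                           auto_unbox = TRUE, digits = 10)
    labels <- array(0, dim(zmapFull@data))
    if (!is.null(v5mt)) labels[maskIndices(v5mt)] <- 1
    labels[maskIndices(mst)] <- 2
    other <- setdiff(maskIndices(hmt),
                     union(if (is.null(v5mt)) integer(0) else
                       maskIndices(v5mt), maskIndices(mst)))
    labels[other] <- pmax(labels[other], 3)
    writeVolume(brainVolume(labels, zmapFull@voxelSize, zmapFull@transform,
                            zmapFull@spaceTag),
                file.path(outDir, "roi_labels.nii.gz"))
    writeReport(report[setdiff(names(report), c("sweep", "table45"))],
                outDir, "provenance")
  }
  report$masks <- list(myelin = myelinMask, hmt = hmt, mst = mst,
                       v5mt = v5mt)
  report
}

#' Materialize a named phantom fixture set on disk
#'
#' Generates a phantom from the spec and writes the surface (GIFTI), the
#' structural T1w/T2w and z-stat volumes (NIfTI), the retinotopy run
#' (NIfTI, optional), the histology series (ASCII PGM + JSON sidecar) and a
#' JSON ground-truth/metadata record.
#'
#' @param dir output directory.
#' @param spec a \linkS4class{PhantomSpec}.
#' @param retinotopy also render the (large) 4D retinotopy run.
#' @param histology also render the histology series.
#' @return invisibly, the truth list written to \code{truth.json}.
#' @export
makePhantomFixtures <- function(dir, spec = phantomSpec(),
                                retinotopy = FALSE, histology = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- makePhantom(spec)
  writeSurface(ph$surface, file.path(dir, "surface.gii"))
  st <- renderStructural(ph$surface, ph$truth, spec)
  writeVolume(st$t1w, file.path(dir, "t1w.nii.gz"))
  writeVolume(st$t2w, file.path(dir, "t2w.nii.gz"))
  ff <- renderFunctional(ph$surface, ph$truth, spec, "full_field")
  writeVolume(ff$zmap, file.path(dir, "zstat_full_field.nii.gz"))
  ip <- renderFunctional(ph$surface, ph$truth, spec, "ipsilateral")
  writeVolume(ip$zmap, file.path(dir, "zstat_ipsilateral.nii.gz"))
  writeMask(ff$clusterVoxels, file.path(dir, "truth_cluster_voxels.txt"))
  truth <- list(patchVertices = ph$truth@patchVertices,
                patchArea = ph$truth@patchArea,
                peakDepth = ph$truth@peakDepth,
                seed = spec@seed)
  if (retinotopy) {
    rr <- renderRetinotopy(ph$surface, ph$truth, spec)
    writeVolume(rr$series, file.path(dir, "retinotopy.nii.gz"))
  }
  if (histology) {
    hh <- renderHistology(ph$surface, ph$truth, spec)
    writeSectionSeries(hh$series, file.path(dir, "histology"))
    truth$sectionLengths <- hh$trueLengths
    truth$sectionPositions <- hh$positions
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
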