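## Areal overlap/correspondence statistics, permutation nulls by intensity
## shuffling, pairwise overlap matrices and the threshold-sensitivity sweep.

newCorrespondence <- function(nOverlap, denominator, context) {
  new("CorrespondenceResult", percent = 100 * nOverlap / denominator,
      nOverlap = as.integer(nOverlap), denominator = as.integer(denominator),
      context = context)
}

#' Percent of a correspondence result
#' @param x a \linkS4class{CorrespondenceResult}.
#' @return numeric percent in [0,100].
#' @export
setGeneric("percent", function(x) standardGeneric("percent"))

#' @rdname percent
#' @export
setMethod("percent", "CorrespondenceResult", function(x) x@percent)

#' Whole-cortex correspondence between two masks
#'
#' 100 * |A intersect B| / |A union B|: the overlapping locations counted
#' once in the denominator.
#'
#' @param maskA,maskB \linkS4class{IndexMask} objects sharing a parent.
#' @return A \linkS4class{CorrespondenceResult}.
#' @export
wholeCortexCorrespondence <- function(maskA, maskB) {
  checkSameParent(maskA, maskB)
  nU <- length(union(maskA@indices, maskB@indices))
  if (nU == 0L)
    stop(corticomapError("empty_masks", "both masks are empty"))
  newCorrespondence(length(intersect(maskA@indices, maskB@indices)), nU,
                    "whole_cortex")
}

#' Correspondence between two masks within a region of interest
#'
#' 100 * |A . B . R| / denominator, with the denominator the thresholded
#' locations within the ROI: by default the union (A u B) within R, counting
#' overlaps once, mirroring the whole-cortex rule; \code{denominator =
#' "sum"} gives the double-counting (Dice-like) variant.
#'
#' @param maskA,maskB thresholded \linkS4class{IndexMask} objects.
#' @param roi the ROI \linkS4class{IndexMask}, non-empty.
#' @param denominator "union" (default) or "sum".
#' @return A \linkS4class{CorrespondenceResult}.
#' @export
roiCorrespondence <- function(maskA, maskB, roi,
                              denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  checkSameParent(maskA, maskB)
  checkSameParent(maskA, roi)
  if (!length(roi@indices))
    stop(corticomapError("empty_roi", "ROI is empty"))
  aR <- intersect(maskA@indices, roi@indices)
  bR <- intersect(maskB@indices, roi@indices)
  den <- if (denominator == "union") length(union(aR, bR))
         else length(aR) + length(bR)
  if (den == 0L)
    stop(corticomapError("empty_roi",
      "no thresholded locations within the ROI"))
  num <- length(intersect(aR, bR))
  if (denominator == "sum") num <- 2L * num
  newCorrespondence(num, den, "roi")
}

#' Percent of an ROI that is heavily myelinated
#'
#' 100 * |roi intersect myelinMask| / |roi|: the share of a functionally
#' defined region whose locations also carry above-threshold myelin signal.
#'
#' @param roi non-empty \linkS4class{IndexMask}.
#' @param myelinMask thresholded myelin \linkS4class{IndexMask}.
#' @return A \linkS4class{CorrespondenceResult}.
#' @export
percentRoiMyelinated <- function(roi, myelinMask) {
  checkSameParent(roi, myelinMask)
  if (!length(roi@indices))
    stop(corticomapError("empty_roi", "ROI is empty"))
  newCorrespondence(length(intersect(roi@indices, myelinMask@indices)),
                    length(roi@indices), "percent_roi")
}

#' Permutation null by intensity shuffling
#'
#' Each permutation independently shuffles each map's valid values across
#' its valid vertices (preserving the value distribution, hence the mask
#' size under quantile rules and approximately under SEM rules),
#' re-thresholds both maps with the same rule, and recomputes the chosen
#' correspondence statistic. The p-value uses the add-one convention.
#'
#' @param mapA,mapB \linkS4class{VertexMap} objects on one surface; for
#'   \code{statistic = "pct_roi"} only \code{mapA} is used (the ROI stays
#'   fixed) and \code{mapB} may be NULL.
#' @param rule a threshold rule (\code{\link{topFraction}} or
#'   \code{\link{meanPlusKSEM}}).
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param statistic "whole_cortex", "roi" or "pct_roi".
#' @param roi ROI \linkS4class{IndexMask}, required for the "roi" and
#'   "pct_roi" statistics.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param exclusionMask optional exclusion \linkS4class{IndexMask}.
#' @return A \linkS4class{PermutationNull}.
#' @export
shuffleNull <- function(mapA, mapB, rule, surface,
                        statistic = c("whole_cortex", "roi", "pct_roi"),
                        roi = NULL,
                        nPerm = 1000L, seed = 0L, exclusionMask = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(nPerm >= 1)
  if (statistic != "pct_roi" && !identical(mapA@surfaceRef, mapB@surfaceRef))
    stop(corticomapError("parent_mismatch", "maps are on different surfaces"))
  if (statistic %in% c("roi", "pct_roi") && is.null(roi))
    stop(corticomapError("missing_roi",
      paste("statistic", statistic, "needs an ROI")))
  stat <- function(a, b) {
    r <- switch(statistic,
                whole_cortex = wholeCortexCorrespondence(a, b),
                roi = roiCorrespondence(a, b, roi),
                pct_roi = percentRoiMyelinated(roi, a))
    r@percent
  }
  thr <- function(m) thresholdMap(m, rule, surface, exclusionMask)
  pair <- function(a) if (statistic == "pct_roi") NULL else thr(a)
  observed <- stat(thr(mapA), pair(mapB))
  shuffleMap <- function(m) {
    idx <- which(m@valid)
    v <- m@values
    v[idx] <- v[sample(idx)]
    out <- m
    out@values <- v
    out
  }
  nulls <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    stat(thr(shuffleMap(mapA)),
         if (statistic == "pct_roi") NULL else thr(shuffleMap(mapB))),
    numeric(1)))
  new("PermutationNull", nPerm = as.integer(nPerm), nullPercents = nulls,
      observed = observed,
      pValue = (1 + sum(nulls >= observed)) / (nPerm + 1))
}

#' Pairwise overlap matrix across subjects' masks
#'
#' Symmetric matrix of the whole-cortex correspondence (or a supplied
#' statistic) over all unordered pairs of masks in one common space, with
#' the mean and sd of the off-diagonal entries attached as attributes.
#'
#' @param masks list of >= 2 \linkS4class{IndexMask} objects.
#' @param statistic a function(maskA, maskB) returning a
#'   \linkS4class{CorrespondenceResult}; default
#'   \code{\link{wholeCortexCorrespondence}}.
#' @return numeric matrix of percents with attributes "mean" and "sd".
#' @export
pairwiseOverlapMatrix <- function(masks,
                                  statistic = wholeCortexCorrespondence) {
  if (length(masks) < 2L)
    stop(corticomapError("too_few_masks", "need at least 2 masks"))
  n <- length(masks)
  M <- matrix(100, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- percent(statistic(masks[[i]], masks[[j]]))
  }
  off <- M[upper.tri(M)]
  attr(M, "mean") <- mean(off)
  attr(M, "sd") <- stats::sd(off)
  M
}

#' Map a voxel mask onto a surface
#'
#' A vertex joins the surface mask when its depth-fraction sample point
#' falls inside a member voxel (nearest-voxel membership), letting
#' volume-defined functional ROIs be compared with surface-defined myelin
#' masks in one parent space.
#'
#' @param mask a voxel \linkS4class{IndexMask}.
#' @param volume the mask's parent \linkS4class{BrainVolume}.
#' @param surface the target \linkS4class{CorticalSurface}.
#' @param depthFraction sampling depth fraction (default 0.5).
#' @return a vertex \linkS4class{IndexMask}.
#' @export
maskToSurface <- function(mask, volume, surface, depthFraction = 0.5) {
  if (!identical(mask@parentRef, parentFingerprint(volume)))
    stop(corticomapError("parent_mismatch", "mask is not on this volume"))
  pts <- surface@verticesWhite +
    depthFraction * (surface@verticesPial - surface@verticesWhite)
  v <- cbind(pts, 1) %*% t(solve(volume@transform))
  ijk <- round(v[, 1:3, drop = FALSE])
  d <- dim(volume@data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  lin <- rep(NA_integer_, nrow(ijk))
  lin[ok] <- 1L + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
  inmask <- logical(prod(d)); inmask[mask@indices] <- TRUE
  vertexMask(which(ok & inmask[ifelse(ok, lin, 1L)]), surface)
}

#' Threshold-sensitivity sweep of structural x functional definitions
#'
#' Re-derives the myelin mask for each structural rule (mean + k SEM over
#' the default grid k = 0, 0.5, 1, 1.5) and the functional ROI for each
#' cluster-forming z (default 1.3, 1.8, 2.3, 2.8), then tabulates mask
#' sizes, percent-of-ROI-myelinated and the whole-cortex correspondence of
#' the two vertex masks for every cell.
#'
#' @param structMap myelin-weighted \linkS4class{VertexMap}.
#' @param funcZmap full-field z \linkS4class{BrainVolume}.
#' @param surface parent \linkS4class{CorticalSurface} (co-registered).
#' @param anchor world coordinate of the putative complex, mm.
#' @param structKs SEM multipliers for the structural axis.
#' @param zList cluster-forming thresholds for the functional axis.
#' @param cfg base \code{\link{clusterConfig}}; its zThreshold is replaced
#'   per cell.
#' @param depthFraction depth fraction for voxel-to-surface ROI conversion.
#' @param exclusionMask optional exclusion mask for the structural rules.
#' @return data.frame with one row per (k, z) cell.
#' @export
thresholdSweep <- function(structMap, funcZmap, surface, anchor,
                           structKs = c(0, 0.5, 1, 1.5),
                           zList = c(1.3, 1.8, 2.3, 2.8),
                           cfg = clusterConfig(minExtent = 10),
                           depthFraction = 0.5, exclusionMask = NULL) {
  rows <- list()
  rois <- lapply(zList, function(z) {
    czz <- cfg; czz$zThreshold <- z
    hmt <- defineHMT(funcZmap, czz, anchor)
    list(vox = hmt,
         surf = maskToSurface(hmt, funcZmap, surface, depthFraction))
  })
  for (k in structKs) {
    mmask <- thresholdMap(structMap, meanPlusKSEM(k), surface, exclusionMask)
    for (iz in seq_along(zList)) {
      roi <- rois[[iz]]$surf
      pct <- if (maskSize(roi)) percent(percentRoiMyelinated(roi, mmask))
             else NA_real_
      corr <- if (maskSize(roi) || maskSize(mmask))
        percent(wholeCortexCorrespondence(roi, mmask)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        structK = k, zThreshold = zList[iz],
        myelinSize = maskSize(mmask), roiSizeVox = maskSize(rois[[iz]]$vox),
        roiSize = maskSize(roi), pctRoiMyelinated = pct,
        correspondence = corr)
    }
  }
  do.call(rbind, rows)
}
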