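## Myelin-weighted map construction and thresholding.

#' Threshold rules for myelin-weighted maps
#'
#' \code{topFraction(f)} keeps vertices whose value is at or above the
#' (1 - f) quantile of the valid, non-excluded values (ties at the boundary
#' are all included). The alternative reading of a "top third of the
#' intensity range" is available with \code{reading = "intensity_range"},
#' which keeps values >= min + (1 - f) * range. \code{meanPlusKSEM(k)} keeps
#' vertices strictly above mean + k * sd/sqrt(n) over the valid,
#' non-excluded values, the rule used for mean-intensity "+ k SEM"
#' thresholds.
#'
#' @param f fraction in (0,1) of vertices (or of the intensity range) kept.
#' @param reading "quantile" (default) or "intensity_range".
#' @param k non-negative number of standard errors above the mean.
#' @return a threshold-rule object.
#' @export
topFraction <- function(f, reading = c("quantile", "intensity_range")) {
  reading <- match.arg(reading)
  stopifnot(f > 0, f < 1)
  structure(list(type = "top_fraction", f = f, reading = reading),
            class = "corticomap_rule")
}

#' @rdname topFraction
#' @export
meanPlusKSEM <- function(k) {
  stopifnot(k >= 0)
  structure(list(type = "mean_plus_k_sem", k = k), class = "corticomap_rule")
}

ruleThreshold <- function(rule, values) {
  if (rule$type == "top_fraction") {
    if (rule$reading == "quantile")
      list(cut = stats::quantile(values, 1 - rule$f, names = FALSE, type = 7),
           strict = FALSE)
    else
      list(cut = min(values) + (1 - rule$f) * (max(values) - min(values)),
           strict = FALSE)
  } else {
    n <- length(values)
    sem <- stats::sd(values) / sqrt(n)
    list(cut = mean(values) + rule$k * sem, strict = TRUE)
  }
}

#' Voxelwise T1w/T2w ratio map
#'
#' Repeats of each modality are averaged first (voxelwise, over valid
#' repeats), then the mean T1w image is divided by the mean T2w image.
#' Voxels whose mean T2w is at or below \code{eps}, or that are invalid in
#' any input, are flagged invalid rather than set to infinity.
#'
#' @param t1wRepeats a \linkS4class{BrainVolume} or list of them.
#' @param t2wRepeats a \linkS4class{BrainVolume} or list of them.
#' @param eps guard level for the denominator.
#' @return A \linkS4class{BrainVolume} holding the ratio.
#' @export
ratioMap <- function(t1wRepeats, t2wRepeats, eps = 1e-6) {
  asList <- function(x) if (is(x, "BrainVolume")) list(x) else x
  t1 <- asList(t1wRepeats); t2 <- asList(t2wRepeats)
  stopifnot(length(t1) >= 1, length(t2) >= 1)
  ref <- t1[[1]]
  for (v in c(t1, t2)) checkSameGrid(ref, v)
  meanOf <- function(vols) {
    acc <- array(0, dim(ref@data)); ok <- array(TRUE, dim(ref@data))
    for (v in vols) { acc <- acc + v@data; ok <- ok & v@valid }
    list(mean = acc / length(vols), ok = ok)
  }
  m1 <- meanOf(t1); m2 <- meanOf(t2)
  valid <- m1$ok & m2$ok & (m2$mean > eps)
  ratio <- array(NA_real_, dim(ref@data))
  ratio[valid] <- m1$mean[valid] / m2$mean[valid]
  brainVolume(ratio, voxelSize = ref@voxelSize, transform = ref@transform,
              spaceTag = ref@spaceTag)
}

#' Sample a volume onto a surface at a cortical depth fraction
#'
#' Each vertex is sampled at white + depthFraction * (pial - white) by
#' trilinear interpolation in voxel space. Vertices whose 8-voxel
#' interpolation neighbourhood touches an invalid voxel are flagged invalid;
#' sample points outside the volume bounds raise an error.
#'
#' @param vol a \linkS4class{BrainVolume}, co-registered with the surface.
#' @param surface a \linkS4class{CorticalSurface}.
#' @param depthFraction unitless in [0,1] (0 = white, 1 = pial).
#' @return A \linkS4class{VertexMap}.
#' @export
sampleToSurface <- function(vol, surface, depthFraction) {
  stopifnot(depthFraction >= 0, depthFraction <= 1)
  pts <- surface@verticesWhite +
    depthFraction * (surface@verticesPial - surface@verticesWhite)
  v <- cbind(pts, 1) %*% t(solve(vol@transform))
  v <- v[, 1:3, drop = FALSE]
  d <- dim(vol@data)
  if (any(v < -1e-9) || any(v > rep(d - 1, each = nrow(v)) + 1e-9))
    stop(corticomapError("sample_out_of_bounds",
      "vertex sample point lies outside the volume"))
  v <- pmin(pmax(v, 0), rep(d - 1, each = nrow(v)))
  i0 <- pmin(floor(v), rep(d - 2, each = nrow(v)))
  fr <- v - i0
  lin <- function(di, dj, dk)
    1L + (i0[, 1] + di) + d[1] * ((i0[, 2] + dj) + d[2] * (i0[, 3] + dk))
  val <- 0; ok <- TRUE
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
         (if (dj) fr[, 2] else 1 - fr[, 2]) *
         (if (dk) fr[, 3] else 1 - fr[, 3])
    ii <- lin(di, dj, dk)
    val <- val + w * vol@data[ii]
    ok <- ok & (vol@valid[ii] | w == 0)
  }
  vertexMap(ifelse(ok, val, NA_real_), surface,
            depthFraction = depthFraction)
}

#' Find the depth fraction with the greatest mean intensity
#'
#' Samples the volume at each candidate cortical thickness fraction and
#' returns the one maximizing the mean over valid vertices; exact ties break
#' toward the smaller fraction. The per-fraction means are attached as the
#' "means" attribute.
#'
#' @param vol a \linkS4class{BrainVolume}.
#' @param surface a \linkS4class{CorticalSurface}.
#' @param fractions candidate fractions (default the 11-step grid 0, 0.1,
#'   ..., 1 used when choosing a sampling depth).
#' @return the selected fraction (numeric scalar).
#' @export
optimalDepthFraction <- function(vol, surface, fractions = seq(0, 1, 0.1)) {
  stopifnot(length(fractions) >= 2)
  fractions <- sort(fractions)
  means <- vapply(fractions, function(f) {
    m <- sampleToSurface(vol, surface, f)
    if (!any(m@valid))
      stop(corticomapError("all_invalid", "all vertices sampled invalid"))
    mean(m@values[m@valid])
  }, numeric(1))
  out <- fractions[which.max(means)]
  attr(out, "means") <- stats::setNames(means, fractions)
  out
}

#' Threshold a vertex map into a "heavily myelinated" mask
#'
#' Applies a \code{\link{topFraction}} or \code{\link{meanPlusKSEM}} rule
#' over the valid, non-excluded vertices. Excluded vertices enter neither
#' the reference statistics (quantile, mean, SEM) nor the output mask.
#'
#' @param map a \linkS4class{VertexMap} with at least 2 valid vertices.
#' @param rule a threshold rule.
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param exclusionMask optional \linkS4class{IndexMask} of vertices to
#'   ignore (e.g. a temporal-lobe artifact mask).
#' @return A vertex \linkS4class{IndexMask}. The threshold value used is
#'   attached as the "threshold" attribute.
#' @export
thresholdMap <- function(map, rule, surface, exclusionMask = NULL) {
  stopifnot(inherits(rule, "corticomap_rule"))
  use <- map@valid
  if (!is.null(exclusionMask)) {
    if (!identical(exclusionMask@parentRef, map@surfaceRef))
      stop(corticomapError("parent_mismatch",
        "exclusion mask is not on the map's surface"))
    use[exclusionMask@indices] <- FALSE
  }
  if (sum(use) < 2L)
    stop(corticomapError("empty_after_exclusion",
      "fewer than 2 usable vertices after exclusion"))
  th <- ruleThreshold(rule, map@values[use])
  keep <- if (th$strict) map@values > th$cut else map@values >= th$cut
  mask <- vertexMask(which(keep & use), surface)
  attr(mask, "threshold") <- th$cut
  mask
}

#' Surface area of the contiguous masked region containing a seed
#'
#' Sums the per-vertex midthickness areas over the edge-connected component
#' of the mask that contains the seed vertex, i.e. the extent of
#' above-threshold vertices in native anatomical space.
#'
#' @param mask a vertex \linkS4class{IndexMask}.
#' @param surface the parent \linkS4class{CorticalSurface}.
#' @param seedVertex 1-based seed vertex, which must be in the mask.
#' @return area in mm^2, with the component's vertex indices attached as the
#'   "vertices" attribute.
#' @export
contiguousRegionArea <- function(mask, surface, seedVertex) {
  if (!identical(mask@parentRef, parentFingerprint(surface)))
    stop(corticomapError("parent_mismatch", "mask is not on this surface"))
  comp <- vertexComponent(mask@indices, surface, seedVertex)
  area <- sum(vertexAreas(surface)[comp])
  attr(area, "vertices") <- comp
  area
}

#' Clip a map's display range
#'
#' Clamps values to [min + low/100 * range, min + high/100 * range] over the
#' full range of valid values. For visualization only: statistics in this
#' package never use clipped values.
#'
#' @param map a \linkS4class{VertexMap}.
#' @param lowPct,highPct percent of the full intensity range (defaults 4 and
#'   96).
#' @return a clipped \linkS4class{VertexMap}.
#' @export
displayClip <- function(map, lowPct = 4, highPct = 96) {
  stopifnot(lowPct < highPct)
  v <- map@values[map@valid]
  if (!length(v)) return(map)
  rng <- range(v)
  if (rng[1] == rng[2]) return(map)
  lo <- rng[1] + lowPct / 100 * diff(rng)
  hi <- rng[1] + highPct / 100 * diff(rng)
  out <- map
  out@values <- pmin(pmax(map@values, lo), hi)
  out@values[!map@valid] <- 0
  out
}
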